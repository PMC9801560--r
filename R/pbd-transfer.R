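# Transfer-integral machinery.
#
# The configuration integral of an N-base-pair chain,
#   Z = int dy_1..dy_N exp(-beta [V_1(y_1) + sum_{i>=2} V_i(y_i) + W(y_i, y_{i-1})]),
# factorizes into a chain of one-dimensional integrals. On a fixed
# quadrature grid it becomes a product of diagonal site factors
# d_i(y) = w(y) exp(-beta V_i(y)) and dense transfer matrices
# T_i(y, y') = exp(-beta W(y, y')), evaluated by iterated matrix-vector
# products: cost linear in N, quadratic in the number of abscissae.
# Boltzmann weights span hundreds of orders of magnitude over long chains,
# so every vector is renormalized per step and an accumulated log-scale is
# carried; all reported probabilities are ratios and therefore invariant
# to the scaling.

# Precomputed engine for one (sequence, temperature, grid, params) context:
# site-factor matrix, per-step transfer matrices (shared across the <=16
# distinct stacking strengths), and forward/backward passes.
.pbd_engine <- function(sequence, temperature, grid, params) {
  bases <- .check_sequence(sequence)
  N <- length(bases)
  if (N < 2) stop("sequence must have at least 2 base pairs")
  beta <- 1 / (params$kB * temperature)
  y <- grid$nodes
  M <- length(y)

  pair <- .pair_type(bases)
  Vat <- onsite_potential(y, "AT", params)
  Vgc <- onsite_potential(y, "GC", params)
  D <- matrix(0, M, N)
  D[, pair == "AT"] <- grid$weights * exp(-beta * Vat)
  D[, pair == "GC"] <- grid$weights * exp(-beta * Vgc)

  # transfer matrices keyed by distinct stacking strength K
  dimers <- paste0(bases[-N], bases[-1])          # step i couples i-1 -> i
  Kstep <- params$K_dimer[dimers]
  Ku <- unique(Kstep)
  # shared anharmonic factor: -beta/2 (1 + rho e^{-delta(y+y')}) (y-y')^2
  B <- -beta * 0.5 * (1 + params$rho * exp(-params$delta * outer(y, y, "+"))) *
    outer(y, y, "-")^2
  Tmats <- lapply(Ku, function(K) exp(K * B))
  names(Tmats) <- as.character(Ku)
  stepT <- as.character(Kstep)                    # length N-1, step i+1

  list(bases = bases, N = N, M = M, beta = beta, grid = grid,
       D = D, Tmats = Tmats, stepT = stepT)
}

# One rescaled propagation step: v -> d * (T v); returns vector + log-scale.
.prop_step <- function(v, Tm, dcol, mask = NULL) {
  v <- dcol * (Tm %*% v)
  if (!is.null(mask)) v <- v * mask
  s <- max(v)
  if (s <= 0) return(list(v = v, logs = -Inf))
  list(v = drop(v / s), logs = log(s))
}

# Forward/backward vectors, normalized columns + per-column log scales.
# F[, i] ~ d_i (T_i F[, i-1]); G[, i] ~ t(T_{i+1}) (d_{i+1} G[, i+1]).
# Z = sum(F[, i] * G[, i]) * exp(LF[i] + LG[i]) for every i.
.forward_backward <- function(eng) {
  N <- eng$N; M <- eng$M
  Fm <- matrix(0, M, N); LF <- numeric(N)
  Gm <- matrix(0, M, N); LG <- numeric(N)
  v <- eng$D[, 1]; s <- max(v); Fm[, 1] <- v / s; LF[1] <- log(s)
  for (i in 2:N) {
    st <- .prop_step(Fm[, i - 1], eng$Tmats[[eng$stepT[i - 1]]], eng$D[, i])
    Fm[, i] <- st$v; LF[i] <- LF[i - 1] + st$logs
  }
  Gm[, N] <- 1; LG[N] <- 0
  for (i in (N - 1):1) {
    # T symmetric (W symmetric in its two arguments), so no transpose needed
    v <- eng$Tmats[[eng$stepT[i]]] %*% (eng$D[, i + 1] * Gm[, i + 1])
    s <- max(v)
    Gm[, i] <- drop(v / s); LG[i] <- LG[i + 1] + log(s)
  }
  logZ <- LF[N] + log(sum(Fm[, N]))
  list(F = Fm, LF = LF, G = Gm, LG = LG, logZ = logZ)
}

# log partition value with an arbitrary per-position mask list (NULL = free);
# single forward pass.
.masked_logZ <- function(eng, masks) {
  v <- eng$D[, 1]
  if (!is.null(masks[[1]])) v <- v * masks[[1]]
  s <- max(v)
  if (s <= 0) return(-Inf)
  v <- v / s; logZ <- log(s)
  for (i in 2:eng$N) {
    st <- .prop_step(v, eng$Tmats[[eng$stepT[i - 1]]], eng$D[, i], masks[[i]])
    if (!is.finite(st$logs)) return(-Inf)
    v <- st$v; logZ <- logZ + st$logs
  }
  logZ + log(sum(v))
}

.constraint_masks <- function(eng, constraint) {
  open <- eng$grid$open
  if (is.null(constraint)) constraint <- rep("free", eng$N)
  if (length(constraint) != eng$N) {
    stop("constraint must give one of free/closed/open for each of the N positions")
  }
  lapply(constraint, function(ci) {
    switch(ci,
           free = NULL,
           unconstrained = NULL,
           closed = as.numeric(!open),
           open = as.numeric(open),
           stop(sprintf("unknown constraint '%s'", ci)))
  })
}

#' Constrained configuration integral of a PBD chain
#'
#' Evaluates the configurational partition value of the chain over the
#' finite quadrature domain, optionally constraining each position to the
#' closed (`y < xi`) or open (`y > xi`) half of the domain. With all
#' positions unconstrained this is the full configuration integral `Z_I`
#' restricted to the grid domain; with all positions open it is the
#' statistical weight `Z_II` of the fully denatured states.
#'
#' @param sequence Base string or character vector over ACGT; length >= 2.
#' @param temperature Temperature in kelvin.
#' @param grid A [quad_grid()].
#' @param params A [pbd_params()].
#' @param constraint `NULL` (all free) or a character vector of length `N`
#'   with entries `"free"`, `"closed"`, or `"open"`.
#' @param log If `TRUE` return the log partition value (recommended for
#'   long chains, where the linear value under/overflows).
#' @return The partition value (or its log).
#' @examples
#' g <- quad_grid(96)
#' transfer_partition("ATAT", 310, g)
#' transfer_partition("ATAT", 310, g, constraint = rep("closed", 4))
#' @export
transfer_partition <- function(sequence, temperature, grid = quad_grid(),
                               params = pbd_params(), constraint = NULL,
                               log = FALSE) {
  eng <- .pbd_engine(sequence, temperature, grid, params)
  lz <- .masked_logZ(eng, .constraint_masks(eng, constraint))
  if (log) lz else exp(lz)
}

#' Probability that a base pair is closed in the dsDNA ensemble
#'
#' `P(j closed) = Z(j closed) / (Z_I - Z_II)`: the statistical weight of
#' configurations with `y_j < xi`, relative to the double-stranded ensemble
#' (all configurations minus the fully open states). The complement
#' `1 - P(j closed)` is the single-base opening probability.
#'
#' @inheritParams transfer_partition
#' @param j Position index (1-based), or `NULL` for all positions at once
#'   (computed in a single forward/backward sweep).
#' @return Probability (scalar, or vector of length `N` when `j` is `NULL`).
#' @examples
#' closed_probability("ATAT", 310, quad_grid(96), j = 2)
#' @export
closed_probability <- function(sequence, temperature, grid = quad_grid(),
                               params = pbd_params(), j = NULL) {
  eng <- .pbd_engine(sequence, temperature, grid, params)
  fb <- .forward_backward(eng)
  logZpi <- .masked_logZ(eng, rep(list(as.numeric(eng$grid$open)), eng$N))
  denom <- 1 - exp(logZpi - fb$logZ)   # (Z_I - Z_II)/Z_I
  if (denom <= .Machine$double.eps * 8) {
    stop("degenerate regime: Z_I - Z_II vanishes within tolerance (chain fully denatured)")
  }
  closed <- as.numeric(!eng$grid$open)
  jj <- if (is.null(j)) seq_len(eng$N) else j
  if (any(jj < 1 | jj > eng$N)) stop("position j outside 1..N")
  p <- vapply(jj, function(k) {
    num <- sum(fb$F[, k] * closed * fb$G[, k])
    exp(fb$LF[k] + fb$LG[k] + log(num) - fb$logZ) / denom
  }, numeric(1))
  pmin(pmax(p, 0), 1)
}

# All-open weights of every length-m window, as log values relative to
# nothing (absolute logs). Returns vector over starts a = 1..N-m+1 with
# logZ of "positions a..a+m-1 all open, rest free". Vectorized over starts:
# running vectors for all starts are propagated together, grouped by the
# transfer matrix of the current step.
.window_open_logZ <- function(eng, fb, m) {
  N <- eng$N; M <- eng$M
  starts <- seq_len(N - m + 1)
  ns <- length(starts)
  open <- as.numeric(eng$grid$open)
  V <- matrix(0, M, ns)
  logs <- numeric(ns)
  # initialize at step t = 1 (site index a): from F[, a-1], or fresh at a = 1
  idx <- starts                      # current site per column
  V[, idx == 1] <- eng$D[, 1] * open
  if (any(idx > 1)) {
    cols <- which(idx > 1)
    a <- starts[cols]
    for (key in unique(eng$stepT[a - 1])) {
      cc <- cols[eng$stepT[a - 1] == key]
      V[, cc] <- (eng$Tmats[[key]] %*% fb$F[, starts[cc] - 1, drop = FALSE]) *
        (open * eng$D[, starts[cc], drop = FALSE])
    }
    logs[cols] <- fb$LF[starts[cols] - 1]
  }
  # no per-step rescaling inside the scan: the window has at most m + 1
  # steps starting from a normalized forward vector, which cannot underflow
  if (m > 1) {
    for (t in 2:m) {
      idx <- starts + t - 1
      for (key in unique(eng$stepT[idx - 1])) {
        cc <- which(eng$stepT[idx - 1] == key)
        V[, cc] <- (eng$Tmats[[key]] %*% V[, cc, drop = FALSE]) *
          (open * eng$D[, idx[cc], drop = FALSE])
      }
    }
  }
  ends <- starts + m - 1
  dots <- colSums(V * fb$G[, ends, drop = FALSE])
  logs + fb$LG[ends] + log(dots)
}
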
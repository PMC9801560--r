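# Bubble statistics in the dsDNA ensemble.
#
# A base pair is open when y > y0. A bubble of exact size m centred at k is
# a run of m consecutive open pairs flanked by closed ones (virtual closed
# flanks beyond the chain ends); for even m the centre is the base directly
# to the left of the midpoint. All probabilities are conditioned on the
# dsDNA ensemble mu = 1 - prod(theta_i), i.e. the fully open state is
# excluded.

# open span [lo, hi] and flank positions for a bubble of size m centred k
.bubble_span <- function(k, m) {
  if (m %% 2 == 0) {
    lo <- k - m / 2 + 1; hi <- k + m / 2
  } else {
    lo <- k - (m - 1) / 2; hi <- k + (m - 1) / 2
  }
  c(lo = lo, hi = hi)
}

#' Bubble probability matrix P_bub(k, m)
#'
#' Probability of a bubble of exact size `m` centred on base pair `k`,
#' conditioned on the molecule being double-stranded (not fully open).
#' Entries whose open span would extend beyond the chain are zero; flanking
#' closed conditions beyond the ends are satisfied trivially (virtual
#' closed flanks). The exact-size-`N` column is identically zero because
#' the all-open state is excluded from the ensemble.
#'
#' @inheritParams transfer_partition
#' @param m_max Largest bubble size to tabulate (`1 <= m_max <= N`).
#' @return An object of class `bubble_matrix`: list with `values`
#'   (`N x m_max` matrix), `sequence_id`, `temperature`.
#' @examples
#' b <- bubble_matrix("ATTAT", 345, quad_grid(96), m_max = 3)
#' b$values
#' @export
bubble_matrix <- function(sequence, temperature, grid = quad_grid(),
                          params = pbd_params(), m_max = NULL,
                          sequence_id = "seq") {
  eng <- .pbd_engine(sequence, temperature, grid, params)
  N <- eng$N
  if (is.null(m_max)) m_max <- N
  if (m_max < 1 || m_max > N) stop("m_max must be in 1..N")
  fb <- .forward_backward(eng)
  open <- as.numeric(eng$grid$open)
  closed <- 1 - open
  logZpi <- .masked_logZ(eng, rep(list(open), N))
  log_denom <- fb$logZ + log1p(-exp(logZpi - fb$logZ))   # log(Z - Z_Pi)

  P <- matrix(0, N, m_max)
  for (m in seq_len(m_max)) {
    for (k in seq_len(N)) {
      sp <- .bubble_span(k, m)
      if (sp["lo"] < 1 || sp["hi"] > N) next       # open span must fit the chain
      masks <- rep(list(NULL), N)
      for (j in sp["lo"]:sp["hi"]) masks[[j]] <- open
      if (sp["lo"] - 1 >= 1) masks[[sp["lo"] - 1]] <- closed
      if (sp["hi"] + 1 <= N) masks[[sp["hi"] + 1]] <- closed
      lz <- .window_logZ_fb(eng, fb, masks, sp)
      num <- exp(lz - log_denom)
      if (m == N) num <- num - exp(logZpi - log_denom)  # exclude all-open state
      P[k, m] <- min(max(num, 0), 1)
    }
  }
  structure(list(values = P, sequence_id = sequence_id,
                 temperature = temperature, m_max = m_max, N = N),
            class = "bubble_matrix")
}

# log partition value with masks confined to a window; propagates from the
# forward vector just before the window to the backward vector at its end.
.window_logZ_fb <- function(eng, fb, masks, sp) {
  lo <- max(1, sp["lo"] - 1); hi <- min(eng$N, sp["hi"] + 1)
  if (lo == 1) {
    v <- eng$D[, 1]
    if (!is.null(masks[[1]])) v <- v * masks[[1]]
    logs <- 0
    from <- 2
  } else {
    v <- fb$F[, lo - 1]
    logs <- fb$LF[lo - 1]
    from <- lo
  }
  if (hi >= from) {
    for (i in from:hi) {
      st <- .prop_step(v, eng$Tmats[[eng$stepT[i - 1]]], eng$D[, i], masks[[i]])
      if (!is.finite(st$logs)) return(-Inf)
      v <- st$v; logs <- logs + st$logs
    }
  }
  logs + fb$LG[hi] + log(sum(v * fb$G[, hi]))
}

#' Participation probability from a bubble matrix
#'
#' `P_part(k, m)`: probability that base pair `k` participates in a bubble
#' of size at least `m`, obtained by summing `P_bub(k', m')` over all sizes
#' `m' >= m` and all centres `k'` whose bubble span covers `k` (separate
#' centre ranges for even and odd `m'`; centres outside the chain
#' contribute zero). Since exact-size bubble events are disjoint, the sum
#' is itself a probability. Note `P_part(k, 1)` is the plain opening
#' probability of base `k` in the dsDNA ensemble, which differs from
#' `P_bub(k, 1)` (the latter requires closed neighbours).
#'
#' @param bub A [bubble_matrix()] computed with `m_max = N` (participation
#'   sums run over all sizes up to the chain length).
#' @param m Minimum bubble size (>= 1).
#' @return An object of class `opening_profile` with one value per base.
#' @export
participation_profile <- function(bub, m = 1) {
  stopifnot(inherits(bub, "bubble_matrix"))
  N <- bub$N
  if (m < 1 || m > bub$m_max) stop("m must be in 1..m_max of the bubble matrix")
  P <- bub$values
  vals <- vapply(seq_len(N), function(k) {
    tot <- 0
    for (mp in m:bub$m_max) {
      if (mp %% 2 == 0) {
        kk <- (k - mp / 2):(k + mp / 2 - 1)
      } else {
        kk <- (k - (mp - 1) / 2):(k + (mp - 1) / 2)
      }
      kk <- kk[kk >= 1 & kk <= N]
      tot <- tot + sum(P[kk, mp])
    }
    tot
  }, numeric(1))
  new_opening_profile(pmin(pmax(vals, 0), 1), bub$sequence_id, bub$temperature,
                      m = m, kind = "participation", trimmed = FALSE)
}

#' Opening / bubble-participation profile of a sequence (direct route)
#'
#' Computes `P_part(k, m)` for every base `k` directly, without tabulating
#' the full bubble matrix: base `k` participates in a bubble of size at
#' least `m` exactly when some window of `m` consecutive open base pairs
#' contains `k`. The union over the (nested-overlap) windows telescopes
#' into all-open window weights of sizes `m` and `m + 1`, each evaluated by
#' the transfer scheme, so the cost is linear in `N`. Agrees with the
#' [participation_profile()] summation over a full [bubble_matrix()] (used
#' as a cross-check in the test-suite) but is fast enough for production
#' windows.
#'
#' @inheritParams transfer_partition
#' @param m Minimum bubble size (1 = single-base opening).
#' @param sequence_id Identifier carried into the result.
#' @return An object of class `opening_profile` (untrimmed, length `N`).
#' @examples
#' opening_profile("ATATTAAT", 345, quad_grid(96), m = 2)
#' @export
opening_profile <- function(sequence, temperature, grid = quad_grid(),
                            params = pbd_params(), m = 1,
                            sequence_id = "seq") {
  eng <- .pbd_engine(sequence, temperature, grid, params)
  N <- eng$N
  if (m < 1 || m > N) stop("m must be in 1..N")
  fb <- .forward_backward(eng)
  open <- as.numeric(eng$grid$open)
  logZpi <- .masked_logZ(eng, rep(list(open), N))
  pPi <- exp(logZpi - fb$logZ)
  q_m <- exp(.window_open_logZ(eng, fb, m) - fb$logZ)      # starts 1..N-m+1
  q_m1 <- if (m < N) exp(.window_open_logZ(eng, fb, m + 1) - fb$logZ) else numeric(0)
  # union over windows [a, a+m-1] containing k, first-occurrence telescoping:
  # P(union_{a=s..t} A_a) = q_m[s] + sum_{a=s+1..t} (q_m[a] - q_m1[a-1])
  cum <- c(0, cumsum(q_m[-1] - q_m1[seq_len(max(0, length(q_m) - 1))]))
  vals <- vapply(seq_len(N), function(k) {
    s <- max(1, k - m + 1); t <- min(k, N - m + 1)
    if (t < s) return(0)
    (q_m[s] + cum[t] - cum[s] - pPi) / (1 - pPi)
  }, numeric(1))
  new_opening_profile(pmin(pmax(vals, 0), 1), sequence_id, temperature,
                      m = m, kind = "participation", trimmed = FALSE)
}

new_opening_profile <- function(values, sequence_id, temperature, m, kind,
                                trimmed) {
  stopifnot(all(values >= 0 & values <= 1))
  structure(list(values = values, sequence_id = sequence_id,
                 temperature = temperature, m = m, kind = kind,
                 trimmed = trimmed),
            class = "opening_profile")
}

#' @export
print.opening_profile <- function(x, ...) {
  cat(sprintf("opening profile '%s': %d values, T = %g K, m = %d%s\n",
              x$sequence_id, length(x$values), x$temperature, x$m,
              if (x$trimmed) " (trimmed)" else ""))
  print(utils::head(round(x$values, 5), 10))
  invisible(x)
}

#' Trimmed probability profile for a 300-base PBD window
#'
#' Production feature extractor: takes the 300-base window centred on a
#' candidate site (positions -150..+149, site at 0-based index 150),
#' computes the bubble-participation profile `P_part(k, m)` over the whole
#' window, and discards the first and last 50 values to remove boundary
#' artefacts of the free chain ends, leaving the 200 central probabilities.
#'
#' @inheritParams opening_profile
#' @param sequence300 A 300-base ACGT string.
#' @return An `opening_profile` with 200 values, flagged trimmed.
#' @export
profile_for_window <- function(sequence300, temperature, grid = quad_grid(),
                               params = pbd_params(), m = 1,
                               sequence_id = "seq") {
  bases <- .check_sequence(sequence300)
  if (length(bases) != 300L) {
    stop(sprintf("PBD window must have exactly 300 bases (got %d)", length(bases)))
  }
  prof <- opening_profile(bases, temperature, grid, params, m = m,
                          sequence_id = sequence_id)
  new_opening_profile(prof$values[51:250], sequence_id, temperature,
                      m = m, kind = "participation", trimmed = TRUE)
}
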
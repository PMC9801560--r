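#' Physical parameters of the PBD model
#'
#' Builds the parameter set of the Peyrard-Bishop-Dauxois (PBD) mesoscopic
#' DNA model with a barrier-augmented on-site potential. Each base pair is
#' described by one stretching coordinate `y` (in angstrom); the on-site
#' potential is a Morse well plus a solvent/entropy barrier for `y > 0`, and
#' neighbouring base pairs are coupled by an anharmonic stacking potential
#' whose effective stiffness drops from `K(1 + rho)` to `K` on opening.
#'
#' Defaults are the published parameterization for heterogeneous B-DNA:
#' per-pair Morse and barrier constants for AT and GC, a single `rho` and
#' `delta` shared by all 16 ordered stacking dimers, and dimer-specific
#' stacking strengths `K` derived from quantum-chemical stacking energies.
#'
#' @param D_AT,D_GC Morse depth (eV).
#' @param alpha_AT,alpha_GC Morse inverse width (1/angstrom).
#' @param b_AT,b_GC Barrier amplitude (eV).
#' @param c_AT,c_GC Barrier inverse width.
#' @param d_AT,d_GC Barrier position factor (dimensionless, in units of the
#'   Morse inflection point).
#' @param rho Relative drop of the stacking stiffness on opening
#'   (dimensionless).
#' @param delta Stacking decay constant (1/angstrom).
#' @param K_dimer Named numeric vector of length 16 mapping each ordered
#'   dimer (read 5'->3' on the given strand, e.g. `"AT"` for A followed by
#'   T) to its stacking strength (eV/angstrom^2).
#' @param y0 Open/closed threshold separation (angstrom).
#' @param kB Boltzmann constant (eV/K).
#'
#' @return An object of class `pbd_params`.
#' @examples
#' p <- pbd_params()
#' p$K_dimer[["AA"]]
#' @export
pbd_params <- function(D_AT = 0.09075, D_GC = 0.09900,
                       alpha_AT = 3.0, alpha_GC = 3.4,
                       b_AT = 4.00, b_GC = 6.00,
                       c_AT = 0.74, c_GC = 0.74,
                       d_AT = 0.20, d_GC = 0.20,
                       rho = 25, delta = 0.8,
                       K_dimer = pbd_stacking_table(),
                       y0 = 1.5,
                       kB = 8.617333e-5) {
  p <- list(D_AT = D_AT, D_GC = D_GC,
            alpha_AT = alpha_AT, alpha_GC = alpha_GC,
            b_AT = b_AT, b_GC = b_GC,
            c_AT = c_AT, c_GC = c_GC,
            d_AT = d_AT, d_GC = d_GC,
            rho = rho, delta = delta,
            K_dimer = K_dimer, y0 = y0, kB = kB)
  scalars <- unlist(p[c("D_AT", "D_GC", "alpha_AT", "alpha_GC",
                        "b_AT", "b_GC", "c_AT", "c_GC",
                        "rho", "delta", "y0", "kB")])
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    stop("all PBD scalar parameters (except barrier position d) must be strictly positive")
  }
  if (!is.numeric(K_dimer) || length(K_dimer) != 16L ||
      !setequal(names(K_dimer), names(pbd_stacking_table()))) {
    stop("K_dimer must be a named numeric vector over the 16 ordered dimers")
  }
  if (any(K_dimer <= 0)) stop("all stacking strengths K must be strictly positive")
  structure(p, class = "pbd_params")
}

#' Published stacking strengths for the 16 ordered dimers
#'
#' Stacking strength `K` (eV/angstrom^2) of the bond between consecutive
#' base pairs, keyed by the 5'->3' dimer on the given strand. Complementary
#' dimers (e.g. `GA`/`TC`) share the same value except for the `GT`/`AC`
#' pair, which differ slightly in the published set.
#'
#' @return Named numeric vector of length 16.
#' @export
pbd_stacking_table <- function() {
  c(AT = 0.00176, AA = 0.00418, TT = 0.00418, GT = 0.00480,
    AC = 0.00462, TA = 0.00506, GA = 0.00546, TC = 0.00546,
    CC = 0.00810, GG = 0.00810, GC = 0.00865, CT = 0.00865,
    AG = 0.00865, CA = 0.01140, TG = 0.01140, CG = 0.01690)
}

#' @export
print.pbd_params <- function(x, ...) {
  cat("PBD model parameters\n")
  cat(sprintf("  Morse:   D_AT=%.5f D_GC=%.5f eV, alpha_AT=%.2f alpha_GC=%.2f 1/A\n",
              x$D_AT, x$D_GC, x$alpha_AT, x$alpha_GC))
  cat(sprintf("  barrier: b_AT=%.2f b_GC=%.2f, c=%.2f, d=%.2f\n",
              x$b_AT, x$b_GC, x$c_AT, x$d_AT))
  cat(sprintf("  stacking: rho=%g, delta=%g 1/A, K in [%.5f, %.5f] eV/A^2\n",
              x$rho, x$delta, min(x$K_dimer), max(x$K_dimer)))
  cat(sprintf("  threshold y0=%g A, kB=%g eV/K\n", x$y0, x$kB))
  invisible(x)
}

#' Quadrature grid for the transfer-integral calculation
#'
#' The configurational integrals of the PBD model are evaluated over a
#' finite stretching domain with an appropriate cut-off. The grid is a
#' composite Gauss-Legendre rule with a panel boundary at the open/closed
#' threshold `xi`, so that the open (`y > xi`) and closed (`y < xi`)
#' constraint masks align exactly with quadrature panels. Most abscissae
#' are placed in the closed panel `[y_min, xi]`, which contains the sharply
#' peaked Morse well; the open plateau `[xi, y_max]` is smooth and needs
#' few points.
#'
#' @param n_points Total number of abscissae (>= 64).
#' @param y_min,y_max Domain bounds (angstrom). The Morse wall makes the
#'   Boltzmann factor vanish below about -2; the integrand reaches its
#'   plateau well before 50.
#' @param xi Open-state cutoff (angstrom); defaults to the same 1.5
#'   threshold used to label a base pair open.
#' @param closed_fraction Fraction of points in the closed panel.
#'
#' @return An object of class `quad_grid` with fields `nodes`, `weights`,
#'   `open` (logical mask `nodes > xi`), and the construction arguments.
#' @examples
#' g <- quad_grid(128)
#' sum(g$weights)  # total domain length
#' @export
quad_grid <- function(n_points = 600, y_min = -2, y_max = 50, xi = 1.5,
                      closed_fraction = 0.7) {
  if (!(y_min < 0 && 0 < xi && xi < y_max)) {
    stop("grid requires y_min < 0 < xi < y_max")
  }
  if (n_points < 64) stop("n_points must be at least 64")
  n1 <- max(16L, round(n_points * closed_fraction))
  n2 <- n_points - n1
  g1 <- pracma::gaussLegendre(n1, y_min, xi)
  g2 <- pracma::gaussLegendre(n2, xi, y_max)
  nodes <- c(g1$x, g2$x)
  weights <- c(g1$w, g2$w)
  stopifnot(all(diff(nodes) > 0), all(weights > 0))
  structure(list(nodes = nodes, weights = weights, open = nodes > xi,
                 y_min = y_min, y_max = y_max, xi = xi,
                 n_points = length(nodes),
                 scheme = "composite-gauss-legendre"),
            class = "quad_grid")
}

#' @export
print.quad_grid <- function(x, ...) {
  cat(sprintf("quadrature grid: %d-point %s on [%g, %g] A, xi = %g A (%d open nodes)\n",
              x$n_points, x$scheme, x$y_min, x$y_max, x$xi, sum(x$open)))
  invisible(x)
}

# pair type ("AT"/"GC") per base, as an index into per-pair constants
.pair_type <- function(bases) {
  ifelse(bases %in% c("A", "T"), "AT", "GC")
}

.check_sequence <- function(sequence) {
  if (length(sequence) == 1L && is.character(sequence)) {
    sequence <- strsplit(toupper(sequence), "")[[1]]
  } else {
    sequence <- toupper(as.character(sequence))
  }
  bad <- setdiff(unique(sequence), c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    stop(sprintf("sequence contains characters outside ACGT: %s",
                 paste(bad, collapse = ", ")))
  }
  sequence
}
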
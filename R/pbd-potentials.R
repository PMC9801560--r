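#' On-site base-pair potential (Morse well plus opening barrier)
#'
#' Energy of stretching a single base pair by `y`:
#' `V(y) = D (exp(-alpha y) - 1)^2 + H(y) b y^3 / cosh^2(c (alpha y - d log 2))`,
#' where `H` is the Heaviside step function, so the barrier term (which
#' models the entropic/solvent cost of re-closing a flipped-out base) acts
#' only for `y > 0`. At the threshold we take `H(0) = 1`; the choice is
#' immaterial because `y^3` vanishes there.
#'
#' @param y Stretching (angstrom); vectorized.
#' @param pair `"AT"` or `"GC"`.
#' @param params A [pbd_params()] object.
#' @return Energy in eV, same length as `y`.
#' @examples
#' onsite_potential(0, "AT")          # 0 at equilibrium
#' onsite_potential(30, "AT")         # ~ Morse depth D_AT
#' @export
onsite_potential <- function(y, pair, params = pbd_params()) {
  if (!pair %in% c("AT", "GC")) {
    stop(sprintf("unknown base-pair type '%s' (must be AT or GC)", pair))
  }
  D <- params[[paste0("D_", pair)]]
  alpha <- params[[paste0("alpha_", pair)]]
  b <- params[[paste0("b_", pair)]]
  cc <- params[[paste0("c_", pair)]]
  d <- params[[paste0("d_", pair)]]
  morse <- D * (exp(-alpha * y) - 1)^2
  barrier <- ifelse(y >= 0, b * y^3 / cosh(cc * (alpha * y - d * log(2)))^2, 0)
  morse + barrier
}

#' Stacking potential between adjacent base pairs
#'
#' `W(y_i, y_prev) = K/2 (1 + rho exp(-delta (y_i + y_prev))) (y_i - y_prev)^2`
#' with the dimer-specific strength `K`. The effective stiffness is
#' `K (1 + rho)` when both pairs are closed and relaxes to `K` when either
#' opens; this anharmonicity produces the sharp denaturation transition.
#'
#' @param y_i,y_prev Stretchings of base pairs `i` and `i - 1` (angstrom);
#'   vectorized.
#' @param dimer Ordered dimer key, 5'->3' on the given strand (base at
#'   `i - 1` followed by base at `i`), e.g. `"AA"`, `"CG"`.
#' @param params A [pbd_params()] object.
#' @return Energy in eV.
#' @examples
#' stacking_potential(1, 0, "AA")
#' @export
stacking_potential <- function(y_i, y_prev, dimer, params = pbd_params()) {
  if (length(dimer) != 1L || !dimer %in% names(params$K_dimer)) {
    stop(sprintf("unknown dimer '%s'", paste(dimer, collapse = "")))
  }
  K <- params$K_dimer[[dimer]]
  0.5 * K * (1 + params$rho * exp(-params$delta * (y_i + y_prev))) * (y_i - y_prev)^2
}
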
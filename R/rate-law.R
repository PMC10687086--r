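#' Quasi-steady-state rate of the luciferase reaction
#'
#' Evaluates the closed-form rate law for a Michaelis-Menten mechanism with
#' competitive product inhibition (enzyme-product complex, dissociation
#' constant `K_p`) and uncompetitive, dead-end substrate inhibition
#' (enzyme-substrate-substrate complex, dissociation constant `K_s`):
#'
#' \deqn{v = \frac{k_{cat} E_0 S}{K_m (1 + P/K_p) + S (1 + S/K_s)}}
#'
#' With `K_p = K_s = Inf` this reduces exactly to plain Michaelis-Menten
#' kinetics.
#'
#' @param params A [kinetic_params()] object.
#' @param S Free substrate concentration, uM (vectorised).
#' @param P Free product concentration, uM (vectorised).
#' @param E0 Total enzyme concentration, uM.
#' @return Reaction rate v in uM/s, same length as `S`/`P`.
#' @examples
#' p <- kinetic_params(k_cat = 2.48, K_m = 0.57)
#' rate_qssa(p, S = 1, P = 0, E0 = 0.01)
#' @export
rate_qssa <- function(params, S, P = 0, E0) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(S < 0) || any(P < 0) || any(E0 < 0)) {
    abort("Concentrations `S`, `P`, `E0` must be nonnegative.")
  }
  n <- max(length(S), length(P))
  S <- rep_len(S, n); P <- rep_len(P, n)
  inv_kp <- if (is.finite(params$K_p)) 1 / params$K_p else 0
  inv_ks <- if (is.finite(params$K_s)) 1 / params$K_s else 0
  denom <- params$K_m * (1 + P * inv_kp) + S * (1 + S * inv_ks)
  v <- params$k_cat * E0 * S / denom
  v[S == 0] <- 0
  v
}

#' Microscopic rate constants consistent with macroscopic kinetics
#'
#' Bridges the macroscopic constants (`k_cat`, `K_m`, `K_p`, `K_s`) to a
#' mass-action network with one shared association rate `k1` for every binding
#' step. The ES dissociation rate follows from the steady-state Michaelis
#' constant, `k_off = k1 * K_m - k_cat`, which requires `k1 > k_cat / K_m`.
#' The EP and ESS complexes are treated as rapid equilibria with on-rate `k1`
#' and off-rates `k1 * K_p` and `k1 * K_s`; infinite dissociation constants
#' switch the complex off entirely (zero on-rate).
#'
#' @param params A [kinetic_params()] object.
#' @param k1 Association rate for all binding steps, 1/uM/s.
#' @return An object of class `micro_rates`: `k1`, `k_off`, `k_cat`, `k_on_p`,
#'   `k_off_p`, `k_on_s`, `k_off_s`.
#' @examples
#' derive_micro_rates(kinetic_params(2.48, 0.57), k1 = 100)
#' @export
derive_micro_rates <- function(params, k1 = 100) {
  stopifnot(inherits(params, "kinetic_params"))
  k1_min <- params$k_cat / params$K_m
  if (k1 <= k1_min) {
    abort(sprintf(
      "k1 = %g 1/uM/s is infeasible: need k1 > k_cat/K_m = %g 1/uM/s so that k_off > 0.",
      k1, k1_min))
  }
  k_off <- k1 * params$K_m - params$k_cat
  has_p <- is.finite(params$K_p)
  has_s <- is.finite(params$K_s)
  structure(list(
    k1 = k1, k_off = k_off, k_cat = params$k_cat,
    k_on_p = if (has_p) k1 else 0,
    k_off_p = if (has_p) k1 * params$K_p else 0,
    k_on_s = if (has_s) k1 else 0,
    k_off_s = if (has_s) k1 * params$K_s else 0
  ), class = "micro_rates")
}

#' Recover macroscopic constants from a micro-rate set
#'
#' Inverse of [derive_micro_rates()]; used for round-trip checks.
#'
#' @param rates A `micro_rates` object.
#' @return A [kinetic_params()] object.
#' @export
macro_from_micro <- function(rates) {
  stopifnot(inherits(rates, "micro_rates"))
  kinetic_params(
    k_cat = rates$k_cat,
    K_m = (rates$k_off + rates$k_cat) / rates$k1,
    K_p = if (rates$k_on_p > 0) rates$k_off_p / rates$k_on_p else Inf,
    K_s = if (rates$k_on_s > 0) rates$k_off_s / rates$k_on_s else Inf
  )
}
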
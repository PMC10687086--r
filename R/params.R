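#' Kinetic parameter set for one enzyme-luciferin pair
#'
#' Bundles the macroscopic constants of the luciferase reaction: the turnover
#' number `k_cat`, the Michaelis constant `K_m`, the dissociation constant of
#' the enzyme-product complex `K_p` (finite values produce competitive product
#' inhibition and flash-like luminescence decay) and the dissociation constant
#' of the dead-end enzyme-substrate-substrate complex `K_s` (finite values
#' produce substrate inhibition at high substrate). `K_p` and `K_s` may be
#' `Inf`, meaning the corresponding complex does not form.
#'
#' Units are fixed package-wide: concentrations in uM, time in seconds.
#'
#' @param k_cat Turnover number, 1/s. Strictly positive.
#' @param K_m Michaelis constant, uM. Strictly positive.
#' @param K_p Enzyme-product dissociation constant, uM; `Inf` disables product
#'   inhibition.
#' @param K_s Enzyme-substrate-substrate dissociation constant, uM; `Inf`
#'   disables substrate inhibition.
#' @return An object of class `kinetic_params` (named list).
#' @examples
#' kinetic_params(k_cat = 2.48, K_m = 0.57, K_p = 0.256)
#' @export
kinetic_params <- function(k_cat, K_m, K_p = Inf, K_s = Inf) {
  for (nm in c("k_cat", "K_m", "K_p", "K_s")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      abort(sprintf("`%s` must be a single non-missing number.", nm))
    }
  }
  if (k_cat <= 0 || K_m <= 0) abort("`k_cat` and `K_m` must be strictly positive.")
  if (!is.finite(k_cat) || !is.finite(K_m)) abort("`k_cat` and `K_m` must be finite.")
  if (K_p <= 0 || K_s <= 0) abort("`K_p` and `K_s` must be positive (Inf allowed).")
  structure(list(k_cat = k_cat, K_m = K_m, K_p = K_p, K_s = K_s),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params>  k_cat = %g /s, K_m = %g uM, K_p = %g uM, K_s = %g uM\n",
    x$k_cat, x$K_m, x$K_p, x$K_s))
  invisible(x)
}

#' Reaction scheme selector
#'
#' Chooses which inhibition terms enter the rate law or mass-action network.
#' `mm_basic` is plain Michaelis-Menten; `mm_prod_inhib` adds competitive
#' product inhibition (requires finite `K_p`); `mm_prod_subs_inhib` adds the
#' dead-end ESS complex as well (requires finite `K_s`); `mass_action` requests
#' full mass-action integration of the same network.
#'
#' @param scheme_id One of `"mm_basic"`, `"mm_prod_inhib"`,
#'   `"mm_prod_subs_inhib"`, `"mass_action"`.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(scheme_id = c("mm_prod_inhib", "mm_basic",
                                         "mm_prod_subs_inhib", "mass_action")) {
  scheme_id <- match.arg(scheme_id)
  structure(list(
    scheme_id = scheme_id,
    dead_end_ESS = scheme_id == "mm_prod_subs_inhib",
    competitive_EP = scheme_id %in% c("mm_prod_inhib", "mm_prod_subs_inhib",
                                      "mass_action")
  ), class = "kinetic_scheme")
}

check_scheme_params <- function(scheme, params) {
  if (scheme$scheme_id == "mm_prod_subs_inhib" && !is.finite(params$K_s)) {
    abort("Scheme `mm_prod_subs_inhib` requires a finite K_s.")
  }
  if (scheme$scheme_id == "mm_prod_inhib" && !is.finite(params$K_p)) {
    abort("Scheme `mm_prod_inhib` requires a finite K_p.")
  }
  invisible(TRUE)
}

#' Assay conditions for one injection experiment
#'
#' Describes a FLUOStar-style injection assay: a pre-injection baseline,
#' injection at time zero, then sampling at a fixed read interval until the
#' stop criterion or the hard time cap.
#'
#' @param E0 Total enzyme concentration, uM (>= 0).
#' @param S0 Initial substrate (luciferin) concentration, uM (> 0).
#' @param baseline_s Pre-injection baseline duration, s.
#' @param read_interval_s Sampling period, s.
#' @param max_duration_s Hard cap on post-injection monitoring, s.
#' @param temperature_label Metadata only; the assays are run at 37 C.
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(E0, S0, baseline_s = 10, read_interval_s = 0.5,
                             max_duration_s = 1000, temperature_label = "37C") {
  if (!is.numeric(E0) || E0 < 0) abort("`E0` must be >= 0.")
  if (!is.numeric(S0) || S0 <= 0) abort("`S0` must be > 0.")
  if (read_interval_s <= 0) abort("`read_interval_s` must be > 0.")
  if (max_duration_s < baseline_s) abort("`max_duration_s` must be >= `baseline_s`.")
  structure(list(E0 = E0, S0 = S0, baseline_s = baseline_s,
                 read_interval_s = read_interval_s,
                 max_duration_s = max_duration_s,
                 temperature_label = temperature_label),
            class = "assay_conditions")
}

#' Published steady-state kinetic constants of NanoLuc variants
#'
#' Reference table of the macroscopic kinetic constants (mean +/- s.d., n = 3)
#' for the NanoLuc wild type and three allosteric-site mutants with the two
#' imidazopyrazinone luciferins coelenterazine (CTZ) and furimazine (FMZ):
#' K_m (uM), k_cat (1/s), K_p (uM), and the specificity constant k_cat/K_m
#' (1/s/uM) as printed, with their standard errors. These serve as generator
#' truths for synthetic studies and as inputs for derived-quantity checks.
#'
#' Note the triple-mutant CTZ row is internally inconsistent as printed
#' (k_cat / K_m = 40 / 0.77 = 51.9, yet 70 +/- 7 is printed);
#' [specificity_table()] flags this computationally.
#'
#' @return A tibble with one row per variant-luciferin pair: `variant`,
#'   `luciferin`, `K_m`, `K_m_se`, `k_cat`, `k_cat_se`, `K_p`, `K_p_se`,
#'   `kcat_over_Km`, `kcat_over_Km_se`.
#' @examples
#' nanoluc_params()
#' @export
nanoluc_params <- function() {
  tibble(
    variant = rep(c("WT", "Y94A", "D9R/K89R", "D9R/H57A/K89R"), times = 2),
    luciferin = rep(c("CTZ", "FMZ"), each = 4),
    K_m       = c(0.57, 3.74, 0.46, 0.77,      0.123, 1.29, 0.157, 0.098),
    K_m_se    = c(0.02, 0.09, 0.01, 0.07,      0.004, 0.02, 0.009, 0.005),
    k_cat     = c(2.48, 0.225, 16.8, 40,       7.88, 0.519, 5.2, 2.74),
    k_cat_se  = c(0.05, 0.004, 0.6, 4,         0.03, 0.007, 0.1, 0.03),
    K_p       = c(0.256, 0.79, 0.163, 0.23,    0.56, 0.85, 0.39, 0.34),
    K_p_se    = c(0.005, 0.04, 0.006, 0.02,    0.01, 0.02, 0.03, 0.02),
    kcat_over_Km    = c(4.4, 0.060, 37, 70,    64, 0.402, 33, 28),
    kcat_over_Km_se = c(0.2, 0.001, 1, 7,      2, 0.006, 2, 1)
  )
}

#' Turn one reference-table row into a `kinetic_params` object
#'
#' @param variant,luciferin Row selector matching [nanoluc_params()].
#' @param K_s Substrate-inhibition constant to attach (the reference table does
#'   not constrain it); default `Inf`.
#' @return A `kinetic_params` object.
#' @export
nanoluc_kinetic_params <- function(variant, luciferin, K_s = Inf) {
  tbl <- nanoluc_params()
  row <- tbl[tbl$variant == variant & tbl$luciferin == luciferin, ]
  if (nrow(row) != 1L) {
    abort(sprintf("No reference row for variant '%s' with luciferin '%s'.",
                  variant, luciferin))
  }
  kinetic_params(k_cat = row$k_cat, K_m = row$K_m, K_p = row$K_p, K_s = K_s)
}
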
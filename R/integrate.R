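#' Integrate a full product-formation progress curve (QSSA model)
#'
#' Solves \eqn{dP/dt = v(S_0 - P, P)} with the quasi-steady-state rate law of
#' [rate_qssa()], from injection (t = 0, P = 0) over the post-injection read
#' grid of the assay. Uses a stiff-capable solver (lsoda) with a compiled
#' right-hand side; output is evaluated exactly at the requested read times.
#'
#' @param params A [kinetic_params()] object.
#' @param cond An [assay_conditions()] object; `E0`, `S0`, `read_interval_s`
#'   and `max_duration_s` define the run.
#' @param scheme A [kinetic_scheme()] object; inhibition terms not in the
#'   scheme are dropped from the rate law.
#' @param rel_tol,abs_tol Integrator tolerances (abs_tol in uM).
#' @param times Optional explicit post-injection output times, s (overrides the
#'   read grid).
#' @return A `progress_curve` tibble with columns `time_s` and `product_uM`
#'   (product is clipped to `[0, S0]`; attribute `S0`, `E0` attached).
#' @examples
#' p <- kinetic_params(2.48, 0.57, K_p = 0.256)
#' pc <- integrate_progress(p, assay_conditions(E0 = 0.01, S0 = 1))
#' tail(pc)
#' @export
integrate_progress <- function(params, cond, scheme = kinetic_scheme("mm_prod_inhib"),
                               rel_tol = 1e-8, abs_tol = 1e-10, times = NULL) {
  stopifnot(inherits(params, "kinetic_params"), inherits(cond, "assay_conditions"),
            inherits(scheme, "kinetic_scheme"))
  if (rel_tol <= 0 || abs_tol <= 0) abort("Integrator tolerances must be positive.")
  if (is.null(times)) {
    times <- seq(0, cond$max_duration_s, by = cond$read_interval_s)
  }
  if (is.unsorted(times, strictly = TRUE)) abort("`times` must be strictly increasing.")
  if (times[1] > 0) times <- c(0, times)

  inv_kp <- if (scheme$competitive_EP && is.finite(params$K_p)) 1 / params$K_p else 0
  inv_ks <- if (scheme$dead_end_ESS && is.finite(params$K_s)) 1 / params$K_s else 0
  if (scheme$scheme_id == "mm_basic") inv_kp <- inv_ks <- 0
  parms <- c(params$k_cat, params$K_m, inv_kp, inv_ks, cond$E0, cond$S0)

  if (cond$E0 == 0) {
    out <- tibble(time_s = times, product_uM = 0)
  } else {
    sol <- deSolve::lsoda(
      y = 0, times = times, func = "lucifit_deriv_qssa", parms = parms,
      dllname = "lucifit", initfunc = "lucifit_init_qssa",
      rtol = rel_tol, atol = abs_tol)
    check_integration(sol, times, "QSSA progress model")
    out <- tibble(time_s = sol[, 1], product_uM = pmin(pmax(sol[, 2], 0), cond$S0))
  }
  new_progress_curve(out, S0 = cond$S0, E0 = cond$E0)
}

new_progress_curve <- function(df, S0, E0, species = NULL) {
  structure(df, class = c("progress_curve", class(df)), S0 = S0, E0 = E0,
            species = species)
}

check_integration <- function(sol, times, what) {
  istate <- attr(sol, "istate")
  bad <- !is.null(istate) && istate[1] < 0
  if (bad || nrow(sol) < length(times) || anyNA(sol)) {
    reached <- if (nrow(sol) > 0) max(sol[stats::complete.cases(sol), 1], -Inf) else -Inf
    abort(sprintf(
      "%s: integration failed near t = %.4g s (requested horizon %.4g s); the segment there is too stiff for the given tolerances.",
      what, reached, max(times)))
  }
  invisible(TRUE)
}

#' Full mass-action simulation of the luciferase network
#'
#' Integrates the mass-action network E + S <-> ES -> E + P with optional
#' product rebinding E + P <-> EP and dead-end ES + S <-> ESS, using the
#' microscopic rates from [derive_micro_rates()]. All six species are
#' integrated independently; conservation of enzyme
#' (E + ES + ESS + EP = E0) and substrate (S + ES + 2 ESS + EP + P = S0)
#' is verified on the output at 1e-6 relative tolerance.
#'
#' The `product_uM` column reports total turned-over product (free P plus
#' enzyme-bound EP), the quantity the luminescence transform integrates to;
#' free P and EP are available in the species columns.
#'
#' @param rates A `micro_rates` object (or explicit list with the same fields).
#' @param cond An [assay_conditions()] object.
#' @inheritParams integrate_progress
#' @return A `progress_curve` tibble with `time_s`, `product_uM` and species
#'   columns `E`, `S`, `ES`, `ESS`, `EP`, `P` (uM).
#' @export
simulate_mass_action <- function(rates, cond, rel_tol = 1e-8, abs_tol = 1e-10,
                                 times = NULL) {
  stopifnot(inherits(cond, "assay_conditions"))
  r <- unclass(rates)
  needed <- c("k1", "k_off", "k_cat", "k_on_p", "k_off_p", "k_on_s", "k_off_s")
  if (!all(needed %in% names(r))) {
    abort(sprintf("`rates` must supply fields: %s", paste(needed, collapse = ", ")))
  }
  if (any(unlist(r[needed]) < 0)) abort("All microscopic rates must be nonnegative.")
  if (is.null(times)) times <- seq(0, cond$max_duration_s, by = cond$read_interval_s)
  if (times[1] > 0) times <- c(0, times)

  y0 <- c(E = cond$E0, S = cond$S0, ES = 0, ESS = 0, EP = 0, P = 0)
  sol <- deSolve::lsoda(
    y = y0, times = times, func = "lucifit_deriv_ma",
    parms = unlist(r[needed]), dllname = "lucifit", initfunc = "lucifit_init_ma",
    rtol = rel_tol, atol = abs_tol)
  check_integration(sol, times, "mass-action network")

  sp <- as_tibble(as.data.frame(sol))
  names(sp) <- c("time_s", "E", "S", "ES", "ESS", "EP", "P")

  enz <- sp$E + sp$ES + sp$ESS + sp$EP
  sub <- sp$S + sp$ES + 2 * sp$ESS + sp$EP + sp$P
  tol_e <- 1e-6 * max(cond$E0, abs_tol)
  tol_s <- 1e-6 * max(cond$S0, abs_tol)
  if (max(abs(enz - cond$E0)) > tol_e || max(abs(sub - cond$S0)) > tol_s) {
    abort(sprintf(
      "Mass conservation violated beyond 1e-6 relative (enzyme drift %.3g uM, substrate drift %.3g uM); tighten integrator tolerances.",
      max(abs(enz - cond$E0)), max(abs(sub - cond$S0))))
  }

  out <- tibble(time_s = sp$time_s, product_uM = pmin(pmax(sp$P + sp$EP, 0), cond$S0))
  out <- dplyr::bind_cols(out, sp[, c("E", "S", "ES", "ESS", "EP", "P")])
  new_progress_curve(out, S0 = cond$S0, E0 = cond$E0,
                     species = c("E", "S", "ES", "ESS", "EP", "P"))
}
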
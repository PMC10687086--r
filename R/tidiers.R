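#' Tidy a global fit into one row per parameter
#'
#' @param x A `lucifit_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `se` (kinetic constants plus the
#'   scaling factor).
#' @export
tidy.lucifit_fit <- function(x, ...) {
  bind_rows(
    x$estimates,
    tibble(term = "scaling_f", estimate = x$scaling_f, se = x$scaling_f_se))
}

#' One-row fit summary
#'
#' @param x A `lucifit_fit`.
#' @param ... Unused.
#' @return Tibble: `chi2`, `reduced_chi2`, `n_points`, `n_params`,
#'   `converged`, `scheme`.
#' @export
glance.lucifit_fit <- function(x, ...) {
  tibble(chi2 = x$chi2,
         reduced_chi2 = x$chi2 / max(x$n_points - x$n_params, 1),
         n_points = x$n_points, n_params = x$n_params,
         converged = x$converged, scheme = x$scheme$scheme_id)
}

#' Observed and fitted conversion curves
#'
#' @param x A `lucifit_fit`.
#' @param ... Unused.
#' @return The fit data plus `fitted` and `resid_norm` (sigma-normalized
#'   residual) columns.
#' @export
augment.lucifit_fit <- function(x, ...) {
  fd <- build_fit_data(x$data, x$E0)
  # evaluate both observables so fitted cumulative curves are always shown
  resid_cum <- make_resid_fun(fd, x$scheme, x$layout, x$conc_correction,
                              observable = "cumulative",
                              fixed_f = x$scaling_f_fixed)
  resid_fit <- make_resid_fun(fd, x$scheme, x$layout, x$conc_correction,
                              observable = x$observable,
                              fixed_f = x$scaling_f_fixed)
  r_cum <- resid_cum(x$par)[seq_len(nrow(x$data))]
  r_fit <- resid_fit(x$par)[seq_len(nrow(x$data))]
  # residuals are emitted level-by-level (ascending S0), well-by-well,
  # time-ordered within well: reproduce that ordering on the data rows
  ord <- order(match(x$data$S0_uM, fd$S0_levels), x$data$well, x$data$time_s)
  out <- x$data[ord, ]
  out$resid_norm <- r_fit
  out$fitted <- out$cumulative_rlu_s - r_cum * out$sigma_rlu_s
  out[order(ord), ]
}

#' Tidy a contour map
#'
#' @param x A `lucifit_contours`.
#' @param ... Unused.
#' @return The grid tibble (`x`, `y`, `chi2`, `inside`).
#' @export
tidy.lucifit_contours <- function(x, ...) x$grid

#' Tidy an initial-rate fit
#'
#' @param x A `lucifit_mm_fit`.
#' @param ... Unused.
#' @export
tidy.lucifit_mm_fit <- function(x, ...) x$estimates
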
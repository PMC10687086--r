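#' Specificity constant with propagated uncertainty
#'
#' Computes k_cat/K_m (the second-order rate constant for reaction at low
#' substrate) with first-order (delta-method) error propagation assuming
#' independent inputs:
#' \eqn{se = (k_{cat}/K_m) \sqrt{(se_{kcat}/k_{cat})^2 + (se_{Km}/K_m)^2}}.
#'
#' @param k_cat Turnover number, 1/s.
#' @param K_m Michaelis constant, uM (> 0).
#' @param k_cat_se,K_m_se Standard errors (default 0).
#' @return One-row tibble: `name`, `value` (1/s/uM), `se`.
#' @examples
#' specificity_constant(2.48, 0.57, 0.05, 0.02)
#' @export
specificity_constant <- function(k_cat, K_m, k_cat_se = 0, K_m_se = 0) {
  if (any(K_m <= 0)) abort("`K_m` must be > 0.")
  value <- k_cat / K_m
  se <- value * sqrt((k_cat_se / k_cat)^2 + (K_m_se / K_m)^2)
  tibble(name = "specificity_constant", value = value, se = se)
}

#' Fold change between a variant and a reference quantity
#'
#' Ratio of two measured quantities with independent first-order error
#' propagation.
#'
#' @param value,se Variant estimate and its standard error.
#' @param ref_value,ref_se Reference estimate and its standard error.
#' @return One-row tibble: `name`, `value` (fold), `se`.
#' @examples
#' fold_change(70, 7, 4.4, 0.2)   # catalytic-efficiency fold of the triple mutant
#' @export
fold_change <- function(value, se = 0, ref_value, ref_se = 0) {
  if (any(ref_value <= 0)) abort("Reference value must be > 0.")
  fc <- value / ref_value
  fc_se <- fc * sqrt((se / value)^2 + (ref_se / ref_value)^2)
  tibble(name = "fold_change", value = fc, se = fc_se)
}

#' Internal-consistency check of a kinetic constants table
#'
#' Recomputes the specificity constant from each row's (k_cat, K_m) pair,
#' propagates its standard error, and compares it with the printed
#' k_cat/K_m value: a row is consistent when the recomputed ratio falls within
#' the printed value's own uncertainty. For the published NanoLuc table this
#' flags exactly one row (the triple mutant with CTZ, where 40/0.77 = 51.9
#' cannot reproduce the printed 70 +/- 7).
#'
#' @param table Tibble in the shape of [nanoluc_params()] (default).
#' @return The table plus `computed_ratio`, `computed_ratio_se`, `consistent`.
#' @export
specificity_table <- function(table = nanoluc_params()) {
  sc <- specificity_constant(table$k_cat, table$K_m, table$k_cat_se, table$K_m_se)
  mutate(table,
         computed_ratio = sc$value,
         computed_ratio_se = sc$se,
         consistent = abs(.data$computed_ratio - .data$kcat_over_Km) <=
           .data$kcat_over_Km_se)
}

# ---- confidence contours --------------------------------------------------

# Grid engine shared by the kinetic and toy uses: for each (x, y) node, fix
# par[ix], par[iy] and re-optimize all remaining parameters, recording the
# resulting chi2. Nodes where re-optimization fails are NA-flagged.
contour_grid_engine <- function(resid_fn, par, lower, upper, ix, iy,
                                xvals, yvals) {
  free <- setdiff(seq_along(par), c(ix, iy))
  chi2 <- matrix(NA_real_, length(xvals), length(yvals))
  warm <- par
  for (i in seq_along(xvals)) {
    par_i <- warm   # warm-start each column from the previous column's start
    for (j in seq_along(yvals)) {
      p0 <- par_i
      p0[ix] <- xvals[i]
      p0[iy] <- yvals[j]
      if (length(free) == 0) {
        chi2[i, j] <- sum(resid_fn(p0)^2)
        next
      }
      sub_fn <- function(q) {
        p <- p0
        p[free] <- q
        resid_fn(p)
      }
      fit <- tryCatch(
        minpack.lm::nls.lm(par = p0[free], fn = sub_fn,
                           lower = lower[free], upper = upper[free],
                           control = minpack.lm::nls.lm.control(maxiter = 80)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        chi2[i, j] <- fit$deviance
        p0[free] <- fit$par
        if (j == 1) par_i <- p0
      }
    }
  }
  chi2
}

# Profile-region threshold for a q-dimensional parameter subset (q = 2 for a
# contour pair), with p total fitted parameters: the q/(n-p) F(q, n-p) rule
# gives calibrated coverage for the pair; substituting p for q yields the
# conservative all-parameter joint region.
fitspace_threshold <- function(chi2_min, p, n, conf = 0.95, q = 2) {
  chi2_min * (1 + q / (n - p) * qf(conf, q, n - p))
}

#' Profile-likelihood confidence contours over a parameter pair
#'
#' For each node of a log-spaced grid over two kinetic parameters, the pair is
#' held fixed and every remaining fitted quantity (other kinetic constants,
#' the scaling factor, concentration corrections) is re-optimized; the
#' resulting chi-squared surface delimits the jointly acceptable region. The
#' boundary follows the F-statistic rule for a two-parameter profile region,
#' \eqn{\chi^2_{min} (1 + 2/(n-p) F_{0.95}(2, n-p))} with p the total number
#' of fitted quantities, which gives calibrated ~95% coverage of the pair;
#' the all-parameter variant \eqn{F(p, n-p)} used for joint regions over
#' every fitted quantity is more conservative.
#'
#' @param fit A converged [fit_global()] result.
#' @param pair Character vector of two fitted kinetic parameter names, e.g.
#'   `c("k_cat", "K_m")`.
#' @param grid_n Nodes per axis (default 25).
#' @param span Grid spans `estimate / span` to `estimate * span` per axis,
#'   log-spaced (default 10).
#' @param conf Confidence level for the boundary (default 0.95).
#' @return A `lucifit_contours` object: `grid` tibble (`x`, `y`, `chi2`,
#'   `inside`), `pair`, `threshold`, `chi2_min`, `estimate`.
#' @export
confidence_contours <- function(fit, pair = c("k_cat", "K_m"), grid_n = 25,
                                span = 10, conf = 0.95) {
  stopifnot(inherits(fit, "lucifit_fit"))
  if (!fit$converged) abort("Contour analysis requires a converged fit.")
  idx <- match(pair, fit$layout$name)
  if (anyNA(idx)) abort(sprintf("Pair must be among fitted parameters: %s",
                                paste(fit$layout$name, collapse = ", ")))
  fd <- build_fit_data(fit$data, fit$E0)
  resid <- make_resid_fun(fd, fit$scheme, fit$layout, fit$conc_correction,
                          observable = fit$observable,
                          fixed_f = fit$scaling_f_fixed)
  est <- fit$par[idx]
  xvals <- seq(est[1] - log(span), est[1] + log(span), length.out = grid_n)
  yvals <- seq(est[2] - log(span), est[2] + log(span), length.out = grid_n)

  chi2 <- contour_grid_engine(resid, fit$par, fit$bounds$lower, fit$bounds$upper,
                              idx[1], idx[2], xvals, yvals)
  thr <- fitspace_threshold(fit$chi2_total, fit$n_params, fit$n_points, conf)
  grid <- tidyr::expand_grid(i = seq_along(xvals), j = seq_along(yvals)) |>
    mutate(x = exp(xvals[.data$i]), y = exp(yvals[.data$j]),
           chi2 = chi2[cbind(.data$i, .data$j)],
           inside = !is.na(.data$chi2) & .data$chi2 <= thr) |>
    select("x", "y", "chi2", "inside")
  structure(list(grid = grid, pair = pair, threshold = thr,
                 chi2_min = fit$chi2_total, conf = conf,
                 estimate = setNames(exp(est), pair)),
            class = "lucifit_contours")
}

#' Is a parameter pair inside the joint confidence region?
#'
#' Single-node version of [confidence_contours()]: fixes the pair at the
#' given values, re-optimizes every other fitted quantity, and compares the
#' profiled chi-squared with the F-rule threshold. Used for coverage studies
#' without building a full grid.
#'
#' @inheritParams confidence_contours
#' @param values Numeric length-2: the (natural-scale) parameter values to
#'   test, in the order of `pair`.
#' @return One-row tibble: `chi2_profile`, `threshold`, `inside`.
#' @export
contour_contains <- function(fit, pair, values, conf = 0.95) {
  stopifnot(inherits(fit, "lucifit_fit"), length(values) == 2)
  idx <- match(pair, fit$layout$name)
  if (anyNA(idx)) abort("Unknown parameter in `pair`.")
  fd <- build_fit_data(fit$data, fit$E0)
  resid <- make_resid_fun(fd, fit$scheme, fit$layout, fit$conc_correction,
                          observable = fit$observable,
                          fixed_f = fit$scaling_f_fixed)
  chi2 <- contour_grid_engine(resid, fit$par, fit$bounds$lower, fit$bounds$upper,
                              idx[1], idx[2], log(values[1]), log(values[2]))[1, 1]
  thr <- fitspace_threshold(fit$chi2_total, fit$n_params, fit$n_points, conf)
  tibble(chi2_profile = chi2, threshold = thr,
         inside = is.finite(chi2) & chi2 <= thr)
}

#' @export
print.lucifit_contours <- function(x, ...) {
  cat(sprintf("<lucifit_contours> %s vs %s, %d nodes, %.0f%% threshold chi2 = %.4g (min %.4g)\n",
              x$pair[1], x$pair[2], nrow(x$grid), 100 * x$conf, x$threshold,
              x$chi2_min))
  invisible(x)
}
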
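#' Initial reaction velocity from a conversion curve
#'
#' The initial velocity is estimated as the least-squares slope of the
#' cumulative signal over the first `window_s` seconds after injection
#' (through the origin-free linear model `cumulative ~ time`). Integrating the
#' signal before taking a slope averages read noise, which is why the slope of
#' the conversion curve is preferred over the first intensity read.
#'
#' @param curve Conversion curve tibble ([cumulative_luminescence()]), in RLU.s
#'   (relative) or uM (calibrated).
#' @param window_s Fit window, s (default 15, the initial-rate monitoring
#'   span); must be positive and covered by the curve.
#' @return One-row tibble: `v0` (slope, signal units per s), `se_v0`,
#'   `n_points`, `window_s`.
#' @export
initial_velocity <- function(curve, window_s = 15) {
  if (window_s <= 0) abort("`window_s` must be > 0.")
  if (max(curve$time_s) < window_s) {
    abort(sprintf("Curve covers only %.3g s; the %g s window is not covered.",
                  max(curve$time_s), window_s))
  }
  sel <- curve$time_s <= window_s
  y <- curve[["cumulative_uM"]] %||% curve[["cumulative_rlu_s"]]
  fit <- lm(y[sel] ~ curve$time_s[sel])
  est <- coef(fit)[2]
  # suppressed: "essentially perfect fit" on noise-free linear curves
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[2])
  tibble(v0 = unname(est), se_v0 = unname(se), n_points = sum(sel),
         window_s = window_s)
}

#' Fit initial velocities to Michaelis-Menten with substrate inhibition
#'
#' Weighted nonlinear least squares of
#' \deqn{v_0 = V_{max} S / (K_m + S + S^2/K_s)}
#' to an initial-velocity series. With `substrate_inhibition = FALSE` the
#' `S^2/K_s` term is dropped. Weights are `1/se_v0^2` when standard errors are
#' available, else unweighted. Fitting is multi-start around heuristic
#' initials (`K_m` from the half-Vmax crossing, `Vmax` from `1.2 * max(v0)`,
#' `K_s` from `10 * max(S0)`), in log space to enforce positivity.
#'
#' When the fitted `K_s` runs beyond `100 * max(S0)` the substrate-inhibition
#' term is declared undetectable (`Ks_detectable = FALSE`) and its estimate
#' should not be interpreted.
#'
#' @param points Tibble with columns `S0` (uM), `v0`, optional `se_v0`.
#' @param substrate_inhibition Include the `S^2/K_s` term?
#' @param n_starts Number of multi-start perturbations (default 5).
#' @param seed Seed for start perturbations.
#' @return Object of class `lucifit_mm_fit`: list with `estimates` tibble
#'   (`term`, `estimate`, `se`), `Ks_detectable`, `converged`, `rss`,
#'   `n_points`, and the underlying `nls` fit.
#' @export
fit_initial_rates <- function(points, substrate_inhibition = TRUE,
                              n_starts = 5, seed = 1L) {
  points <- as_tibble(points)
  if (!all(c("S0", "v0") %in% names(points))) {
    abort("`points` needs columns `S0` and `v0`.")
  }
  if (length(unique(points$S0)) < 3 + substrate_inhibition) {
    abort("Need at least 3 (4 with substrate inhibition) distinct S0 values.")
  }
  se_col <- points[["se_v0"]]
  w <- if (!is.null(se_col) && all(is.finite(se_col)) && all(se_col > 0)) {
    1 / se_col^2
  } else {
    rep(1, nrow(points))
  }

  vmax0 <- 1.2 * max(points$v0)
  km0 <- {
    half <- points$S0[which.min(abs(points$v0 - max(points$v0) / 2))]
    max(half, 1e-6)
  }
  ks0 <- 10 * max(points$S0)

  fml <- if (substrate_inhibition) {
    v0 ~ exp(lVmax) * S0 / (exp(lKm) + S0 + S0^2 / exp(lKs))
  } else {
    v0 ~ exp(lVmax) * S0 / (exp(lKm) + S0)
  }
  base_start <- c(lVmax = log(vmax0), lKm = log(km0),
                  if (substrate_inhibition) c(lKs = log(ks0)))

  starts <- with_seed(seed, {
    c(list(base_start),
      purrr::map(seq_len(max(0, n_starts - 1)), function(i) {
        base_start + runif(length(base_start), -log(3), log(3))
      }))
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = points, start = as.list(st), weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("Initial-rate fit failed to converge from all starts.")
  }
  fit <- best$fit
  lp <- coef(fit)
  lse <- sqrt(diag(vcov(fit)))
  est <- exp(lp)
  se <- est * lse   # delta method from log scale
  terms <- c("Vmax", "K_m", if (substrate_inhibition) "K_s")
  ks_detectable <- if (substrate_inhibition) {
    unname(est["lKs"]) < 100 * max(points$S0)
  } else NA
  structure(list(
    estimates = tibble(term = terms, estimate = unname(est), se = unname(se)),
    Ks_detectable = ks_detectable,
    converged = fit$convInfo$isConv %||% TRUE,
    rss = best$rss, n_points = nrow(points), fit = fit
  ), class = "lucifit_mm_fit")
}

#' @export
print.lucifit_mm_fit <- function(x, ...) {
  cat("<initial-rate fit>\n")
  print(x$estimates)
  if (isFALSE(x$Ks_detectable)) cat("No detectable substrate inhibition (K_s at bound).\n")
  invisible(x)
}
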
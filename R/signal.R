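#' Forward luminescence model: intensity from a progress curve
#'
#' Plate readers integrate photons over each read window, so the recorded
#' intensity is modelled as the average product-formation rate over the
#' interval, scaled by the signal factor `scaling_f` (RLU.s per uM):
#' \eqn{I_i = f (P(t_i) - P(t_{i-1})) / \Delta t_i}. Summing \eqn{I_i \Delta t_i}
#' telescopes back to \eqn{f P(t_N)} exactly, which makes this transform the
#' exact inverse of [cumulative_luminescence()].
#'
#' @param curve A `progress_curve` (from [integrate_progress()] or
#'   [simulate_mass_action()]).
#' @param scaling_f Signal scaling factor, RLU.s per uM (> 0).
#' @param read_interval_s Optional resampling interval; when it does not match
#'   the curve grid the product trajectory is linearly resampled (reported via
#'   a message).
#' @return A luminescence-trace tibble with `time_s` (read times, first read
#'   one interval after injection) and `intensity_rlu`.
#' @export
intensity_from_progress <- function(curve, scaling_f, read_interval_s = NULL) {
  if (scaling_f <= 0) abort("`scaling_f` must be > 0.")
  tt <- curve$time_s
  pp <- curve$product_uM
  if (!is.null(read_interval_s)) {
    grid <- seq(0, max(tt), by = read_interval_s)
    if (!isTRUE(all.equal(grid, tt[seq_along(grid)], tolerance = 1e-10)) ||
        length(grid) != length(tt)) {
      rlang::inform("Read interval not commensurate with curve grid; product trajectory resampled linearly.")
      pp <- approx(tt, pp, xout = grid, rule = 2)$y
      tt <- grid
    }
  }
  if (tt[1] != 0) {
    tt <- c(0, tt)
    pp <- c(0, pp)
  }
  dt <- diff(tt)
  tibble(time_s = tt[-1], intensity_rlu = scaling_f * diff(pp) / dt)
}

#' Subtract the pre-injection baseline from a raw trace
#'
#' The pre-injection segment defines the background as its median; the
#' background is subtracted from all reads, negative post-subtraction
#' intensities are clipped at zero (count reported via a message), baseline
#' reads are dropped and times are re-referenced so injection is t = 0.
#'
#' @param trace Raw trace tibble with `time_s`, `intensity_rlu` and optionally
#'   `sigma_rlu`; injection time taken from the `injection_time_s` attribute or
#'   the `injection_s` argument.
#' @param injection_s Injection time on the trace clock, s.
#' @return Trimmed trace tibble (attributes `background_rlu`, `n_clipped`).
#' @export
trim_baseline <- function(trace, injection_s = attr(trace, "injection_time_s")) {
  if (is.null(injection_s)) abort("Injection time unknown: supply `injection_s`.")
  pre <- trace$time_s <= injection_s
  background <- if (any(pre)) median(trace$intensity_rlu[pre]) else 0
  out <- trace[!pre, , drop = FALSE]
  out$time_s <- out$time_s - injection_s
  corr <- out$intensity_rlu - background
  n_clipped <- sum(corr < 0)
  if (n_clipped > 0) {
    rlang::inform(sprintf("Clipped %d negative background-subtracted reads to 0.", n_clipped))
  }
  out$intensity_rlu <- pmax(corr, 0)
  out <- as_tibble(out)
  n_pre <- sum(pre)
  bg_se <- if (n_pre >= 2) {
    # SE of the sample median under approximate normality
    1.2533 * stats::sd(trace$intensity_rlu[pre]) / sqrt(n_pre)
  } else 0
  attr(out, "background_rlu") <- background
  attr(out, "background_se_rlu") <- bg_se
  attr(out, "n_clipped") <- n_clipped
  attr(out, "injection_time_s") <- 0
  out
}

#' Cumulative luminescence (conversion curve) from an intensity trace
#'
#' Transforms a baseline-trimmed intensity trace into cumulative luminescence
#' over time, the observable that is proportional to product concentration via
#' the scaling factor and that eliminates the need for absolute photon-yield
#' calibration. Accumulation is rectangle-wise over each read interval
#' (\eqn{C_i = \sum_{j \le i} I_j \Delta t_j}, \eqn{t_0 = 0}), the exact
#' inverse of [intensity_from_progress()].
#'
#' When a `sigma_rlu` column is present, per-point uncertainties are
#' propagated as the running sum of the per-interval variances:
#' \eqn{\sigma_{C,i}^2 = \sum_{j \le i} \sigma_j^2 \Delta t_j^2}.
#'
#' @param trace Trimmed trace tibble (`time_s` from injection, strictly
#'   increasing; `intensity_rlu`; optional `sigma_rlu`).
#' @return A conversion-curve tibble with `time_s`, `cumulative_rlu_s` and
#'   (when sigma was available) `sigma_rlu_s`; attribute `calibrated = FALSE`.
#' @export
cumulative_luminescence <- function(trace) {
  tt <- trace$time_s
  if (is.unsorted(tt, strictly = TRUE)) {
    abort("Trace time vector must be strictly increasing.")
  }
  dt <- diff(c(0, tt))
  if (any(dt <= 0)) abort("Trace must start after injection (t = 0).")
  out <- tibble(time_s = tt,
                cumulative_rlu_s = cumsum(trace$intensity_rlu * dt))
  if (!is.null(trace[["sigma_rlu"]])) {
    out$sigma_rlu_s <- sqrt(cumsum((trace[["sigma_rlu"]] * dt)^2))
  }
  for (a in c("background_rlu", "injection_time_s")) {
    attr(out, a) <- attr(trace, a)
  }
  attr(out, "calibrated") <- FALSE
  out
}

#' Calibrate the signal scaling factor from a complete-conversion curve
#'
#' When a reaction has run to completion (mirroring the excess-enzyme
#' calibration ensuring > 99.5% conversion), the plateau of the cumulative
#' luminescence equals `scaling_f * S0`, so
#' `scaling_f = plateau / S0`. Completion is verified from the curve itself:
#' the terminal intensity (terminal cumulative increment per second) must have
#' decayed below 0.5% of its maximum. If the criterion is unmet the achieved
#' conversion fraction is estimated by exponential-tail extrapolation and a
#' truncation error is raised unless `override = TRUE`.
#'
#' Because monitoring stops while a small signal remains, the plateau is
#' corrected for the unconverted remainder by extrapolating the terminal
#' exponential intensity decay (remaining signal = terminal intensity times
#' the decay time constant); for a run truncated at x% of maximal intensity
#' this removes an otherwise irreducible ~x% downward bias.
#'
#' @param curve Conversion curve from [cumulative_luminescence()].
#' @param S0 Substrate concentration actually converted, uM.
#' @param conversion_threshold Required conversion fraction (default 0.995).
#' @param override Skip the completion check (use with care).
#' @return The scaling factor, RLU.s per uM (scalar).
#' @export
calibrate_scaling <- function(curve, S0, conversion_threshold = 0.995,
                              override = FALSE) {
  if (S0 <= 0) abort("`S0` must be > 0.")
  tt <- curve$time_s
  cum <- curve$cumulative_rlu_s
  inten <- diff(c(0, cum)) / diff(c(0, tt))
  sm <- if (length(inten) >= 5) runmed(inten, 5) else inten
  remaining <- tail_remaining_signal(tt, sm)
  achieved <- if (is.na(remaining)) NA_real_ else
    cum[length(cum)] / (cum[length(cum)] + remaining)
  if (!override) {
    frac_int <- sm[length(sm)] / max(sm)
    ok <- (is.finite(frac_int) && frac_int < 0.005) ||
      (is.finite(achieved) && achieved >= conversion_threshold)
    if (!ok) {
      abort(sprintf(
        "Conversion incomplete: terminal intensity is %.2g of maximum (needs < 0.005); estimated conversion fraction %.3f < %.3f. Pass override = TRUE to calibrate anyway.",
        frac_int, achieved, conversion_threshold))
    }
  }
  plateau <- cum[length(cum)] + if (is.finite(remaining)) remaining else 0
  plateau / S0
}

# Remaining signal (RLU.s) past the end of the record, from an exponential
# fit to the intensity tail: remaining ~ I_final / |decay rate|.
tail_remaining_signal <- function(tt, inten) {
  n <- length(tt)
  idx <- seq(max(1L, floor(0.8 * n)), n)
  ii <- inten[idx]
  keep <- ii > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- lm(log(ii[keep]) ~ tt[idx][keep])
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  unname(max(inten[n], 0) / abs(slope))
}

#' Specific luciferase activity from the initial monitoring window
#'
#' The specific activity is the mean background-free intensity over the first
#' `window_s` seconds after injection divided by the molar enzyme
#' concentration, expressed in RLU/s/M. A stability flag records whether the
#' intensity at the end of the window stays within 2% of the intensity at the
#' start (enzyme concentrations in the source assays were tailored so it
#' does); instability is flagged, not raised.
#'
#' @param trace Trimmed trace tibble (`time_s` from injection).
#' @param E0 Enzyme concentration, uM (> 0).
#' @param window_s Monitoring window, s (default 15, the assay's span).
#' @return One-row tibble: `activity_rlu_s_M`, `stable`, `window_s`.
#' @export
specific_activity <- function(trace, E0, window_s = 15) {
  if (E0 <= 0) abort("`E0` must be > 0 to express activity per molar enzyme.")
  in_win <- trace$time_s <= window_s
  if (max(trace$time_s) < window_s) {
    abort(sprintf("Trace covers only %.3g s; %g s post-injection required.",
                  max(trace$time_s), window_s))
  }
  ii <- trace$intensity_rlu[in_win]
  activity <- mean(ii) / (E0 * 1e-6)
  i_start <- ii[1]
  i_end <- ii[length(ii)]
  stable <- is.finite(i_start) && i_start > 0 && abs(i_end / i_start - 1) <= 0.02
  tibble(activity_rlu_s_M = activity, stable = stable, window_s = window_s)
}

#' Relative activities with respect to a reference variant
#'
#' Rescales activities so the reference variant reads 100%.
#'
#' @param activities Tibble with columns `variant` and `activity` (any
#'   consistent unit), or a named numeric vector.
#' @param reference_variant Name of the reference (must be present, > 0).
#' @return Tibble `variant`, `activity`, `relative_pct`.
#' @export
relative_activity <- function(activities, reference_variant) {
  if (is.numeric(activities) && !is.null(names(activities))) {
    activities <- tibble(variant = names(activities), activity = unname(activities))
  }
  if (!all(c("variant", "activity") %in% names(activities))) {
    abort("`activities` needs columns `variant` and `activity`.")
  }
  ref <- activities$activity[activities$variant == reference_variant]
  if (length(ref) != 1L || !is.finite(ref) || ref <= 0) {
    abort(sprintf("Reference variant '%s' missing or non-positive.", reference_variant))
  }
  mutate(as_tibble(activities), relative_pct = 100 * .data$activity / ref)
}
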
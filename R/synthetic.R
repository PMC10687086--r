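#' Noise model for synthetic luminescence reads
#'
#' Gaussian measurement noise with a proportional and an additive component:
#' a read with true intensity I is drawn from
#' N(I, sqrt((cv * I)^2 + sd^2)). The generating standard deviation is
#' recorded as the per-point sigma, so sigma-normalized residuals are exactly
#' unit-scaled under the truth. With both components zero the recorded sigma
#' is 1 RLU (unit weights) so weighted objectives stay defined on noise-free
#' data.
#'
#' @param proportional_cv Proportional coefficient of variation (default 0.02,
#'   replicate-level scatter typical of injector plate reads).
#' @param additive_sd Additive read noise, RLU (default 5).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `noise_model` object.
#' @export
noise_model <- function(proportional_cv = 0.02, additive_sd = 5, seed = 1L) {
  if (proportional_cv < 0 || additive_sd < 0) abort("Noise components must be >= 0.")
  if (is.null(seed) || !is.finite(seed)) abort("A finite integer `seed` is required.")
  structure(list(proportional_cv = proportional_cv, additive_sd = additive_sd,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Concentration-series design
#'
#' The progress-curve series covers substrate concentrations at fixed
#' multiples of K_m (default 0.25-4 x K_m) with replicate wells.
#'
#' @param multipliers Positive K_m multiples (default `c(0.25, 0.5, 1, 2, 4)`).
#' @param replicates Wells per concentration level (default 3).
#' @return A `series_design` object.
#' @export
series_design <- function(multipliers = c(0.25, 0.5, 1, 2, 4), replicates = 3L) {
  if (any(multipliers <= 0)) abort("All multipliers must be > 0.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  structure(list(multipliers = sort(multipliers), replicates = as.integer(replicates)),
            class = "series_design")
}

#' Substrate concentrations for a progress-curve series
#'
#' @param K_m Michaelis constant, uM (> 0).
#' @param design A [series_design()].
#' @return Ascending numeric vector of S0 values, uM.
#' @examples
#' design_concentration_series(0.57, series_design())
#' @export
design_concentration_series <- function(K_m, design = series_design()) {
  if (K_m <= 0) abort("`K_m` must be > 0.")
  sort(design$multipliers * K_m)
}

#' Apply bounded uniform jitter to prepared concentrations
#'
#' Emulates dilution/pipetting error: each value is multiplied by an
#' independent uniform draw in `[1 - max_fraction, 1 + max_fraction]`.
#'
#' @param values Concentrations, uM.
#' @param max_fraction Maximum relative perturbation (default 0.05).
#' @param seed Optional seed for reproducible draws.
#' @return Perturbed vector, same length.
#' @export
jitter_concentrations <- function(values, max_fraction = 0.05, seed = NULL) {
  if (max_fraction < 0) abort("`max_fraction` must be >= 0.")
  if (max_fraction == 0) return(values)
  with_seed(seed, values * runif(length(values), 1 - max_fraction, 1 + max_fraction))
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream), restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate one synthetic plate-reader luminescence trace
#'
#' Emulates an injection assay: `baseline_s` of background-only reads,
#' injection, then sampling at the read interval. The true post-injection
#' intensity is the forward model of [intensity_from_progress()] applied to
#' the integrated progress curve, plus the background. Recording stops at the
#' first read where the 5-point running median of the background-free signal
#' falls below 0.5% of its running maximum (the smoothing guards against
#' noise-triggered early stops), or at the `max_duration_s` cap.
#'
#' @param params A [kinetic_params()] truth.
#' @param cond An [assay_conditions()] object.
#' @param scheme A [kinetic_scheme()].
#' @param scaling_f Signal scaling factor, RLU.s per uM.
#' @param noise A [noise_model()]; its seed makes the trace reproducible.
#' @param background_rlu Constant background level, RLU (default 100; actual
#'   instrument backgrounds are not standardized, the value used is recorded
#'   in the attributes).
#' @param true_S0 Actual substrate concentration if it differs from the
#'   nominal `cond$S0` (e.g. after [jitter_concentrations()]).
#' @return Trace tibble `time_s` (recording clock, injection at
#'   `cond$baseline_s`), `intensity_rlu`, `sigma_rlu`; attributes
#'   `injection_time_s`, `background_rlu`, `scaling_f`, `true_S0`, `seed`.
#' @export
generate_trace <- function(params, cond, scheme = kinetic_scheme("mm_prod_inhib"),
                           scaling_f = 1e6, noise = noise_model(),
                           background_rlu = 100, true_S0 = NULL) {
  true_S0 <- true_S0 %||% cond$S0
  cond_true <- cond
  cond_true$S0 <- true_S0

  tau <- seq(0, cond$max_duration_s, by = cond$read_interval_s)
  if (cond$E0 > 0) {
    pc <- integrate_progress(params, cond_true, scheme, times = tau)
    signal <- intensity_from_progress(pc, scaling_f)$intensity_rlu
  } else {
    signal <- rep(0, length(tau) - 1L)
  }

  t_base <- seq(0, cond$baseline_s - cond$read_interval_s, by = cond$read_interval_s)
  if (cond$baseline_s == 0) t_base <- numeric(0)
  t_post <- cond$baseline_s + tau[-1]
  times <- c(t_base, t_post)
  i_true <- c(rep(0, length(t_base)), signal) + background_rlu

  noise_sd <- sqrt((noise$proportional_cv * i_true)^2 + noise$additive_sd^2)
  intensity <- with_seed(noise$seed, i_true + rnorm(length(i_true), 0, noise_sd))
  # recorded sigma is the generating SD; unit weights for noise-free data
  sigma <- if (all(noise_sd == 0)) rep(1, length(noise_sd)) else noise_sd

  # stop rule on the background-free post-injection signal
  post_idx <- seq(length(t_base) + 1L, length(times))
  sig_meas <- intensity[post_idx] - background_rlu
  sm <- if (length(sig_meas) >= 5) runmed(sig_meas, 5) else sig_meas
  runmax <- cummax(sm)
  stop_at <- which(sm < 0.005 * runmax & runmax > 0)
  keep <- if (length(stop_at) > 0) {
    c(seq_along(t_base), post_idx[seq_len(stop_at[1])])
  } else {
    seq_along(times)
  }

  out <- tibble(time_s = times[keep], intensity_rlu = intensity[keep],
                sigma_rlu = sigma[keep])
  attr(out, "injection_time_s") <- cond$baseline_s
  attr(out, "background_rlu") <- background_rlu
  attr(out, "scaling_f") <- scaling_f
  attr(out, "true_S0") <- true_S0
  attr(out, "seed") <- noise$seed
  out
}

#' Generate a full synthetic kinetic study
#'
#' Fixture factory emulating a complete progress-curve study: for each
#' enzyme-luciferin truth, a 0.25-4 x K_m concentration series with
#' replicates, per-level +/-5% concentration-preparation jitter (one prepared
#' dilution per level, shared by its replicates), injection baseline, noise
#' and the stop rule. A machine-readable truth record accompanies the traces
#' for recovery testing.
#'
#' @param truths Tibble with one row per enzyme-luciferin pair: columns
#'   `variant`, `luciferin`, `k_cat`, `K_m`, `K_p` (`Inf` allowed), optional
#'   `K_s` (default `Inf`), `E0_uM`, optional `scaling_f` (default 1e6).
#' @param design A [series_design()].
#' @param noise A [noise_model()]; all per-trace seeds derive from its seed.
#' @param scheme A [kinetic_scheme()].
#' @param jitter_fraction Concentration-preparation error bound (default 0.05;
#'   0 disables jitter).
#' @param read_interval_s,max_duration_s,baseline_s Assay timing, s.
#' @param background_rlu Background level, RLU.
#' @return A `lucifit_study`: list with `traces` (long tibble with metadata
#'   columns `variant`, `luciferin`, `E0_uM`, `S0_uM` (nominal), `replicate`,
#'   `well`) and `truth` (per-well truth tibble).
#' @export
generate_study <- function(truths, design = series_design(), noise = noise_model(),
                           scheme = kinetic_scheme("mm_prod_inhib"),
                           jitter_fraction = 0.05, read_interval_s = 0.5,
                           max_duration_s = 1000, baseline_s = 10,
                           background_rlu = 100) {
  if (nrow(truths) == 0) {
    return(structure(list(traces = tibble(), truth = tibble()), class = "lucifit_study"))
  }
  truths <- as_tibble(truths)
  if (is.null(truths$K_s)) truths$K_s <- Inf
  if (is.null(truths$scaling_f)) truths$scaling_f <- 1e6
  key <- paste(truths$variant, truths$luciferin, sep = "/")
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate variant-luciferin ids: %s",
                  paste(unique(key[duplicated(key)]), collapse = ", ")))
  }

  trace_seed <- 0L
  all_traces <- list()
  all_truth <- list()
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    params <- kinetic_params(tr$k_cat, tr$K_m, tr$K_p, tr$K_s)
    S0_nominal <- design_concentration_series(tr$K_m, design)
    S0_true <- jitter_concentrations(S0_nominal, jitter_fraction,
                                     seed = noise$seed + 7919L * i)
    for (l in seq_along(S0_nominal)) {
      cond <- assay_conditions(E0 = tr$E0_uM, S0 = S0_nominal[l],
                               baseline_s = baseline_s,
                               read_interval_s = read_interval_s,
                               max_duration_s = max_duration_s)
      for (r in seq_len(design$replicates)) {
        trace_seed <- trace_seed + 1L
        nm <- noise_model(noise$proportional_cv, noise$additive_sd,
                          seed = (noise$seed + 104729L * trace_seed) %% .Machine$integer.max)
        trace <- generate_trace(params, cond, scheme, scaling_f = tr$scaling_f,
                                noise = nm, background_rlu = background_rlu,
                                true_S0 = S0_true[l])
        well <- sprintf("%s/%s/S%02d/r%d", tr$variant, tr$luciferin, l, r)
        all_traces[[well]] <- mutate(trace, variant = tr$variant,
                                     luciferin = tr$luciferin, E0_uM = tr$E0_uM,
                                     S0_uM = S0_nominal[l], replicate = r,
                                     well = well)
        all_truth[[well]] <- tibble(
          well = well, variant = tr$variant, luciferin = tr$luciferin,
          level = l, replicate = r, S0_nominal = S0_nominal[l],
          S0_true = S0_true[l], E0_uM = tr$E0_uM, k_cat = tr$k_cat,
          K_m = tr$K_m, K_p = tr$K_p, K_s = tr$K_s, scaling_f = tr$scaling_f,
          background_rlu = background_rlu, seed = attr(trace, "seed"),
          baseline_s = baseline_s, read_interval_s = read_interval_s)
      }
    }
  }
  structure(list(traces = list_rbind(all_traces), truth = list_rbind(all_truth)),
            class = "lucifit_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
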
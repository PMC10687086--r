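#' Read a plate-reader trace CSV
#'
#' The trace format is RFC-4180 CSV (UTF-8, decimal point, comma separator,
#' header required) with one row per read:
#' `time_s, intensity_rlu, sigma_rlu (optional), variant, luciferin, E0_uM,
#' S0_uM, replicate` and optionally `well`. Times must be strictly increasing
#' within each well.
#'
#' @param path CSV file path.
#' @return Long trace tibble (with a `well` column derived from the metadata
#'   if absent).
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("time_s", "intensity_rlu", "variant", "luciferin", "E0_uM",
                "S0_uM", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Trace CSV is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"well" %in% names(df)) {
    df$well <- paste(df$variant, df$luciferin, df$S0_uM, df$replicate, sep = "/")
  }
  bad <- df |>
    group_by(.data$well) |>
    summarise(mono = !is.unsorted(.data$time_s, strictly = TRUE),
              first_bad = if (all(diff(.data$time_s) > 0)) NA_integer_ else
                which(diff(.data$time_s) <= 0)[1] + 1L) |>
    filter(!.data$mono)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-monotone time vector in well '%s' (row %d within well).",
                  bad$well[1], bad$first_bad[1]))
  }
  df
}

#' Write a trace tibble (or study) to the trace CSV format
#'
#' @param traces Long trace tibble or `lucifit_study`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "lucifit_study")) traces <- traces$traces
  readr::write_csv(traces, path, progress = FALSE)
  invisible(path)
}

#' Write / read the study truth sidecar (JSON)
#'
#' The truth record of a synthetic study round-trips through JSON unchanged
#' (`Inf` encoded as the string `"Inf"`).
#'
#' @param truth Truth tibble from [generate_study()].
#' @param path JSON path.
#' @return `path` invisibly (writer); truth tibble (reader).
#' @export
write_truth_json <- function(truth, path) {
  out <- as.data.frame(truth)
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && any(is.infinite(out[[cl]]))) {
      out[[cl]] <- ifelse(is.infinite(out[[cl]]), "Inf", as.character(out[[cl]]))
    }
  }
  jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  num_cols <- c("S0_nominal", "S0_true", "E0_uM", "k_cat", "K_m", "K_p", "K_s",
                "scaling_f", "background_rlu", "baseline_s", "read_interval_s")
  for (cl in intersect(num_cols, names(df))) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  as_tibble(df)
}

#' Validated run configuration for the two-stage pipeline
#'
#' Collects every tunable of the workflow in one validated object. Unknown
#' keys are rejected, and a seed is mandatory: all randomness in a pipeline
#' run flows from it.
#'
#' @param seed Integer seed (required).
#' @param scheme_id Kinetic scheme id (see [kinetic_scheme()]).
#' @param truths Truth tibble for simulation mode (see [generate_study()]),
#'   or `NULL` when reading traces from `input_csv`.
#' @param input_csv Optional path to a trace CSV (measurement mode).
#' @param design A [series_design()].
#' @param noise_cv,noise_sd Noise model components for simulation mode.
#' @param jitter_fraction Concentration-preparation error bound.
#' @param read_interval_s,max_duration_s,baseline_s Assay timing, s.
#' @param multistart_n Global-fit starts.
#' @param conc_correction Fit per-level S0 corrections?
#' @param contour_pair Optional character pair for contour analysis (`NULL`
#'   disables it).
#' @param contour_grid_n Contour grid nodes per axis.
#' @param output_dir Optional output directory; when set, results are written
#'   as JSON/CSV files.
#' @param ... Unknown keys: rejected.
#' @return A `run_config` object.
#' @export
run_config <- function(seed, scheme_id = "mm_prod_inhib", truths = NULL,
                       input_csv = NULL, design = series_design(),
                       noise_cv = 0.02, noise_sd = 5, jitter_fraction = 0.05,
                       read_interval_s = 0.5, max_duration_s = 1000,
                       baseline_s = 10, multistart_n = 4,
                       conc_correction = TRUE, contour_pair = NULL,
                       contour_grid_n = 15, output_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(names(extra), collapse = ", ")))
  }
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    abort("A seed is mandatory: every stochastic step must be reproducible.")
  }
  if (is.null(truths) && is.null(input_csv)) {
    abort("Provide either `truths` (simulation mode) or `input_csv`.")
  }
  structure(list(seed = as.integer(seed), scheme_id = scheme_id,
                 truths = truths, input_csv = input_csv, design = design,
                 noise_cv = noise_cv, noise_sd = noise_sd,
                 jitter_fraction = jitter_fraction,
                 read_interval_s = read_interval_s,
                 max_duration_s = max_duration_s, baseline_s = baseline_s,
                 multistart_n = multistart_n, conc_correction = conc_correction,
                 contour_pair = contour_pair, contour_grid_n = contour_grid_n,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the two-stage kinetics pipeline
#'
#' Executes the full workflow on each enzyme-luciferin series: conversion
#' transform, stage 1 (initial-rate fit seeding K_m and Vmax), stage 2
#' (global progress-curve fit), derived quantities with propagated errors,
#' and optional confidence contours. In simulation mode the input study is
#' generated from the configured truths first. All numeric outputs are
#' deterministic functions of the configuration.
#'
#' @param config A [run_config()].
#' @return A `lucifit_report`: list with `fits` (per-series `lucifit_fit`),
#'   `summary` (tidy per-series parameter table), `derived` (specificity
#'   constants), `contours` (optional), `log` (decisions and seeds), and in
#'   simulation mode `study` (the generated bundle).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scheme <- kinetic_scheme(config$scheme_id)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("scheme: %s", config$scheme_id),
                 sprintf("read_interval_s: %g (declared default)", config$read_interval_s),
                 "sigma source: generating noise model (simulation) / CSV sigma column",
                 "observable: cumulative luminescence")

  study <- NULL
  if (!is.null(config$input_csv)) {
    traces <- read_trace_csv(config$input_csv)
    log_lines <- c(log_lines, sprintf("input: %s", config$input_csv))
  } else {
    study <- generate_study(
      config$truths, design = config$design,
      noise = noise_model(config$noise_cv, config$noise_sd, seed = config$seed),
      scheme = scheme, jitter_fraction = config$jitter_fraction,
      read_interval_s = config$read_interval_s,
      max_duration_s = config$max_duration_s, baseline_s = config$baseline_s)
    traces <- study$traces
    log_lines <- c(log_lines, "input: simulated study")
  }
  if (!"sigma_rlu" %in% names(traces)) {
    abort("Traces carry no sigma; the pipeline refuses to fit unweighted data.")
  }

  curves <- study_conversion_curves(traces, injection_s = config$baseline_s)
  series <- distinct(curves, .data$variant, .data$luciferin, .data$E0_uM)

  fits <- purrr::pmap(series, function(variant, luciferin, E0_uM) {
    sub <- filter(curves, .data$variant == !!variant, .data$luciferin == !!luciferin)
    v0 <- sub |>
      group_by(.data$well, .data$S0_uM) |>
      dplyr::group_modify(function(df, key) initial_velocity(df)) |>
      ungroup()
    ir <- tryCatch(
      fit_initial_rates(dplyr::rename(v0, S0 = "S0_uM"),
                        substrate_inhibition = FALSE, seed = config$seed),
      error = function(e) NULL)
    init <- if (!is.null(ir)) {
      km <- ir$estimates$estimate[ir$estimates$term == "K_m"]
      vmax <- ir$estimates$estimate[ir$estimates$term == "Vmax"]
      list(K_m = km)   # Vmax is in RLU/s; k_cat seeding handled by fill_init
    } else NULL
    fit_global(sub, E0 = E0_uM, scheme = scheme, init = init,
               multistart_n = config$multistart_n, seed = config$seed,
               conc_correction = config$conc_correction)
  })
  names(fits) <- paste(series$variant, series$luciferin, sep = "/")

  summary_tbl <- imap(fits, function(f, nm) {
    mutate(tidy(f), series = nm, .before = 1)
  }) |> list_rbind()

  derived <- imap(fits, function(f, nm) {
    est <- f$estimates
    kc <- est[est$term == "k_cat", ]
    km <- est[est$term == "K_m", ]
    mutate(specificity_constant(kc$estimate, km$estimate,
                                kc$se %|NA|% 0, km$se %|NA|% 0),
           series = nm, .before = 1)
  }) |> list_rbind()

  contours <- NULL
  if (!is.null(config$contour_pair)) {
    contours <- purrr::map(fits, confidence_contours,
                           pair = config$contour_pair,
                           grid_n = config$contour_grid_n)
  }

  report <- structure(list(fits = fits, summary = summary_tbl, derived = derived,
                           contours = contours, log = log_lines, study = study,
                           config = config),
                      class = "lucifit_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      purrr::map(fits, function(f) list(
        estimates = f$estimates, scaling_f = f$scaling_f, chi2 = f$chi2,
        n_points = f$n_points, n_params = f$n_params, converged = f$converged,
        conc_corrections = f$conc_corrections)),
      file.path(config$output_dir, "fit_results.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    readr::write_csv(derived, file.path(config$output_dir, "derived_quantities.csv"))
    writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
    if (!is.null(contours)) {
      for (nm in names(contours)) {
        readr::write_csv(contours[[nm]]$grid,
                         file.path(config$output_dir,
                                   sprintf("contours_%s.csv", gsub("/", "_", nm))))
      }
    }
  }
  report
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' @export
print.lucifit_report <- function(x, ...) {
  cat(sprintf("<lucifit_report>  %d series\n", length(x$fits)))
  print(x$summary)
  invisible(x)
}
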
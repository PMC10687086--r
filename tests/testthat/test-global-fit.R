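# Shared noiseless fixture: wild-type/CTZ truth, 5-level series, 1 replicate,
# coarse 2 s read grid to keep the suite fast.
noiseless_curves <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      st <- generate_study(truth_row(), design = series_design(replicates = 1),
                           noise = noise_model(0, 0, seed = 1),
                           jitter_fraction = 0, read_interval_s = 2)
      memo <<- study_conversion_curves(st)
    }
    memo
  }
})

test_that("chi-squared objective obeys its defining identities", {
  curves <- noiseless_curves()
  truth <- wt_ctz()
  # data generated exactly by the model at the evaluated parameters -> ~0
  chi0 <- chi_squared(curves, truth, scaling_f = 1e6, E0 = 0.01)
  expect_lt(chi0, 1e-10 * nrow(curves))
  # scaling every sigma by c divides the objective by c^2
  off <- kinetic_params(2.48 * 1.3, 0.57, K_p = 0.256)
  chi_a <- chi_squared(curves, off, 1e6, 0.01)
  curves2 <- dplyr::mutate(curves, sigma_rlu_s = sigma_rlu_s * 3)
  chi_b <- chi_squared(curves2, off, 1e6, 0.01)
  expect_equal(chi_b, chi_a / 9, tolerance = 1e-12)
  expect_gt(chi_a, 0)
})

test_that("chi-squared matches hand arithmetic on a 3-point toy curve", {
  # model P(t) for E0 = 0 is identically 0, so model cumulative = 0 and the
  # objective reduces to sum((obs/sigma)^2), hand-computable
  toy <- tibble::tibble(well = "w", S0_uM = 1, time_s = c(1, 2, 3),
                        cumulative_rlu_s = c(3, 4, 12), sigma_rlu_s = c(1, 2, 4))
  p <- wt_ctz()
  # with E0 ~ 0 the model cumulative vanishes, so by hand:
  # (3/1)^2 + (4/2)^2 + (12/4)^2 = 9 + 4 + 9 = 22
  chi <- chi_squared(toy, p, scaling_f = 1, E0 = 1e-12)
  expect_equal(chi, 22, tolerance = 1e-6)
})

test_that("missing sigma is a configuration error, not silent unweighting", {
  curves <- dplyr::select(noiseless_curves(), -sigma_rlu_s)
  expect_error(chi_squared(curves, wt_ctz(), 1e6, 0.01), "sigma")
  expect_error(fit_global(curves, E0 = 0.01), "sigma")
})

test_that("init at truth on noiseless data is a fixed point", {
  curves <- noiseless_curves()
  fit <- fit_global(curves, E0 = 0.01, multistart_n = 1,
                    init = list(k_cat = 2.48, K_m = 0.57, K_p = 0.256,
                                scaling_f = 1e6))
  expect_true(fit$converged)
  expect_lt(fit$chi2, 1e-8)
  expect_equal(fit$estimates$estimate, c(2.48, 0.57, 0.256), tolerance = 1e-5)
  expect_equal(fit$scaling_f, 1e6, tolerance = 1e-5)
})

test_that("noiseless curves are recovered from perturbed starts to 0.1%", {
  # wild-type/FMZ generating constants, init off by x/÷3
  st <- generate_study(truth_row("WT", "FMZ", k_cat = 7.88, K_m = 0.123,
                                 K_p = 0.56),
                       design = series_design(replicates = 1),
                       noise = noise_model(0, 0, seed = 2),
                       jitter_fraction = 0, read_interval_s = 2)
  curves <- study_conversion_curves(st)
  fit <- fit_global(curves, E0 = 0.01, multistart_n = 1,
                    init = list(k_cat = 7.88 * 3, K_m = 0.123 / 3,
                                K_p = 0.56 * 3, scaling_f = 1e6 / 3))
  rel <- abs(fit$estimates$estimate / c(7.88, 0.123, 0.56) - 1)
  expect_lt(max(rel), 1e-3)
  expect_equal(fit$scaling_f, 1e6, tolerance = 1e-3)
})

test_that("estimates are invariant to dataset order", {
  curves <- noiseless_curves()
  fit1 <- fit_global(curves, E0 = 0.01, multistart_n = 1,
                     init = list(k_cat = 3, K_m = 0.4, K_p = 0.4, scaling_f = 8e5))
  set.seed(31)
  fit2 <- fit_global(curves[sample(nrow(curves)), ], E0 = 0.01, multistart_n = 1,
                     init = list(k_cat = 3, K_m = 0.4, K_p = 0.4, scaling_f = 8e5))
  expect_equal(fit2$estimates$estimate, fit1$estimates$estimate,
               tolerance = 1e-10)
})

test_that("concentration corrections stay inside the +/-5% box", {
  st <- generate_study(truth_row(), design = series_design(replicates = 1),
                       noise = noise_model(0.02, 5, seed = 3),
                       jitter_fraction = 0.05, read_interval_s = 2)
  curves <- study_conversion_curves(st)
  fit <- fit_global(curves, E0 = 0.01, multistart_n = 1)
  expect_true(all(fit$conc_corrections$correction >= 0.95 - 1e-9))
  expect_true(all(fit$conc_corrections$correction <= 1.05 + 1e-9))
  expect_true(fit$converged)
})

test_that("truncating all curves below 50% conversion inflates the scaling-factor SE", {
  st <- generate_study(truth_row(), design = series_design(replicates = 1),
                       noise = noise_model(0.02, 5, seed = 4),
                       jitter_fraction = 0, read_interval_s = 2)
  curves <- study_conversion_curves(st)
  fit_full <- fit_global(curves, E0 = 0.01, multistart_n = 1,
                         conc_correction = FALSE)
  trunc <- curves |>
    dplyr::group_by(well) |>
    dplyr::filter(cumulative_rlu_s < 0.5 * 1e6 * S0_uM) |>
    dplyr::ungroup()
  fit_trunc <- fit_global(trunc, E0 = 0.01, multistart_n = 1,
                          conc_correction = FALSE,
                          init = list(k_cat = 2.48, K_m = 0.57, K_p = 0.256,
                                      scaling_f = 1e6))
  expect_gt(fit_trunc$scaling_f_se / fit_trunc$scaling_f,
            5 * fit_full$scaling_f_se / fit_full$scaling_f)
})

test_that("depletion check reports the conversion fraction", {
  pc <- integrate_progress(kinetic_params(2.48, 0.57),
                           assay_conditions(E0 = 0.05, S0 = 0.5, max_duration_s = 400))
  cc <- cumulative_luminescence(intensity_from_progress(pc, 1e6))
  full <- check_depletion(cc, S0 = 0.5, scaling_f = 1e6)
  expect_true(full$pass)
  expect_equal(full$conversion_fraction, 1, tolerance = 1e-3)
  part <- check_depletion(cc[cc$cumulative_rlu_s < 0.6 * 5e5, ], S0 = 0.5,
                          scaling_f = 1e6)
  expect_false(part$pass)
  expect_equal(part$conversion_fraction, 0.6, tolerance = 0.02)
})

test_that("tidiers expose estimates, fit stats and residuals", {
  curves <- noiseless_curves()
  fit <- fit_global(curves, E0 = 0.01, multistart_n = 1,
                    init = list(k_cat = 2.48, K_m = 0.57, K_p = 0.256,
                                scaling_f = 1e6))
  td <- tidy(fit)
  expect_true(all(c("k_cat", "K_m", "K_p", "scaling_f") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$n_points, nrow(curves))
  expect_true(gl$converged)
  aug <- augment(fit)
  expect_equal(nrow(aug), nrow(curves))
  expect_lt(max(abs(aug$resid_norm)), 1e-3)
  expect_s3_class(autoplot(fit), "ggplot")
})
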
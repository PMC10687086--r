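test_that("intensity/cumulative transforms are exact inverses up to scaling", {
  pc <- integrate_progress(wt_ctz(), assay_conditions(E0 = 0.01, S0 = 1,
                                                      max_duration_s = 300))
  tr <- intensity_from_progress(pc, scaling_f = 1e6)
  cc <- cumulative_luminescence(tr)
  expect_equal(cc$cumulative_rlu_s, 1e6 * pc$product_uM[-1], tolerance = 1e-12)
  # telescoping: total integrated signal recovers terminal product exactly
  dt <- diff(pc$time_s)
  expect_equal(sum(tr$intensity_rlu * dt) / 1e6, max(pc$product_uM),
               tolerance = 1e-12)
})

test_that("round-trip identity holds on random product trajectories", {
  set.seed(11)
  for (i in 1:20) {
    tt <- c(0, sort(runif(50, 0.01, 100)))
    P <- cumsum(c(0, runif(50, 0, 0.05)))   # nondecreasing trajectory
    curve <- tibble::tibble(time_s = tt, product_uM = P)
    f <- 10^runif(1, 3, 7)
    back <- cumulative_luminescence(intensity_from_progress(curve, f))
    expect_equal(back$cumulative_rlu_s, f * P[-1], tolerance = 1e-10)
  }
})

test_that("constant product gives zero intensity; zero trace gives zero curve", {
  curve <- tibble::tibble(time_s = seq(0, 10, 0.5), product_uM = 0.7)
  tr <- intensity_from_progress(curve, 1e5)
  expect_true(all(tr$intensity_rlu == 0))
  expect_true(all(cumulative_luminescence(tr)$cumulative_rlu_s == 0))
})

test_that("cumulative sigma grows as the running sum of per-point variances", {
  # Monte-Carlo check of the propagated uncertainty law
  set.seed(3)
  n <- 40
  tt <- seq(0.5, 20, by = 0.5)
  sigma <- runif(n, 2, 10)
  reps <- purrr::map(1:1000, function(i) {
    tr <- tibble::tibble(time_s = tt, intensity_rlu = rnorm(n, 0, sigma),
                         sigma_rlu = sigma)
    cumulative_luminescence(tr)$cumulative_rlu_s
  })
  emp_sd <- apply(do.call(rbind, reps), 2, sd)
  pred_sd <- sqrt(cumsum((sigma * 0.5)^2))
  expect_lt(max(abs(emp_sd / pred_sd - 1)), 0.15)
})

test_that("cumulative transform rejects non-monotone time vectors", {
  tr <- tibble::tibble(time_s = c(1, 2, 2), intensity_rlu = 1:3)
  expect_error(cumulative_luminescence(tr), "strictly increasing")
})

test_that("scaling calibration recovers the generating factor and guards truncation", {
  pc <- integrate_progress(kinetic_params(2.48, 0.57),
                           assay_conditions(E0 = 0.05, S0 = 0.5, max_duration_s = 400))
  cc <- cumulative_luminescence(intensity_from_progress(pc, 1e6))
  f <- calibrate_scaling(cc, S0 = 0.5)
  expect_equal(f, 1e6, tolerance = 1e-5)   # conversion is complete

  truncated <- cc[cc$time_s <= approx(pc$product_uM[-1], cc$time_s, 0.25,
                                      ties = "ordered")$y, ]
  expect_error(calibrate_scaling(truncated, S0 = 0.5), "incomplete")
})

test_that("noisy complete-conversion calibration recovers f within 1%", {
  truth <- truth_row(E0_uM = 0.05, K_p = Inf)
  errs <- purrr::map_dbl(1:100, function(s) {
    st <- generate_study(truth,
                         design = series_design(multipliers = 1, replicates = 1),
                         noise = noise_model(0.02, 0, seed = s),
                         jitter_fraction = 0)
    curves <- study_conversion_curves(st)
    f <- calibrate_scaling(curves, S0 = 0.57)
    f / 1e6 - 1
  })
  expect_lt(median(abs(errs)), 0.01)
  expect_lt(max(abs(errs)), 0.05)
})

test_that("baseline trimming subtracts the median background and clips negatives", {
  tr <- tibble::tibble(time_s = seq(0, 20, 0.5),
                       intensity_rlu = c(rep(100, 20), rep(500, 21)))
  attr(tr, "injection_time_s") <- 9.5
  out <- trim_baseline(tr)
  expect_equal(attr(out, "background_rlu"), 100)
  expect_equal(out$time_s[1], 0.5)
  expect_true(all(out$intensity_rlu == 400))
  # negative post-subtraction reads are clipped with a message
  tr2 <- tibble::tibble(time_s = seq(0, 20, 0.5),
                        intensity_rlu = c(rep(100, 20), rep(50, 21)))
  expect_message(out2 <- trim_baseline(tr2, injection_s = 9.5), "Clipped")
  expect_true(all(out2$intensity_rlu == 0))
})

test_that("specific activity is the 15-s mean over molar enzyme, with stability flag", {
  tr <- tibble::tibble(time_s = seq(0.5, 20, 0.5), intensity_rlu = 1000)
  out <- specific_activity(tr, E0 = 1e-3)   # 1e-3 uM = 1e-9 M
  expect_equal(out$activity_rlu_s_M, 1e12)
  expect_true(out$stable)

  decay <- tibble::tibble(time_s = seq(0.5, 20, 0.5),
                          intensity_rlu = 1000 * (1 - 0.05 * seq(0.5, 20, 0.5) / 15))
  expect_false(specific_activity(decay, E0 = 1e-3)$stable)
  expect_error(specific_activity(tr, E0 = 0), "E0")
  expect_error(specific_activity(tr[tr$time_s < 10, ], E0 = 1e-3), "required")
})

test_that("specific activity is linear in 1/E0 in the substrate-saturated regime", {
  p <- kinetic_params(2.48, 0.57)      # no product inhibition: flat initial phase
  acts <- purrr::map_dbl(c(0.001, 0.002), function(E0) {
    cond <- assay_conditions(E0 = E0, S0 = 50, max_duration_s = 20)
    pc <- integrate_progress(p, cond)
    tr <- intensity_from_progress(pc, 1e6)
    specific_activity(tr, E0 = E0)$activity_rlu_s_M
  })
  expect_equal(acts[1], acts[2], tolerance = 0.01)
})

test_that("relative activity rescales to the reference = 100%", {
  acts <- tibble::tibble(variant = c("WT", "M1", "M2"),
                         activity = c(2e12, 9e12, 0))
  out <- relative_activity(acts, "WT")
  expect_equal(out$relative_pct, c(100, 450, 0))
  expect_error(relative_activity(acts, "missing"), "missing")
  expect_error(relative_activity(tibble::tibble(variant = "A", activity = 0), "A"),
               "non-positive")
})
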
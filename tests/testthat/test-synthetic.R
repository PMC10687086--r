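test_that("concentration series is K_m multiples, ascending and positive", {
  s <- design_concentration_series(0.57)
  expect_equal(s, c(0.1425, 0.285, 0.57, 1.14, 2.28))
  expect_equal(length(s), 5)
  expect_true(all(s > 0))
  expect_error(series_design(multipliers = c(-1, 2)), "> 0")
  expect_error(design_concentration_series(0), "> 0")
})

test_that("concentration jitter is bounded, seed-reproducible, and identity at 0", {
  x <- c(0.2, 1, 5)
  expect_identical(jitter_concentrations(x, max_fraction = 0), x)
  set.seed(99)
  big <- jitter_concentrations(rep(1, 1e4), 0.05)
  expect_true(all(abs(big - 1) <= 0.05))
  a <- jitter_concentrations(x, 0.05, seed = 4)
  b <- jitter_concentrations(x, 0.05, seed = 4)
  expect_identical(a, b)
  # and the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(jitter_concentrations(x, 0.05, seed = 4))
  expect_identical(runif(1), before)
})

test_that("generated traces are deterministic given the seed", {
  cond <- assay_conditions(E0 = 0.01, S0 = 0.5, max_duration_s = 100)
  a <- generate_trace(wt_ctz(), cond, noise = noise_model(seed = 12))
  b <- generate_trace(wt_ctz(), cond, noise = noise_model(seed = 12))
  expect_identical(a, b)
  c <- generate_trace(wt_ctz(), cond, noise = noise_model(seed = 13))
  expect_false(identical(a$intensity_rlu, c$intensity_rlu))
})

test_that("zero-noise trace equals the forward model point for point", {
  cond <- assay_conditions(E0 = 0.01, S0 = 0.5, max_duration_s = 300)
  tr <- generate_trace(wt_ctz(), cond, scaling_f = 1e6,
                       noise = noise_model(0, 0, seed = 1),
                       background_rlu = 100)
  post <- tr[tr$time_s > 10, ]
  pc <- integrate_progress(wt_ctz(), cond)
  expected <- intensity_from_progress(pc, 1e6)
  n <- nrow(post)
  expect_equal(post$intensity_rlu - 100, expected$intensity_rlu[seq_len(n)],
               tolerance = 1e-9)
  # Euler-oracle agreement of the same trace (independent route)
  P_euler <- euler_progress(2.48, 0.57, 0.256, Inf, 0.01, 0.5, pc$time_s)
  I_euler <- 1e6 * diff(P_euler) / diff(pc$time_s)
  expect_lt(max(abs((post$intensity_rlu - 100) - I_euler[seq_len(n)])) /
              max(I_euler), 2e-3)
})

test_that("zero-enzyme zero-noise trace is flat baseline capped at 1000 s", {
  cond <- assay_conditions(E0 = 0, S0 = 0.5)
  tr <- generate_trace(wt_ctz(), cond, noise = noise_model(0, 0, seed = 1),
                       background_rlu = 50)
  expect_true(all(tr$intensity_rlu == 50))
  expect_equal(max(tr$time_s), 10 + 1000)
})

test_that("stop rule truncates fast reactions at 0.5% of max and caps slow ones", {
  # fast: high enzyme, strong product inhibition drives intensity down quickly
  fast <- generate_trace(kinetic_params(5, 0.3, K_p = 0.1),
                         assay_conditions(E0 = 0.05, S0 = 0.5),
                         noise = noise_model(0, 0, seed = 1))
  expect_lt(max(fast$time_s), 1010)
  sig <- fast$intensity_rlu[fast$time_s > 10] - 100
  n <- length(sig)
  expect_lt(sig[n], 0.005 * max(sig))          # last read is below threshold
  expect_true(all(sig[-n] >= 0.005 * cummax(sig)[-n]))  # and it is the first such read

  # slow: tiny enzyme concentration, conversion far from complete at the cap
  slow <- generate_trace(wt_ctz(), assay_conditions(E0 = 1e-4, S0 = 2),
                         noise = noise_model(0, 0, seed = 1))
  expect_equal(max(slow$time_s), 1010)
})

test_that("study generation counts wells and records a faithful truth table", {
  truths <- dplyr::bind_rows(
    truth_row("WT", "CTZ"), truth_row("WT", "FMZ", k_cat = 7.88, K_m = 0.123,
                                      K_p = 0.56))
  st <- generate_study(truths, design = series_design(multipliers = c(0.5, 1, 2),
                                                      replicates = 2),
                       noise = noise_model(seed = 5), max_duration_s = 100)
  expect_equal(nrow(st$truth), 2 * 3 * 2)
  expect_equal(dplyr::n_distinct(st$traces$well), 12)
  expect_true(all(abs(st$truth$S0_true / st$truth$S0_nominal - 1) <= 0.05))
  # replicates of one level share the same prepared (true) concentration
  per_level <- st$truth |> dplyr::distinct(variant, luciferin, level, S0_true)
  expect_equal(nrow(per_level), 2 * 3)

  # determinism of the full bundle
  st2 <- generate_study(truths, design = series_design(multipliers = c(0.5, 1, 2),
                                                       replicates = 2),
                        noise = noise_model(seed = 5), max_duration_s = 100)
  expect_identical(st$traces, st2$traces)

  expect_error(generate_study(dplyr::bind_rows(truth_row(), truth_row())),
               "Duplicate")
  empty <- generate_study(truth_row()[0, ])
  expect_equal(nrow(empty$traces), 0)
})

test_that("recorded sigma matches the generating noise law", {
  cond <- assay_conditions(E0 = 0.01, S0 = 0.5, max_duration_s = 50)
  reps <- purrr::map(1:1000, function(s) {
    generate_trace(wt_ctz(), cond, noise = noise_model(0.05, 8, seed = s),
                   background_rlu = 100)
  })
  len <- min(purrr::map_int(reps, nrow))
  mat <- do.call(rbind, purrr::map(reps, function(r) r$intensity_rlu[seq_len(len)]))
  sig <- reps[[1]]$sigma_rlu[seq_len(len)]
  z <- sweep(sweep(mat, 2, colMeans(mat)), 2, sig, "/")
  # z-scores should be standard normal: unit sd and approximate normality
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 0.15)
  expect_gt(stats::shapiro.test(as.vector(z[, 5]))$p.value, 0.001)
})
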
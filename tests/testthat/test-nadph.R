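test_that("replicate averaging drops the first run and means the rest", {
  run <- trigger_run(n_replicates = 4)
  times <- seq(0, 15, by = run$sample_interval)
  mk <- function(v, id) nadph_trace(times, rep(v, length(times)),
                                    replicate_id = id)
  same <- lapply(1:4, function(i) mk(2.5, i))
  expect_equal(average_replicates(same)$signal, same[[1]]$signal)

  consts <- Map(mk, 1:4, 1:4)
  expect_equal(unique(average_replicates(consts)$signal), 3)  # mean of 2,3,4

  short <- nadph_trace(times[-length(times)], rep(1, length(times) - 1))
  expect_error(average_replicates(list(mk(1, 1), short)), "grids differ")
  expect_error(average_replicates(list(mk(1, 1))), "at least 2")
})

test_that("photo-reducible level follows the dark-end-subtracted pulse/pre-pulse ratio", {
  tr <- constructed_nadph_trace(prepulse = 0.5, pulse_max = 1.3, dark_end = 0.1)
  expect_equal(photoreducible_level(tr), (1.3 - 0.1) / (0.5 - 0.1),
               tolerance = 1e-12)   # = 3.0
  flat <- constructed_nadph_trace(prepulse = 1, pulse_max = 1, dark_end = 1)
  expect_warning(r <- photoreducible_level(flat), "undefined")
  expect_true(is.na(r))
})

test_that("the analytic photo-reducible ratio of the generator is recovered", {
  sim <- simulate_nadph_trace(oxidation_rate = 2.0, noise_sd = 0, seed = 5)
  avg <- average_replicates(sim$traces)
  expect_equal(photoreducible_level(avg), sim$truth$photoreducible_ratio_true,
               tolerance = 1e-9)
})

test_that("photo-reducible level is shift-invariant and scale-invariant", {
  sim <- simulate_nadph_trace(oxidation_rate = 1.2, noise_sd = 0.01, seed = 9)
  tr <- average_replicates(sim$traces)
  base <- photoreducible_level(tr)
  shifted <- nadph_trace(tr$time_s, tr$signal + 5.3)
  expect_equal(photoreducible_level(shifted), base, tolerance = 1e-9)
  scaled <- nadph_trace(tr$time_s, tr$signal * 7.7)
  expect_equal(photoreducible_level(scaled), base, tolerance = 1e-9)
})

test_that("noiseless oxidation rate is recovered to 1e-6 and degenerate traces flagged", {
  # direct construction: offset 0.1, amplitude 1, rate 2
  times <- seq(0, 15, by = 0.02)
  y <- ifelse(times < 1.6, 1.1, 0.1 + 1 * exp(-2 * (times - 1.6)))
  fit <- oxidation_rate(nadph_trace(times, y))
  expect_true(fit$converged)
  expect_equal(fit$oxidation_rate, 2.0, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1.0, tolerance = 1e-6)
  expect_equal(fit$offset, 0.1, tolerance = 1e-6)
  expect_true(fit$fit_window_end > 1.6 && fit$fit_window_end <= 15)

  # strictly constant dark segment (pulse sample excluded)
  tconst <- seq(0, 15, by = 0.02)
  yconst <- ifelse(tconst < 1, 1, ifelse(tconst < 1.6, 2, 0.5))
  expect_false(oxidation_rate(nadph_trace(tconst, yconst))$converged)
})

test_that("oxidation rate is invariant to shifting and positive scaling", {
  sim <- simulate_nadph_trace(oxidation_rate = 0.7, noise_sd = 0, seed = 3)
  tr <- average_replicates(sim$traces)
  base <- oxidation_rate(tr)$oxidation_rate
  expect_equal(oxidation_rate(nadph_trace(tr$time_s, tr$signal + 4))$oxidation_rate,
               base, tolerance = 1e-9)
  expect_equal(oxidation_rate(nadph_trace(tr$time_s, tr$signal * 11))$oxidation_rate,
               base, tolerance = 1e-9)
})

test_that("median relative error over noisy replicates is below 5%", {
  errs <- vapply(1:100, function(s) {
    sim <- simulate_nadph_trace(oxidation_rate = 0.5, amplitude = 1,
                                noise_sd = 0.02, seed = s)
    fit <- oxidation_rate(average_replicates(sim$traces))
    if (fit$converged) abs(fit$oxidation_rate - 0.5) / 0.5 else NA_real_
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("faster decays flatten sooner: fit windows shrink, estimates stay ordered", {
  rates <- c(0.2, 0.5, 1, 2, 4)
  fits <- lapply(rates, function(k) {
    sim <- simulate_nadph_trace(oxidation_rate = k, noise_sd = 0, seed = 1)
    oxidation_rate(average_replicates(sim$traces))
  })
  ends <- vapply(fits, `[[`, numeric(1), "fit_window_end")
  est <- vapply(fits, `[[`, numeric(1), "oxidation_rate")
  expect_true(all(diff(ends) <= 1e-9))
  expect_true(all(diff(est) > 0))
})

test_that("analyze_nadph_run bundles averaging, level and rate", {
  sim <- simulate_nadph_trace(oxidation_rate = 1.5, noise_sd = 0.01, seed = 22)
  res <- analyze_nadph_run(sim$traces)
  expect_equal(res$oxidation$oxidation_rate, 1.5, tolerance = 0.05)
  expect_equal(res$photoreducible_level, sim$truth$photoreducible_ratio_true,
               tolerance = 0.05)
})
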
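test_that("uniform field (bound_fraction 0, no noise) is diffuse: per-cell nsd is 0", {
  f <- simulate_cell_field(5, c(128, 128), bound_fraction = 0, seed = 11)
  mask <- segment_cells(max_project(f$stack, "chlorophyll"))
  het <- heterogeneity_series(f$stack, mask)
  expect_equal(het$cells$nsd, rep(0, nrow(het$cells)))
})

test_that("per-cell total eYFP intensity is conserved across bound fractions", {
  f1 <- simulate_cell_field(12, c(256, 256), bound_fraction = 1, seed = 4)
  f0 <- simulate_cell_field(12, c(256, 256), bound_fraction = 0, seed = 4)
  mask <- segment_cells(max_project(f0$stack, "chlorophyll"))
  e1 <- get_plane(f1$stack, 1, "eyfp")
  e0 <- get_plane(f0$stack, 1, "eyfp")
  in_cell <- mask$labels > 0
  s1 <- tapply(e1[in_cell], mask$labels[in_cell], sum)
  s0 <- tapply(e0[in_cell], mask$labels[in_cell], sum)
  expect_true(max(abs(s1 - s0) / s0) < 1e-9)
})

test_that("generators are bit-identical under identical seed and parameters", {
  a <- simulate_cell_field(8, c(160, 160), bound_fraction = 0.4, noise_sd = 0.1,
                           seed = 99)
  b <- simulate_cell_field(8, c(160, 160), bound_fraction = 0.4, noise_sd = 0.1,
                           seed = 99)
  expect_identical(a$stack$pixels, b$stack$pixels)

  s1 <- simulate_nadph_trace(oxidation_rate = 1, noise_sd = 0.05, seed = 7)
  s2 <- simulate_nadph_trace(oxidation_rate = 1, noise_sd = 0.05, seed = 7)
  expect_identical(lapply(s1$traces, `[[`, "signal"),
                   lapply(s2$traces, `[[`, "signal"))

  t1 <- simulate_assay_trace(slope = 0.02, noise_sd = 0.01, seed = 3)
  t2 <- simulate_assay_trace(slope = 0.02, noise_sd = 0.01, seed = 3)
  expect_identical(t1$od340, t2$od340)
})

test_that("generator seeding does not disturb the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_cell_field(3, c(96, 96), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("impossible placements raise a placement-failure error", {
  expect_error(simulate_cell_field(500, c(96, 96), seed = 1),
               "could not place")
  expect_error(simulate_cell_field(3, c(20, 20), seed = 1), "too small")
})

test_that("default schedule gives 31 dark frames at t = 0,10,...,300 and 64 light frames", {
  sch <- acquisition_schedule()
  dark <- sch$frame_times[sch$illumination == "dark"]
  light <- sch$frame_times[sch$illumination == "light"]
  expect_equal(dark, seq(0, 300, by = 10))
  expect_length(light, floor(30 / 0.47) + 1)   # 64
  expect_true(all(diff(sch$frame_times) > 0))
})

test_that("ground-truth bound fraction follows first-order kinetics", {
  tl <- simulate_timelapse(k_assembly = 0.01, k_disassembly = 0.1,
                           n_cells = 2, seed = 1, image_shape = c(96, 96))
  b <- tl$truth$bound_fraction_series
  expect_equal(b$bound_fraction[b$time_s == 300], 1 - exp(-3),
               tolerance = 1e-12)
  expect_true(all(b$bound_fraction >= 0 & b$bound_fraction <= 1))
  expect_error(simulate_timelapse(k_assembly = 0, k_disassembly = 0.1,
                                  n_cells = 2, seed = 1),
               "strictly positive")
})

test_that("trigger run spans 15 s and the noiseless pulse is the trace maximum", {
  run <- trigger_run()
  expect_equal(run$total_duration, 15.0)
  sim <- simulate_nadph_trace(run, oxidation_rate = 0.8, noise_sd = 0, seed = 2)
  tr <- sim$traces[[1]]
  expect_equal(max(tr$time_s), 15.0, tolerance = 1e-9)
  tmax <- tr$time_s[which.max(tr$signal)]
  expect_true(tmax >= 1.0 && tmax <= 1.6)
  expect_error(simulate_nadph_trace(amplitude = -1, seed = 1), "amplitude")
  expect_error(trigger_run(sample_interval = 0.7), "sample_interval")
})

test_that("noiseless assay traces are exact: flat at slope 0, slope recovered exactly", {
  flat <- simulate_assay_trace(slope = 0, noise_sd = 0, seed = 1)
  expect_equal(diff(range(flat$od340)), 0)
  tr <- simulate_assay_trace(slope = 0.01, noise_sd = 0, seed = 1)
  act <- zwf_activity(tr)
  expect_equal(act$slope, 0.01, tolerance = 1e-12)
  expect_error(simulate_assay_trace(slope = 0.01, duration = -5, seed = 1),
               "duration")
})

test_that("ground_truth rejects invalid fractions and rates", {
  expect_error(ground_truth(data.frame(time_s = 0, bound_fraction = 1.2)),
               "\\[0,1\\]")
  expect_error(ground_truth(k_assembly = -1), "strictly positive")
})
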
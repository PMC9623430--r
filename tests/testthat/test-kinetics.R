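test_that("noiseless closed-form transitions are recovered to 1e-6", {
  t <- seq(0, 300, by = 10)
  rising <- data.frame(time_s = t, nsd = 0.3 * (1 - exp(-0.05 * t)))
  fa <- fit_transition(rising, "assembly")
  expect_true(fa$converged)
  expect_equal(fa$rate, 0.05, tolerance = 1e-6)
  expect_equal(fa$t_half, log(2) / 0.05, tolerance = 1e-6)
  expect_equal(fa$baseline, 0, tolerance = 1e-6)
  expect_equal(fa$plateau, 0.3, tolerance = 1e-6)

  tl <- seq(0, 30, by = 0.47)
  falling <- data.frame(time_s = tl, nsd = 0.3 * exp(-0.1 * tl))
  fd <- fit_transition(falling, "disassembly")
  expect_true(fd$converged)
  expect_equal(fd$rate, 0.10, tolerance = 1e-6)
})

test_that("constant traces are flagged with no rate", {
  flat <- data.frame(time_s = seq(0, 100, by = 10), nsd = rep(0.2, 11))
  f <- fit_transition(flat, "assembly")
  expect_false(f$converged)
  expect_true(is.na(f$rate))
  expect_error(fit_transition(flat[1:3, ], "assembly"), "at least 5")
})

test_that("model-free half time agrees with ln2/rate on densely sampled noiseless data", {
  tl <- seq(0, 30, by = 0.47)
  falling <- data.frame(time_s = tl, nsd = 0.3 * exp(-0.2 * tl))
  f <- fit_transition(falling, "disassembly")
  expect_lt(abs(log(2) / f$rate - f$t_half_model_free), 2 * 0.47)

  t <- seq(0, 300, by = 10)
  rising <- data.frame(time_s = t, nsd = 0.5 * (1 - exp(-0.05 * t)))
  fa <- fit_transition(rising, "assembly")
  expect_lt(abs(log(2) / fa$rate - fa$t_half_model_free), 2 * 10)
})

test_that("rates are recovered within 10% median error from noisy nsd traces", {
  errs <- c(
    vapply(1:100, function(s) {
      tr <- synthetic_transition_trace(0.030, "assembly", 0.1, seed = s)
      f <- fit_transition(tr, "assembly")
      if (f$converged) abs(f$rate - 0.030) / 0.030 else NA_real_
    }, numeric(1)),
    vapply(1:100, function(s) {
      tr <- synthetic_transition_trace(0.15, "disassembly", 0.1, seed = 1000 + s)
      f <- fit_transition(tr, "disassembly")
      if (f$converged) abs(f$rate - 0.15) / 0.15 else NA_real_
    }, numeric(1))
  )
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("GapDH2-preset assembly is fitted faster than PRK in >= 95% of pairs", {
  kg <- kinetic_preset("gapdh2")$k_assembly
  kp <- kinetic_preset("prk")$k_assembly
  expect_gt(kg, kp)
  wins <- vapply(1:200, function(s) {
    fg <- fit_transition(synthetic_transition_trace(kg, "assembly", 0.1,
                                                    seed = s), "assembly")
    fp <- fit_transition(synthetic_transition_trace(kp, "assembly", 0.1,
                                                    seed = 5000 + s), "assembly")
    fg$converged && fp$converged && fg$rate > fp$rate
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("per-cell fits are summarized by median and MAD across cells", {
  tl <- simulate_timelapse(k_assembly = 0.03, k_disassembly = 0.06,
                           n_cells = 5, seed = 2, image_shape = c(160, 160))
  mask <- segment_cells(max_project(tl$stack, "chlorophyll"))
  het <- heterogeneity_series(tl$stack, mask)
  fits <- fit_transitions(het, "assembly")
  expect_equal(nrow(fits$per_cell), 5)
  expect_equal(fits$summary$rate_median, 0.03, tolerance = 1e-6)
  expect_equal(fits$summary$rate_median,
               median(fits$per_cell$rate[fits$per_cell$converged]))
  fd <- fit_transitions(het, "disassembly")
  expect_equal(fd$summary$rate_median, 0.06, tolerance = 1e-6)
})
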
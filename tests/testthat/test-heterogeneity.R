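mask3 <- labeled_mask(matrix(c(1, 1, 1), 1, 3))

test_that("cell_stats reproduces hand-computed mean, sample SD and nsd", {
  s <- cell_stats(matrix(c(5, 5, 5), 1, 3), mask3, 1)
  expect_equal(c(s$mean_intensity, s$sd_intensity, s$nsd), c(5, 0, 0))
  s <- cell_stats(matrix(c(1, 2, 3), 1, 3), mask3, 1)
  expect_equal(c(s$mean_intensity, s$sd_intensity, s$nsd), c(2, 1, 0.5))
  s10 <- cell_stats(matrix(c(10, 20, 30), 1, 3), mask3, 1)
  expect_equal(s10$nsd, 0.5)   # scale invariance of the CV
  p <- cell_stats(matrix(c(1, 2, 3), 1, 3), mask3, 1, sd_type = "population")
  expect_equal(p$sd_intensity, sqrt(2 / 3))
})

test_that("nsd is invariant under positive rescaling of the eYFP channel", {
  f <- simulate_cell_field(6, c(160, 160), bound_fraction = 0.6,
                           noise_sd = 0.05, seed = 13)
  mask <- segment_cells(max_project(f$stack, "chlorophyll"))
  img <- get_plane(f$stack, 1, "eyfp")
  for (cc in c(0.001, 3, 1e4)) {
    for (id in seq_len(mask$n_cells)) {
      expect_equal(cell_stats(img * cc, mask, id)$nsd,
                   cell_stats(img, mask, id)$nsd, tolerance = 1e-12)
    }
  }
})

test_that("nsd is zero iff the region is perfectly uniform", {
  expect_equal(cell_stats(matrix(7, 2, 2), labeled_mask(matrix(1, 2, 2)), 1)$nsd, 0)
  img <- matrix(c(7, 7, 7, 7.001), 2, 2)
  expect_gt(cell_stats(img, labeled_mask(matrix(1, 2, 2)), 1)$nsd, 0)
})

test_that("zero-mean regions are flagged, not silently zero", {
  expect_warning(s <- cell_stats(matrix(0, 1, 3), mask3, 1), "undefined")
  expect_true(is.na(s$nsd))
  expect_false(s$nsd_defined)
  expect_error(cell_stats(matrix(1, 1, 3), labeled_mask(matrix(c(1, 0, 0), 1, 3)), 1),
               "fewer than 2")
})

test_that("heterogeneity_series equals the brute-force per-frame loop", {
  for (seed in 1:3) {
    f <- simulate_cell_field(5, c(128, 128), bound_fraction = 0.5,
                             noise_sd = 0.1, seed = seed)
    mask <- segment_cells(max_project(f$stack, "chlorophyll"))
    got <- heterogeneity_series(f$stack, mask)$cells
    want <- oracle_heterogeneity(f$stack, mask)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12)
    expect_equal(got$nsd, want$nsd, tolerance = 1e-12)
  }
})

test_that("population summary equals the brute-force mean/SD of the cell table", {
  f <- simulate_cell_field(8, c(160, 160), bound_fraction = 0.4,
                           noise_sd = 0.05, seed = 31)
  mask <- segment_cells(max_project(f$stack, "chlorophyll"))
  het <- heterogeneity_series(f$stack, mask)
  expect_equal(het$population$nsd_mean, mean(het$cells$nsd), tolerance = 1e-12)
  expect_equal(het$population$nsd_sd, sd(het$cells$nsd), tolerance = 1e-12)
})

test_that("nsd increases strictly with the bound fraction at fixed total intensity", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  nsd <- vapply(grid, function(b) {
    f <- simulate_cell_field(5, c(160, 160), bound_fraction = b, seed = 7)
    mask <- segment_cells(max_project(f$stack, "chlorophyll"))
    mean(heterogeneity_series(f$stack, mask)$cells$nsd)
  }, numeric(1))
  expect_true(all(diff(nsd) > 0))
})

test_that("noiseless dark-phase nsd traces are non-decreasing", {
  tl <- simulate_timelapse(k_assembly = 0.02, k_disassembly = 0.1,
                           n_cells = 4, seed = 17, image_shape = c(160, 160))
  mask <- segment_cells(max_project(tl$stack, "chlorophyll"))
  het <- heterogeneity_series(tl$stack, mask)
  dark <- het$cells[het$cells$illumination == "dark", ]
  for (id in unique(dark$cell_id))
    expect_true(all(diff(dark$nsd[dark$cell_id == id]) >= -1e-12))
})

test_that("an empty mask yields an empty result with a warning", {
  f <- simulate_cell_field(3, c(96, 96), seed = 2)
  empty <- labeled_mask(matrix(0L, 96, 96))
  expect_warning(het <- heterogeneity_series(f$stack, empty), "empty mask")
  expect_equal(nrow(het$cells), 0)
})
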
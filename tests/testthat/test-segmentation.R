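make_stack <- function(frames) {
  px <- array(0, dim = c(length(frames), 2, nrow(frames[[1]]), ncol(frames[[1]])))
  for (f in seq_along(frames)) {
    px[f, 1, , ] <- frames[[f]]
    px[f, 2, , ] <- frames[[f]]
  }
  image_stack(px, frame_times = seq_along(frames),
              channel_roles = c(chlorophyll = 1L, eyfp = 2L),
              illumination = rep("dark", length(frames)))
}

test_that("max projection takes the per-pixel maximum across frames", {
  st <- make_stack(list(matrix(c(0, 1), 1, 2), matrix(c(2, 0), 1, 2)))
  expect_equal(max_project(st, "chlorophyll"), matrix(c(2, 1), 1, 2))
  one <- make_stack(list(matrix(1:6, 2, 3)))
  expect_equal(max_project(one, "chlorophyll"), matrix(1:6, 2, 3))
  rs <- random_stack(5, seed = 42)
  expect_equal(max_project(rs, "eyfp"), oracle_max_project(rs, "eyfp"),
               tolerance = 1e-15)
})

test_that("disjoint bright regions are counted and blank images give zero cells", {
  img <- matrix(0, 60, 60)
  img[10:20, 10:20] <- 1
  img[35:45, 35:45] <- 1
  expect_equal(segment_cells(img, min_area = 10)$n_cells, 2)
  expect_equal(segment_cells(matrix(0, 30, 30))$n_cells, 0)
  expect_error(segment_cells(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("synthetic fields are recovered cell for cell with high overlap", {
  f <- simulate_cell_field(20, c(512, 512), bound_fraction = 0.5,
                           noise_sd = 0.02, seed = 8)
  mask <- segment_cells(max_project(f$stack, "chlorophyll"), min_area = 50)
  expect_equal(mask$n_cells, 20)
  cells <- f$truth$cells
  nr <- 512
  hit <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    lab <- mask$labels[round(cells$center_row[i]), round(cells$center_col[i])]
    expect_gt(lab, 0)
    hit[i] <- lab
  }
  expect_equal(sort(hit), 1:20)   # each center in exactly one distinct label
  # Jaccard of each recovered region against its ground-truth ellipse
  for (i in seq_len(nrow(cells))) {
    g <- cells[i, ]
    rows <- rep(1:nr, times = nr); cols <- rep(1:nr, each = nr)
    ref <- which(((rows - g$center_row) / g$radius_row)^2 +
                   ((cols - g$center_col) / g$radius_col)^2 <= 1)
    expect_gte(jaccard_overlap(mask, hit[i], ref), 0.8)
  }
})

test_that("segmentation is invariant to positive rescaling of the image", {
  f <- simulate_cell_field(10, c(256, 256), bound_fraction = 0.3,
                           noise_sd = 0.05, seed = 21)
  img <- max_project(f$stack, "chlorophyll")
  m1 <- segment_cells(img)
  m2 <- segment_cells(img * 37.5)
  expect_identical(m1$labels, m2$labels)
})

test_that("the area filter drops regions below min_area", {
  img <- matrix(0, 40, 40)
  img[5:6, 5:6] <- 1          # 4 px
  img[20:30, 20:30] <- 1      # 121 px
  m <- segment_cells(img, min_area = 50)
  expect_equal(m$n_cells, 1)
  expect_true(all(region_table(m)$area >= 50))
})

test_that("labels come back contiguous, in raster order of their first pixel", {
  img <- matrix(0, 50, 50)
  img[30:40, 2:10] <- 1   # lower-left
  img[2:10, 30:40] <- 1   # upper-right (earlier in row-major raster order)
  m <- segment_cells(img, min_area = 10)
  expect_equal(m$n_cells, 2)
  tab <- region_table(m)
  expect_lt(tab$centroid_row[1], tab$centroid_row[2])
  expect_error(labeled_mask(matrix(c(0, 2), 1, 2)), "contiguous")
})
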
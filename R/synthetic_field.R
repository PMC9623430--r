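#' Ground truth attached to synthetic data
#'
#' All generators return, next to the data, a `ground_truth` object recording
#' the parameters the downstream estimators are supposed to recover.
#'
#' @param bound_fraction_series data.frame with columns `time_s`,
#'   `bound_fraction` (each fraction in \[0,1\]).
#' @param cells data.frame of cell geometry (`cell`, `center_row`,
#'   `center_col`, `radius_row`, `radius_col`), or `NULL`.
#' @param spots_per_cell positive integer or `NA`.
#' @param k_assembly,k_disassembly first-order rate constants (s^-1) or `NA`.
#' @param oxidation_rate_true NAD(P)H dark oxidation rate (s^-1) or `NA`.
#' @param photoreducible_ratio_true analytic photo-reducible level or `NA`.
#' @param extra named list of additional generator internals.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(bound_fraction_series = NULL, cells = NULL,
                         spots_per_cell = NA_integer_,
                         k_assembly = NA_real_, k_disassembly = NA_real_,
                         oxidation_rate_true = NA_real_,
                         photoreducible_ratio_true = NA_real_,
                         extra = list()) {
  if (!is.null(bound_fraction_series)) {
    b <- bound_fraction_series$bound_fraction
    if (any(b < 0 | b > 1)) stop("bound fractions must lie in [0,1]")
  }
  for (r in c(k_assembly, k_disassembly, oxidation_rate_true))
    if (!is.na(r) && r <= 0) stop("rates must be strictly positive where defined")
  if (!is.na(spots_per_cell) && spots_per_cell < 1)
    stop("'spots_per_cell' must be a positive integer")
  structure(
    list(bound_fraction_series = bound_fraction_series, cells = cells,
         spots_per_cell = spots_per_cell, k_assembly = k_assembly,
         k_disassembly = k_disassembly, oxidation_rate_true = oxidation_rate_true,
         photoreducible_ratio_true = photoreducible_ratio_true, extra = extra),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  if (!is.null(x$cells)) cat(sprintf("  %d cell(s), %s spot(s)/cell\n",
                                     nrow(x$cells), x$spots_per_cell))
  if (!is.na(x$k_assembly))
    cat(sprintf("  k_assembly = %g /s, k_disassembly = %g /s\n",
                x$k_assembly, x$k_disassembly))
  if (!is.na(x$oxidation_rate_true))
    cat(sprintf("  oxidation rate = %g /s, photo-reducible ratio = %g\n",
                x$oxidation_rate_true, x$photoreducible_ratio_true))
  invisible(x)
}

# Draw non-overlapping elliptical cells and per-cell spot centers.
# All randomness happens here so that the rendered field geometry is
# independent of bound_fraction (needed for intensity-conservation and
# monotonicity properties). Caller is responsible for seeding.
draw_field_geometry <- function(n_cells, image_shape, spots_per_cell,
                                radius_range = c(8, 12), spot_spread = 0.6) {
  nr <- image_shape[1]; nc <- image_shape[2]
  rmax <- radius_range[2]
  margin <- rmax + 2
  if (n_cells > 0 && (nr < 2 * margin + 2 || nc < 2 * margin + 2))
    stop("image too small to place cells")
  centers <- matrix(numeric(0), 0, 2)
  radii <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  max_attempts <- max(200L, 200L * n_cells)
  while (nrow(centers) < n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf("could not place %d non-overlapping cells in a %d x %d image",
                   n_cells, nr, nc))
    cy <- runif(1, margin + 1, nr - margin)
    cx <- runif(1, margin + 1, nc - margin)
    ry <- runif(1, radius_range[1], radius_range[2])
    rx <- runif(1, radius_range[1], radius_range[2])
    ok <- TRUE
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
      ok <- all(d > pmax(radii[, 1], radii[, 2]) + max(ry, rx) + 2)
    }
    if (ok) {
      centers <- rbind(centers, c(cy, cx))
      radii <- rbind(radii, c(ry, rx))
    }
  }
  spot_centers <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    # uniform points in the unit disk, mapped into the shrunken ellipse
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < spots_per_cell) {
      p <- runif(2, -1, 1)
      if (sum(p^2) <= 1) pts <- rbind(pts, p)
    }
    spot_centers[[i]] <- cbind(
      row = centers[i, 1] + spot_spread * radii[i, 1] * pts[, 1],
      col = centers[i, 2] + spot_spread * radii[i, 2] * pts[, 2]
    )
  }
  list(
    cells = if (n_cells > 0)
      data.frame(cell = seq_len(n_cells), center_row = centers[, 1],
                 center_col = centers[, 2], radius_row = radii[, 1],
                 radius_col = radii[, 2])
    else data.frame(cell = integer(0), center_row = numeric(0),
                    center_col = numeric(0), radius_row = numeric(0),
                    radius_col = numeric(0)),
    spot_centers = spot_centers,
    image_shape = image_shape
  )
}

# Linear pixel indices and coordinates of one cell's ellipse interior.
cell_pixels <- function(geom, i) {
  g <- geom$cells[i, ]
  nr <- geom$image_shape[1]; nc <- geom$image_shape[2]
  rows <- max(1, floor(g$center_row - g$radius_row)):min(nr, ceiling(g$center_row + g$radius_row))
  cols <- max(1, floor(g$center_col - g$radius_col)):min(nc, ceiling(g$center_col + g$radius_col))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  inside <- ((rr - g$center_row) / g$radius_row)^2 +
    ((cc - g$center_col) / g$radius_col)^2 <= 1
  list(row = rr[inside], col = cc[inside],
       idx = rr[inside] + (cc[inside] - 1L) * nr)
}

# Render one two-channel frame. The per-cell total eYFP intensity is exactly
# `total_intensity` for every bound_fraction: the diffuse pool carries
# (1-b)*T spread evenly over the cell, each of the n spots carries b*T/n via
# a Gaussian kernel normalized over the cell's own pixels.
render_field <- function(geom, bound_fraction, total_intensity = 1000,
                         chl_level = 0.8, spot_sigma = 1.5) {
  nr <- geom$image_shape[1]; nc <- geom$image_shape[2]
  chl <- matrix(0, nr, nc)
  eyfp <- matrix(0, nr, nc)
  nsp <- if (length(geom$spot_centers) > 0) nrow(geom$spot_centers[[1]]) else 0L
  for (i in seq_len(nrow(geom$cells))) {
    px <- cell_pixels(geom, i)
    chl[px$idx] <- chl_level
    eyfp[px$idx] <- eyfp[px$idx] +
      (1 - bound_fraction) * total_intensity / length(px$idx)
    if (bound_fraction > 0 && nsp > 0) {
      sc <- geom$spot_centers[[i]]
      for (j in seq_len(nsp)) {
        k <- exp(-((px$row - sc[j, "row"])^2 + (px$col - sc[j, "col"])^2) /
                   (2 * spot_sigma^2))
        eyfp[px$idx] <- eyfp[px$idx] +
          bound_fraction * total_intensity / nsp * k / sum(k)
      }
    }
  }
  list(chl = chl, eyfp = eyfp)
}

#' Simulate a single two-channel field of cells
#'
#' Generates one frame of compact bright elliptical cells on a dark
#' background (chlorophyll channel) with an eYFP channel in which a fraction
#' `bound_fraction` of each cell's fixed total intensity is concentrated into
#' diffraction-limited punctate spots (Gaussian kernels) and the remainder is
#' spread evenly across the cell — mimicking a fluorescence-tagged enzyme
#' partitioned between a CP12-bound punctate pool and a free diffuse pool.
#'
#' @param n_cells number of cells to place (non-overlapping; an error is
#'   raised after bounded retries if they do not fit).
#' @param image_shape integer c(rows, cols) of the canvas, default 512 x 512.
#' @param bound_fraction fraction of eYFP intensity in spots, in \[0,1\].
#' @param spots_per_cell number of punctate spots per cell (1-5 is typical).
#' @param noise_sd additive Gaussian noise SD (intensity units), clipped at 0.
#' @param seed integer RNG seed (mandatory; no global state is consumed).
#' @param total_intensity per-cell total eYFP intensity (conserved across
#'   `bound_fraction`).
#' @param chl_level chlorophyll intensity inside cells.
#' @param spot_sigma Gaussian spot kernel SD in pixels.
#' @param radius_range cell ellipse radii range in pixels.
#' @return A list with elements `stack` (single-frame [image_stack()];
#'   channel 1 chlorophyll, channel 2 eYFP) and `truth` ([ground_truth()]).
#' @export
simulate_cell_field <- function(n_cells, image_shape = c(512, 512),
                                bound_fraction = 0, spots_per_cell = 3,
                                noise_sd = 0, seed,
                                total_intensity = 1000, chl_level = 0.8,
                                spot_sigma = 1.5, radius_range = c(8, 12)) {
  if (n_cells < 0) stop("'n_cells' must be >= 0")
  if (bound_fraction < 0 || bound_fraction > 1)
    stop("'bound_fraction' must lie in [0,1]")
  if (spots_per_cell < 1) stop("'spots_per_cell' must be >= 1")
  with_seed(seed, {
    geom <- draw_field_geometry(n_cells, image_shape, spots_per_cell,
                                radius_range = radius_range)
    f <- render_field(geom, bound_fraction, total_intensity, chl_level,
                      spot_sigma)
    if (noise_sd > 0) {
      f$chl <- pmax(f$chl + rnorm(length(f$chl), sd = noise_sd), 0)
      f$eyfp <- pmax(f$eyfp + rnorm(length(f$eyfp), sd = noise_sd), 0)
    }
    px <- array(0, dim = c(1, 2, image_shape[1], image_shape[2]))
    px[1, 1, , ] <- f$chl
    px[1, 2, , ] <- f$eyfp
    stack <- image_stack(px, frame_times = 0,
                         channel_roles = c(chlorophyll = 1L, eyfp = 2L),
                         illumination = "dark")
    truth <- ground_truth(
      bound_fraction_series = data.frame(time_s = 0,
                                         bound_fraction = bound_fraction),
      cells = geom$cells, spots_per_cell = as.integer(spots_per_cell),
      extra = list(spot_centers = geom$spot_centers,
                   total_intensity = total_intensity,
                   image_shape = image_shape)
    )
    list(stack = stack, truth = truth)
  })
}
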
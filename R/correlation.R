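#' Assemble a light-series point table
#'
#' One row per investigated actinic light intensity: the per-cell nsd summary
#' from fixed-cell images and the NAD(P)H oxidation rate measured at the same
#' intensity.
#'
#' @param light_intensity umol photons m^-2 s^-1 (0 = darkness).
#' @param nsd_mean,nsd_sd mean and SD over cells of the per-cell nsd.
#' @param oxidation_rate fitted dark oxidation rate (s^-1).
#' @param n_cells number of cells behind each nsd summary.
#' @return data.frame of class `light_points`.
#' @export
light_points <- function(light_intensity, nsd_mean, nsd_sd = NA_real_,
                         oxidation_rate = NA_real_, n_cells = NA_integer_) {
  if (any(light_intensity < 0)) stop("'light_intensity' must be >= 0")
  if (any(!is.na(n_cells) & n_cells < 1)) stop("'n_cells' must be >= 1")
  structure(
    data.frame(light_intensity = light_intensity, nsd_mean = nsd_mean,
               nsd_sd = nsd_sd, oxidation_rate = oxidation_rate,
               n_cells = n_cells),
    class = c("light_points", "data.frame")
  )
}

#' Linear heterogeneity-versus-oxidation-rate regression
#'
#' Ordinary least squares of the per-intensity mean nsd against the NAD(P)H
#' oxidation rate measured at the same light intensity — the cross-modal
#' relation linking complex formation to the cellular redox state.
#'
#' @param points a `light_points` data.frame (or any data.frame with columns
#'   `nsd_mean` and `oxidation_rate`).
#' @return An object of class `light_linear_fit` with `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying `lm` fit.
#' @export
light_series_regression <- function(points) {
  d <- points[is.finite(points$nsd_mean) & is.finite(points$oxidation_rate), ]
  if (nrow(d) < 2) stop("need at least 2 points with finite values")
  if (sd(d$oxidation_rate) == 0) stop("zero variance in oxidation rate")
  if (nrow(d) == 2)
    warning("only 2 points: regression is a perfect fit by construction")
  fit <- lm(nsd_mean ~ oxidation_rate, data = d)
  ssr <- sum(residuals(fit)^2)
  sst <- sum((d$nsd_mean - mean(d$nsd_mean))^2)
  r2 <- if (nrow(d) == 2 || sst == 0) 1 else 1 - ssr / sst
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n = nrow(d), lm = fit),
    class = "light_linear_fit"
  )
}

#' @export
print.light_linear_fit <- function(x, ...) {
  cat(sprintf("<light_linear_fit> nsd = %.4g + %.4g * rate, r^2 = %.4f, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.light_linear_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.light_linear_fit <- function(object, oxidation_rate, ...) {
  object$intercept + object$slope * oxidation_rate
}

#' Exponential light response of complex fluorescence
#'
#' Fits `nsd(I) = c0 + a * exp(-b * I)` with a, b > 0 to the per-intensity
#' nsd means: complex fluorescence rises exponentially with decreasing light
#' intensity towards its maximum in complete darkness (I = 0).
#'
#' @param points a `light_points` data.frame; needs >= 4 points spanning
#'   darkness (I = 0) and light (I > 0).
#' @return An object of class `light_exp_fit` with `a`, `b`, `c0`,
#'   `converged`, `rmse`, `n`. Data that increase with light intensity
#'   contradict the model and come back flagged (`converged = FALSE`).
#' @export
exp_light_response <- function(points) {
  d <- points[is.finite(points$nsd_mean) & is.finite(points$light_intensity), ]
  if (nrow(d) < 4) stop("need at least 4 points")
  if (!any(d$light_intensity == 0) || !any(d$light_intensity > 0))
    stop("points must span darkness (I = 0) and light (I > 0)")
  I <- d$light_intensity
  y <- d$nsd_mean

  flagged <- function(reason) {
    structure(list(a = NA_real_, b = NA_real_, c0 = NA_real_,
                   converged = FALSE, rmse = NA_real_, n = nrow(d),
                   reason = reason),
              class = "light_exp_fit")
  }
  if (sd(y) == 0) return(flagged("flat response"))
  # monotone increase of nsd with light contradicts a decaying response
  if (cor(I, y) > 0 && y[which.min(I)] <= y[which.max(I)])
    return(flagged("nsd increases with light intensity"))

  start <- list(c0 = min(y), a = max(y) - min(y),
                b = 1 / max(mean(I[I > 0]), .Machine$double.eps))
  fit <- lm_fit(function(p) p$c0 + p$a * exp(-p$b * I), y, start,
                lower = c(c0 = -Inf, a = 1e-12, b = 1e-12))
  if (is.null(fit)) return(flagged("fit failure"))
  p <- fit$par
  if (p[["a"]] <= 1e-10 || p[["b"]] <= 1e-10)
    return(flagged("degenerate (flat) fit"))
  structure(
    list(a = p[["a"]], b = p[["b"]], c0 = p[["c0"]],
         converged = TRUE, rmse = fit$rmse, n = nrow(d),
         reason = NULL),
    class = "light_exp_fit"
  )
}

#' @export
print.light_exp_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<light_exp_fit> nsd(I) = %.4g + %.4g * exp(-%.4g * I), n = %d\n",
                x$c0, x$a, x$b, x$n))
  else cat(sprintf("<light_exp_fit> NOT converged (%s)\n", x$reason))
  invisible(x)
}

#' @export
coef.light_exp_fit <- function(object, ...) {
  c(c0 = object$c0, a = object$a, b = object$b)
}

#' @export
predict.light_exp_fit <- function(object, light_intensity, ...) {
  if (!object$converged) stop("fit did not converge")
  object$c0 + object$a * exp(-object$b * light_intensity)
}

#' Simulate a full light-intensity study
#'
#' End-to-end synthetic analogue of a fixed-cell light series: at each
#' actinic intensity the true bound fraction follows an exponential light
#' response `b(I) = b_dark_offset + b_amplitude * exp(-b_decay * I)` and the
#' true NAD(P)H oxidation rate is linearly coupled to it,
#' `rate(I) = rate_at_zero + coupling * b(I)` (negative coupling: the more
#' enzyme is sequestered, the slower the dark re-oxidation). For each
#' intensity a cell field is generated, segmented and measured, and a
#' replicate NAD(P)H series is generated and fitted, yielding one
#' `light_points` row per intensity.
#'
#' @param intensities actinic intensities (umol photons m^-2 s^-1, include 0
#'   for darkness).
#' @param n_cells cells per field.
#' @param image_shape field canvas in pixels.
#' @param run a [trigger_run()] for the NAD(P)H side.
#' @param response list(b_dark_offset, b_amplitude, b_decay) for b(I).
#' @param coupling list(rate_at_zero, slope): oxidation rate per bound
#'   fraction.
#' @param noise_frac noise level as a fraction of the relevant scale (diffuse
#'   eYFP level for images, pulse amplitude for traces).
#' @param seed integer RNG seed.
#' @param min_area segmentation area filter.
#' @return List with `points` (a `light_points` table), `truth` (per-intensity
#'   true bound fractions and rates, and the coupling), and `details`.
#' @export
simulate_light_study <- function(intensities = c(0, 25, 50, 100, 200, 400),
                                 n_cells = 20, image_shape = c(256, 256),
                                 run = trigger_run(),
                                 response = list(b_dark_offset = 0.05,
                                                 b_amplitude = 0.75,
                                                 b_decay = 0.02),
                                 coupling = list(rate_at_zero = 2.2,
                                                 slope = -2.25),
                                 noise_frac = 0.05, seed, min_area = 50) {
  b_true <- response$b_dark_offset +
    response$b_amplitude * exp(-response$b_decay * intensities)
  rate_true <- coupling$rate_at_zero + coupling$slope * b_true
  if (any(rate_true <= 0)) stop("coupling yields non-positive oxidation rates")
  total_intensity <- 1000
  rows <- vector("list", length(intensities))
  for (i in seq_along(intensities)) {
    seed_i <- seed * 1000L + i
    diffuse_level <- total_intensity * (1 - b_true[i]) / (pi * 10^2)
    fld <- simulate_cell_field(
      n_cells = n_cells, image_shape = image_shape,
      bound_fraction = b_true[i], noise_sd = noise_frac * diffuse_level,
      seed = seed_i, total_intensity = total_intensity)
    mask <- segment_cells(max_project(fld$stack, "chlorophyll"),
                          min_area = min_area)
    het <- heterogeneity_series(fld$stack, mask)
    amp <- 1
    sim <- simulate_nadph_trace(run = run, baseline = 2, amplitude = amp,
                                oxidation_rate = rate_true[i],
                                steady_offset = 1.5,
                                noise_sd = noise_frac * amp,
                                seed = seed_i + 500L,
                                light_intensity = intensities[i])
    res <- analyze_nadph_run(sim$traces)
    rows[[i]] <- data.frame(
      light_intensity = intensities[i],
      nsd_mean = het$population$nsd_mean[1],
      nsd_sd = het$population$nsd_sd[1],
      oxidation_rate = res$oxidation$oxidation_rate,
      n_cells = het$population$n_cells[1],
      photoreducible_level = res$photoreducible_level
    )
  }
  pts <- do.call(rbind, rows)
  list(
    points = structure(pts, class = c("light_points", "data.frame")),
    truth = list(bound_fraction = b_true, oxidation_rate = rate_true,
                 coupling = coupling, response = response),
    details = list(intensities = intensities, n_cells = n_cells,
                   noise_frac = noise_frac, seed = seed)
  )
}
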
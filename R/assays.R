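#' Glucose 6-phosphate dehydrogenase (Zwf) activity from an OD340 trace
#'
#' NADPH produced by the Zwf reaction absorbs at 340 nm, so the enzyme
#' activity is the initial linear rate of OD340 increase after substrate
#' addition. The estimator scans all `window_minutes`-long spans of the
#' post-substrate segment, keeps the one with the best linear fit (largest
#' R^2), and converts its slope to a specific activity via Beer-Lambert:
#'
#'   rate (mM/min) = slope (OD/min) / (epsilon * path length),
#'   activity (nmol min^-1 mg^-1) = rate * well volume * 1e6 / protein mass.
#'
#' @param trace an [assay_trace()] (times in minutes, `substrate_added_at`
#'   and the well metadata carried as attributes).
#' @param window_minutes length of the linear window (default 10 min).
#' @param epsilon_mM_cm molar extinction coefficient of NADPH at 340 nm
#'   (default 6.22 mM^-1 cm^-1).
#' @return An object of class `zwf_activity` with `activity`
#'   (nmol NADPH min^-1 mg^-1 protein), `slope` (OD/min), `window` (min),
#'   `r_squared`. A negative best slope yields activity 0 with a warning.
#' @export
zwf_activity <- function(trace, window_minutes = 10, epsilon_mM_cm = 6.22) {
  stopifnot(inherits(trace, "assay_trace"))
  t_add <- attr(trace, "substrate_added_at")
  if (is.null(t_add) || !any(trace$time_min < t_add))
    stop("missing baseline segment before substrate addition")
  post <- trace[trace$time_min >= t_add, ]
  if (nrow(post) < 3 || max(post$time_min) - min(post$time_min) < window_minutes)
    stop("post-substrate segment shorter than the fit window")
  t <- post$time_min
  y <- post$od340
  starts <- which(t <= max(t) - window_minutes)
  best <- NULL
  for (i in starts) {
    j <- which(t >= t[i] & t <= t[i] + window_minutes + 1e-9)
    if (length(j) < 3) next
    f <- lm(y[j] ~ t[j])
    ssr <- sum(residuals(f)^2)
    sst <- sum((y[j] - mean(y[j]))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 1   # flat window: perfectly linear
    cand <- list(slope = unname(coef(f)[2]), r2 = r2,
                 window = c(t[i], t[max(j)]))
    if (is.null(best) || r2 > best$r2 ||
        (r2 == best$r2 && abs(cand$slope) > abs(best$slope)))
      best <- cand
  }
  slope <- best$slope
  if (slope < 0) {
    warning("negative OD340 slope; activity reported as 0")
    slope_eff <- 0
  } else slope_eff <- slope
  path <- attr(trace, "path_length_cm")
  vol <- attr(trace, "well_volume_l")
  mg <- attr(trace, "protein_mass_mg")
  rate_mM_min <- slope_eff / (epsilon_mM_cm * path)    # mmol L^-1 min^-1
  nmol_min <- rate_mM_min * vol * 1e6                  # mM * L = mmol -> nmol
  structure(
    list(activity = nmol_min / mg, slope = slope, window = best$window,
         r_squared = best$r2, epsilon_mM_cm = epsilon_mM_cm,
         path_length_cm = path, well_volume_l = vol, protein_mass_mg = mg),
    class = "zwf_activity"
  )
}

#' @export
print.zwf_activity <- function(x, ...) {
  cat(sprintf("<zwf_activity> %.4g nmol NADPH min^-1 mg^-1 protein\n",
              x$activity))
  cat(sprintf("  slope = %.4g OD/min over [%.1f, %.1f] min (r^2 = %.4f)\n",
              x$slope, x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

#' Ratio report between two activity measurements
#'
#' Expresses paired comparisons (light vs dark extracts, with vs without
#' DTT) as a simple activity ratio.
#'
#' @param numerator,denominator `zwf_activity` objects or plain numerics.
#' @return Single numeric ratio.
#' @export
activity_ratio <- function(numerator, denominator) {
  val <- function(x) if (inherits(x, "zwf_activity")) x$activity else as.numeric(x)
  a <- val(numerator); b <- val(denominator)
  if (b == 0) stop("denominator activity is 0")
  a / b
}

#' Linear calibration curve
#'
#' Least-squares line through (concentration, absorbance) standards, not
#' forced through the origin (colorimetric assays typically have a nonzero
#' blank).
#'
#' @param concentration,absorbance numeric vectors of standards (>= 2 points).
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `range` (the calibrated concentration range) and the points.
#' @export
calibration_curve <- function(concentration, absorbance) {
  if (length(concentration) < 2 || length(concentration) != length(absorbance))
    stop("need >= 2 (concentration, absorbance) pairs")
  fit <- lm(absorbance ~ concentration)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be > 0")
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         range = range(concentration),
         points = data.frame(concentration = concentration,
                             absorbance = absorbance)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> A = %.4g + %.4g * c, range [%g, %g]\n",
              x$intercept, x$slope, x$range[1], x$range[2]))
  invisible(x)
}

#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  object$intercept + object$slope * concentration
}

#' Concentrations from absorbances via a calibration curve
#'
#' Inverts the calibration line: concentration = (A - intercept) / slope.
#' Values outside the calibrated concentration range are still returned but
#' flagged as extrapolations.
#'
#' @param absorbances numeric vector.
#' @param curve a [calibration_curve()].
#' @return data.frame with columns `absorbance`, `concentration`,
#'   `extrapolated`.
#' @export
quantify_from_calibration <- function(absorbances, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (absorbances - curve$intercept) / curve$slope
  tol <- 1e-9 * max(1, diff(curve$range))   # boundary values are in range
  data.frame(absorbance = absorbances, concentration = conc,
             extrapolated = conc < curve$range[1] - tol |
               conc > curve$range[2] + tol)
}
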
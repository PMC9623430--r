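#' Fit assembly or disassembly kinetics to one heterogeneity trace
#'
#' Least-squares fit of a monoexponential transition
#' `y(t) = plateau + (baseline - plateau) * exp(-rate * (t - t0))`
#' to the nsd values of one illumination phase, where `t0` is the first time
#' point of the phase. Assembly fits the dark phase (nsd rising towards a
#' plateau), disassembly the light phase (nsd decaying). A model-free half
#' time — the first time the trace crosses the midpoint between the medians
#' of its first and last three points — is reported alongside so that
#' conclusions never rest on the functional form.
#'
#' @param trace data.frame with columns `time_s` and `nsd` (as returned by
#'   [cell_trace()]), optionally with an `illumination` column used to
#'   restrict to the relevant phase.
#' @param direction `"assembly"` (dark phase) or `"disassembly"` (light phase).
#' @param rate_bounds allowed rate range in s^-1.
#' @return An object of class `transition_fit` with elements `direction`,
#'   `rate`, `plateau`, `baseline`, `t_half` (ln 2 / rate),
#'   `t_half_model_free`, `fit_window`, `rmse`, `converged`, `n`. A constant
#'   trace or a failed fit returns `converged = FALSE` with `rate = NA` and
#'   only the model-free half time.
#' @export
fit_transition <- function(trace, direction = c("assembly", "disassembly"),
                           rate_bounds = c(1e-5, 10)) {
  direction <- match.arg(direction)
  stopifnot(all(c("time_s", "nsd") %in% names(trace)))
  if ("illumination" %in% names(trace)) {
    phase <- if (direction == "assembly") "dark" else "light"
    trace <- trace[trace$illumination == phase, ]
  }
  trace <- trace[is.finite(trace$nsd), ]
  t <- trace$time_s
  y <- trace$nsd
  if (length(t) < 5) stop("need at least 5 points in the phase")
  t0 <- t[1]
  window <- c(t0, t[length(t)])
  duration <- diff(window)

  med_start <- median(head(y, 3))
  med_end <- median(tail(y, 3))
  mid <- (med_start + med_end) / 2
  t_half_mf <- model_free_crossing(t, y, mid, rising = med_end > med_start) - t0

  flagged <- function(reason) {
    structure(list(direction = direction, rate = NA_real_, plateau = NA_real_,
                   baseline = NA_real_, t_half = NA_real_,
                   t_half_model_free = t_half_mf, fit_window = window,
                   rmse = NA_real_, converged = FALSE, n = length(t),
                   reason = reason),
              class = "transition_fit")
  }
  if (sd(y) == 0) return(flagged("constant trace"))

  start <- list(plateau = mean(tail(y, 3)), baseline = mean(head(y, 3)),
                rate = 3 / duration)
  fit <- lm_fit(
    function(p) p$plateau + (p$baseline - p$plateau) * exp(-p$rate * (t - t0)),
    y, start,
    lower = c(plateau = -Inf, baseline = -Inf, rate = rate_bounds[1]),
    upper = c(plateau = Inf, baseline = Inf, rate = rate_bounds[2]))
  if (is.null(fit)) return(flagged("fit failure"))
  p <- fit$par
  if (!is.finite(p[["rate"]]) || p[["rate"]] <= 0)
    return(flagged("non-positive rate"))
  structure(
    list(direction = direction, rate = p[["rate"]],
         plateau = p[["plateau"]], baseline = p[["baseline"]],
         t_half = log(2) / p[["rate"]], t_half_model_free = t_half_mf,
         fit_window = window,
         rmse = fit$rmse, converged = TRUE,
         n = length(t), reason = NULL, t0 = t0),
    class = "transition_fit"
  )
}

# First crossing of level `mid` by linear interpolation; NA if never crossed.
model_free_crossing <- function(t, y, mid, rising = TRUE) {
  hit <- if (rising) y >= mid else y <= mid
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(t[1])
  f <- (mid - y[i - 1]) / (y[i] - y[i - 1])
  t[i - 1] + f * (t[i] - t[i - 1])
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf("<transition_fit> %s, n = %d\n", x$direction, x$n))
  if (x$converged) {
    cat(sprintf("  rate = %.5g /s (t1/2 = %.4g s), baseline = %.4g, plateau = %.4g\n",
                x$rate, x$t_half, x$baseline, x$plateau))
    cat(sprintf("  rmse = %.3g, model-free t1/2 = %.4g s\n",
                x$rmse, x$t_half_model_free))
  } else {
    cat(sprintf("  NOT converged (%s); model-free t1/2 = %.4g s\n",
                x$reason, x$t_half_model_free))
  }
  invisible(x)
}

#' @export
coef.transition_fit <- function(object, ...) {
  c(rate = object$rate, baseline = object$baseline, plateau = object$plateau)
}

#' @export
predict.transition_fit <- function(object, times, ...) {
  if (!object$converged) stop("fit did not converge")
  object$plateau + (object$baseline - object$plateau) *
    exp(-object$rate * (times - object$t0))
}

#' Fit transition kinetics for every cell and summarize
#'
#' Runs [fit_transition()] on each cell of an [heterogeneity_series()] result
#' and summarizes the converged rates by median and MAD across cells (robust
#' to segmentation outliers).
#'
#' @param traces an `nsd_traces` object.
#' @param direction passed to [fit_transition()].
#' @param ... further arguments for [fit_transition()].
#' @return An object of class `transition_fits`: list with `per_cell`
#'   (data.frame of per-cell parameters) and `summary` (median/MAD of rate
#'   and half time over converged fits).
#' @export
fit_transitions <- function(traces, direction = c("assembly", "disassembly"),
                            ...) {
  direction <- match.arg(direction)
  stopifnot(inherits(traces, "nsd_traces"))
  ids <- sort(unique(traces$cells$cell_id))
  fits <- lapply(ids, function(id)
    fit_transition(cell_trace(traces, id), direction = direction, ...))
  per_cell <- data.frame(
    cell_id = ids,
    rate = vapply(fits, function(f) f$rate, numeric(1)),
    baseline = vapply(fits, function(f) f$baseline, numeric(1)),
    plateau = vapply(fits, function(f) f$plateau, numeric(1)),
    t_half = vapply(fits, function(f) f$t_half, numeric(1)),
    t_half_model_free = vapply(fits, function(f) f$t_half_model_free, numeric(1)),
    rmse = vapply(fits, function(f) f$rmse, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  conv <- per_cell[per_cell$converged, ]
  structure(
    list(per_cell = per_cell,
         summary = data.frame(
           direction = direction, n_cells = nrow(per_cell),
           n_converged = nrow(conv),
           rate_median = median(conv$rate), rate_mad = mad(conv$rate),
           t_half_median = median(conv$t_half), t_half_mad = mad(conv$t_half)),
         fits = fits),
    class = "transition_fits"
  )
}

#' @export
print.transition_fits <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<transition_fits> %s: %d/%d cells converged\n",
              s$direction, s$n_converged, s$n_cells))
  cat(sprintf("  rate median = %.5g /s (MAD %.3g), t1/2 median = %.4g s\n",
              s$rate_median, s$rate_mad, s$t_half_median))
  invisible(x)
}
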
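#' Average replicate NAD(P)H traces, dropping the first run
#'
#' The first run of a replicate series is treated as a conditioning run and
#' discarded; the remaining runs are averaged pointwise (for the standard
#' four-replicate series: runs 2-4).
#'
#' @param traces list of [nadph_trace()] replicates on identical time grids.
#' @return A single [nadph_trace()] (the pointwise mean), annotated with
#'   `replicate_id = "mean"`.
#' @export
average_replicates <- function(traces) {
  if (!is.list(traces) || length(traces) < 2)
    stop("need at least 2 replicate traces")
  t0 <- traces[[1]]$time_s
  for (tr in traces[-1]) {
    if (length(tr$time_s) != length(t0) ||
        max(abs(tr$time_s - t0)) > 1e-9)
      stop("replicate time grids differ")
  }
  kept <- traces[-1]
  sig <- rowMeans(do.call(cbind, lapply(kept, function(tr) tr$signal)))
  nadph_trace(t0, sig, landmarks = trace_landmarks(traces[[1]]),
              light_intensity = attr(traces[[1]], "light_intensity"),
              replicate_id = "mean")
}

# Dark-end reference level: mean of the final `n_last` samples (robust to
# noise) or the literal last sample.
dark_end_level <- function(trace, method = c("mean5", "last"), n_last = 5) {
  method <- match.arg(method)
  s <- trace$signal
  if (method == "last") s[length(s)] else mean(tail(s, n_last))
}

#' Photo-reducible NAD(P)H level
#'
#' The signal at the end of the dark period is subtracted from the whole
#' trace; the ratio of the maximum in the pulse window (between the actinic
#' end at 1 s and the pulse end at 1.6 s) to the pre-pulse level (0 s to 1 s)
#' is returned. A ratio of r means the saturating pulse can raise the
#' (dark-end-corrected) NAD(P)H signal to r times its pre-pulse level.
#'
#' @param trace a [nadph_trace()] covering all landmarks.
#' @param dark_end_method `"mean5"` (mean of the final five samples, default)
#'   or `"last"` (literal final sample).
#' @param prepulse_method `"mean"` (mean over \[0 s, 1 s), default) or
#'   `"endpoint"` (last pre-pulse sample).
#' @param tol denominators smaller than `tol` (in absolute value) are treated
#'   as a division by ~0: the ratio is undefined.
#' @return The ratio as a single numeric; `NA` with a warning if undefined.
#' @export
photoreducible_level <- function(trace, dark_end_method = c("mean5", "last"),
                                 prepulse_method = c("mean", "endpoint"),
                                 tol = 1e-12) {
  stopifnot(inherits(trace, "nadph_trace"))
  prepulse_method <- match.arg(prepulse_method)
  lmk <- trace_landmarks(trace)
  d <- dark_end_level(trace, dark_end_method)
  s <- trace$signal - d
  t <- trace$time_s
  in_pulse <- t >= lmk[["actinic_end"]] & t <= lmk[["pulse_end"]]
  pre <- t < lmk[["actinic_end"]]
  if (!any(in_pulse) || !any(pre)) stop("trace does not cover the landmarks")
  denom <- switch(prepulse_method,
                  mean = mean(s[pre]),
                  endpoint = s[pre][sum(pre)])
  if (abs(denom) <= tol) {
    warning("pre-pulse level equals the dark-end level; ratio undefined")
    return(NA_real_)
  }
  max(s[in_pulse]) / denom
}

#' Dark oxidation-rate fit with adaptive slope-threshold window
#'
#' Fits `y(t) = offset + amplitude * exp(-rate * (t - t_dark))` to the dark
#' segment of a NAD(P)H trace, starting at the beginning of the dark period
#' (the pulse end, samples at exactly that time included). The fit window is
#' extended forward in steps of `window_step` samples; after each fit the
#' absolute slope of the fitted curve at the current window end,
#' `amplitude * rate * exp(-rate * (t_end - t_dark))`, is compared against
#' `slope_threshold` (signal units per second): once it drops below the
#' threshold — the relaxation has flattened out — the window stops growing
#' and the current fit is returned. If the slope never reaches the threshold
#' the window runs to the end of the trace.
#'
#' @param trace a [nadph_trace()].
#' @param slope_threshold stopping slope in signal units per second
#'   (default 5e-8; instrument-scale dependent, so exposed as a parameter).
#' @param window_step number of samples added per extension (default 10).
#' @param min_samples minimum dark-segment samples required.
#' @return An object of class `oxidation_fit` with `oxidation_rate` (s^-1),
#'   `amplitude`, `offset`, `fit_window_end` (s), `converged`, `rmse`, `n`.
#'   A non-decaying or unfittable segment yields `converged = FALSE` and
#'   `oxidation_rate = NA`.
#' @export
oxidation_rate <- function(trace, slope_threshold = 5e-8, window_step = 10L,
                           min_samples = 10L) {
  stopifnot(inherits(trace, "nadph_trace"))
  lmk <- trace_landmarks(trace)
  t_dark <- lmk[["pulse_end"]]
  dark <- which(trace$time_s >= t_dark - 1e-9)
  if (length(dark) < min_samples)
    stop("dark segment has fewer than ", min_samples, " samples")
  t <- trace$time_s[dark] - t_dark
  y <- trace$signal[dark]

  flagged <- function(reason, end_s = t[length(t)] + t_dark) {
    structure(list(oxidation_rate = NA_real_, amplitude = NA_real_,
                   offset = NA_real_, fit_window_end = end_s,
                   converged = FALSE, rmse = NA_real_, n = length(t),
                   reason = reason, t_dark = t_dark),
              class = "oxidation_fit")
  }
  if (sd(y) == 0) return(flagged("constant dark segment"))

  ends <- unique(c(seq(min_samples, length(t), by = window_step), length(t)))
  start <- list(offset = min(y), amplitude = max(y) - min(y),
                rate = 1 / max(t[min_samples], .Machine$double.eps))
  fit <- NULL
  end_used <- length(t)
  for (e in ends) {
    tw <- t[1:e]
    f <- lm_fit(function(p) p$offset + p$amplitude * exp(-p$rate * tw),
                y[1:e], start,
                lower = c(offset = -Inf, amplitude = -Inf, rate = 1e-8))
    if (is.null(f)) next
    p <- f$par
    start <- as.list(p)                      # warm start for the next window
    fit <- f
    end_used <- e
    slope_at_end <- abs(p[["amplitude"]] * p[["rate"]] *
                          exp(-p[["rate"]] * tw[e]))
    if (is.finite(slope_at_end) && slope_at_end < slope_threshold) break
  }
  if (is.null(fit)) return(flagged("fit failure"))
  p <- fit$par
  if (!is.finite(p[["rate"]]) || p[["rate"]] <= 1e-8 || p[["amplitude"]] <= 0)
    return(flagged("non-decaying segment", t[end_used] + t_dark))
  structure(
    list(oxidation_rate = p[["rate"]], amplitude = p[["amplitude"]],
         offset = p[["offset"]], fit_window_end = t[end_used] + t_dark,
         converged = TRUE, rmse = fit$rmse,
         n = end_used, reason = NULL, t_dark = t_dark),
    class = "oxidation_fit"
  )
}

#' @export
print.oxidation_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<oxidation_fit> rate = %.5g /s, amplitude = %.4g, offset = %.4g\n",
                x$oxidation_rate, x$amplitude, x$offset))
    cat(sprintf("  fit window ends at %.3f s (%d samples), rmse = %.3g\n",
                x$fit_window_end, x$n, x$rmse))
  } else {
    cat(sprintf("<oxidation_fit> NOT converged (%s)\n", x$reason))
  }
  invisible(x)
}

#' @export
coef.oxidation_fit <- function(object, ...) {
  c(rate = object$oxidation_rate, amplitude = object$amplitude,
    offset = object$offset)
}

#' @export
predict.oxidation_fit <- function(object, times, ...) {
  if (!object$converged) stop("fit did not converge")
  object$offset + object$amplitude *
    exp(-object$oxidation_rate * (times - object$t_dark))
}

#' Full analysis of one replicate series
#'
#' Convenience wrapper: average the replicates (dropping the first), then
#' compute the photo-reducible level and the dark oxidation-rate fit.
#'
#' @param traces list of [nadph_trace()] replicates.
#' @param ... passed to [oxidation_rate()].
#' @return List with `trace` (the averaged trace), `photoreducible_level`,
#'   and `oxidation` (the `oxidation_fit`).
#' @export
analyze_nadph_run <- function(traces, ...) {
  avg <- average_replicates(traces)
  list(trace = avg,
       photoreducible_level = photoreducible_level(avg),
       oxidation = oxidation_rate(avg, ...))
}
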
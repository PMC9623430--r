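#' Per-cell intensity statistics on one image plane
#'
#' Mean, standard deviation and normalized standard deviation (nsd, the
#' coefficient of variation sd/mean) of one cell's eYFP pixel intensities.
#' The nsd is the heterogeneity statistic: a perfectly diffuse signal gives
#' nsd = 0, punctate concentration of the same total intensity raises it, and
#' it is invariant to rescaling the whole image by a positive constant.
#'
#' @param eyfp_image numeric matrix (row, col).
#' @param mask a [labeled_mask()] of the same shape.
#' @param cell_id label of the cell to measure (must exist in the mask, with
#'   at least 2 pixels).
#' @param time,illumination optional frame annotations copied into the result.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return One-row data.frame of class `cell_frame_stats` with columns
#'   `cell_id`, `time`, `illumination`, `mean_intensity`, `sd_intensity`,
#'   `nsd`, `nsd_defined`. If the mean intensity is 0 the nsd is undefined:
#'   it is returned as `NA` with `nsd_defined = FALSE` and a warning, never
#'   silently as 0.
#' @export
cell_stats <- function(eyfp_image, mask, cell_id, time = NA_real_,
                       illumination = NA_character_,
                       sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(mask, "labeled_mask"))
  if (!identical(dim(eyfp_image), dim(mask$labels)))
    stop("image and mask shapes differ")
  if (!cell_id %in% seq_len(mask$n_cells)) stop("unknown cell_id")
  v <- eyfp_image[mask$labels == cell_id]
  if (length(v) < 2) stop("region has fewer than 2 pixels")
  m <- mean(v)
  s <- sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  defined <- m > 0
  if (!defined) warning("mean intensity is 0; nsd undefined for cell ", cell_id)
  structure(
    data.frame(cell_id = cell_id, time = time, illumination = illumination,
               mean_intensity = m, sd_intensity = s,
               nsd = if (defined) s / m else NA_real_, nsd_defined = defined),
    class = c("cell_frame_stats", "data.frame")
  )
}

#' Per-cell heterogeneity time series over a stack
#'
#' Applies [cell_stats()] to the eYFP channel of every frame and every
#' labeled cell, and summarizes the population (mean and SD of nsd across
#' cells) per frame.
#'
#' @param stack an [image_stack()].
#' @param mask a [labeled_mask()] sharing the stack's spatial shape (computed
#'   once, typically from [max_project()] of the chlorophyll channel, and held
#'   static across frames).
#' @param sd_type passed to [cell_stats()].
#' @return An object of class `nsd_traces`: a list with `cells` (tidy
#'   data.frame: `frame`, `time_s`, `illumination`, `cell_id`, `mean`, `sd`,
#'   `nsd`) and `population` (per-frame `nsd_mean`, `nsd_sd`, `n_cells`).
#'   An empty mask yields empty tables with a warning.
#' @export
heterogeneity_series <- function(stack, mask,
                                 sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(stack, "image_stack"), inherits(mask, "labeled_mask"))
  if (!identical(dim(stack$pixels)[3:4], dim(mask$labels)))
    stop("stack and mask spatial shapes differ")
  nf <- n_frames(stack)
  if (mask$n_cells == 0) {
    warning("empty mask: no cells to measure")
    empty <- data.frame(frame = integer(0), time_s = numeric(0),
                        illumination = character(0), cell_id = integer(0),
                        mean = numeric(0), sd = numeric(0), nsd = numeric(0))
    return(structure(list(cells = empty,
                          population = data.frame(frame = integer(0),
                                                  time_s = numeric(0),
                                                  illumination = character(0),
                                                  nsd_mean = numeric(0),
                                                  nsd_sd = numeric(0),
                                                  n_cells = integer(0))),
                     class = "nsd_traces"))
  }
  lab <- mask$labels
  in_cell <- lab > 0
  k <- lab[in_cell]
  n_per <- tabulate(k, nbins = mask$n_cells)
  if (any(n_per < 2)) stop("every labeled region needs >= 2 pixels")
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    v <- get_plane(stack, f, "eyfp")[in_cell]
    sums <- tapply(v, k, sum)
    m <- as.numeric(sums) / n_per
    ss <- tapply((v - m[k])^2, k, sum)
    denom <- if (sd_type == "sample") n_per - 1 else n_per
    s <- sqrt(as.numeric(ss) / denom)
    rows[[f]] <- data.frame(
      frame = f, time_s = stack$frame_times[f],
      illumination = stack$illumination[f],
      cell_id = seq_len(mask$n_cells), mean = m, sd = s,
      nsd = ifelse(m > 0, s / m, NA_real_)
    )
  }
  cells <- do.call(rbind, rows)
  pop <- do.call(rbind, lapply(split(cells, cells$frame), function(d) {
    data.frame(frame = d$frame[1], time_s = d$time_s[1],
               illumination = d$illumination[1],
               nsd_mean = mean(d$nsd, na.rm = TRUE),
               nsd_sd = sd(d$nsd, na.rm = TRUE),
               n_cells = sum(!is.na(d$nsd)))
  }))
  rownames(cells) <- rownames(pop) <- NULL
  structure(list(cells = cells, population = pop), class = "nsd_traces")
}

#' @export
print.nsd_traces <- function(x, ...) {
  nf <- length(unique(x$cells$frame))
  nc <- length(unique(x$cells$cell_id))
  cat(sprintf("<nsd_traces> %d cell(s) x %d frame(s)\n", nc, nf))
  if (nrow(x$population) > 0) {
    cat("  population nsd (first/last frame): ",
        sprintf("%.4f / %.4f\n", x$population$nsd_mean[1],
                x$population$nsd_mean[nrow(x$population)]))
  }
  invisible(x)
}

#' @export
plot.nsd_traces <- function(x, which = c("population", "cells"), ...) {
  which <- match.arg(which)
  if (which == "population") {
    plot(x$population$time_s, x$population$nsd_mean, type = "l",
         xlab = "time (s)", ylab = "normalized SD (mean over cells)", ...)
  } else {
    w <- split(x$cells$nsd, x$cells$cell_id)
    t <- sort(unique(x$cells$time_s))
    matplot(t, do.call(cbind, w), type = "l", lty = 1,
            xlab = "time (s)", ylab = "normalized SD", ...)
  }
  invisible(x)
}

#' Extract one cell's nsd trace
#'
#' @param traces an `nsd_traces` object from [heterogeneity_series()].
#' @param cell_id cell label.
#' @return data.frame `time_s`, `nsd`, `illumination` for that cell.
#' @export
cell_trace <- function(traces, cell_id) {
  stopifnot(inherits(traces, "nsd_traces"))
  d <- traces$cells[traces$cells$cell_id == cell_id,
                    c("time_s", "nsd", "illumination")]
  if (nrow(d) == 0) stop("unknown cell_id")
  rownames(d) <- NULL
  d
}

#' Rescale an nsd trace to \[0,1\] for plotting
#'
#' Purely cosmetic min-max rescaling; fits always operate on raw nsd values.
#'
#' @param nsd numeric vector.
#' @return Rescaled vector (constant input maps to 0).
#' @export
rescale01 <- function(nsd) {
  r <- range(nsd, na.rm = TRUE)
  if (diff(r) == 0) return(rep(0, length(nsd)))
  (nsd - r[1]) / diff(r)
}
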
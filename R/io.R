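#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pixel data go into a 32-bit float multi-page TIFF (pages ordered
#' frame-major, channels within frame); frame times, illumination flags and
#' channel roles go into a JSON sidecar next to it.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param meta_path sidecar path (default `<path>.json`).
#' @return Invisibly, `path`.
#' @export
write_image_stack <- function(stack, path, meta_path = paste0(path, ".json")) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  # TIFF storage is defined on [0,1]; rescale by the stack maximum and record
  # the factor in the sidecar so reading restores the original intensities
  scale <- max(stack$pixels, 1e-300)
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (f in seq_len(d[1])) for (ch in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- stack$pixels[f, ch, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(n_frames = d[1], n_channels = d[2],
               frame_times = stack$frame_times,
               illumination = stack$illumination,
               channel_roles = as.list(stack$channel_roles),
               intensity_scale = scale)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path.
#' @param meta_path sidecar path (default `<path>.json`).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, meta_path = paste0(path, ".json")) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nf <- meta$n_frames; nch <- meta$n_channels
  if (length(pages) != nf * nch) stop("page count does not match sidecar")
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  scale <- meta$intensity_scale %||% 1
  px <- array(0, dim = c(nf, nch, nr, nc))
  i <- 0L
  for (f in seq_len(nf)) for (ch in seq_len(nch)) {
    i <- i + 1L
    px[f, ch, , ] <- pages[[i]] * scale
  }
  roles <- unlist(meta$channel_roles)
  image_stack(px, frame_times = meta$frame_times,
              channel_roles = setNames(as.integer(roles), names(roles)),
              illumination = meta$illumination)
}

#' Write a labeled mask as 16-bit TIFF plus a region table CSV
#'
#' @param mask a [labeled_mask()] (at most 65535 labels).
#' @param path output TIFF path.
#' @param table_path region-table CSV path (default `<path>.csv`), or `NULL`
#'   to skip.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path, table_path = paste0(path, ".csv")) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (mask$n_cells > 65535) stop("too many labels for 16-bit storage")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  if (!is.null(table_path))
    write.csv(region_table(mask), table_path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled mask written by [write_mask()]
#'
#' @param path TIFF path.
#' @return A [labeled_mask()].
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  labeled_mask(round(m * 65535))
}

#' Write NAD(P)H replicate traces to tidy CSV
#'
#' Columns: `time_s`, `signal`, `replicate`, `light_intensity`. Landmarks are
#' not serialized; pass them to [read_nadph_traces()] (defaults cover the
#' standard 1 s / 0.6 s / 13.4 s trigger run).
#'
#' @param traces list of [nadph_trace()] replicates.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_nadph_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(time_s = tr$time_s, signal = tr$signal,
               replicate = attr(tr, "replicate_id"),
               light_intensity = attr(tr, "light_intensity"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read NAD(P)H replicate traces from tidy CSV
#'
#' @param path CSV path written by [write_nadph_traces()].
#' @param landmarks named vector (`actinic_end`, `pulse_end`, `trace_end`).
#' @return List of [nadph_trace()] replicates.
#' @export
read_nadph_traces <- function(path, landmarks = c(actinic_end = 1,
                                                  pulse_end = 1.6,
                                                  trace_end = 15)) {
  d <- read.csv(path)
  lapply(split(d, d$replicate), function(g) {
    nadph_trace(g$time_s, g$signal, landmarks = landmarks,
                light_intensity = g$light_intensity[1],
                replicate_id = g$replicate[1])
  })
}

#' Serialize ground truth to JSON
#'
#' Non-serializable internals (schedule/run objects) are unclassed; matrices
#' become row-major lists.
#'
#' @param truth a [ground_truth()].
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- unclass(truth)
  x$extra <- lapply(x$extra, function(e) if (is.object(e)) unclass(e) else e)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
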
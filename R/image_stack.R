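#' Timed two-channel image stack
#'
#' Container for fluorescence time-lapse data: a 4-d pixel array indexed
#' (frame, channel, row, col), strictly increasing frame times, a mapping of
#' channel roles (which channel carries chlorophyll autofluorescence, which
#' the eYFP fusion signal), and a per-frame illumination flag.
#'
#' @param pixels numeric array, dim = (frame, channel, row, col), non-negative.
#' @param frame_times numeric vector of acquisition times in seconds, strictly
#'   increasing, one per frame.
#' @param channel_roles named integer vector mapping roles to channel indices;
#'   must contain exactly one `chlorophyll` and one `eyfp` entry.
#' @param illumination character vector, one of `"dark"`/`"light"` per frame.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, frame_times, channel_roles, illumination) {
  if (!is.array(pixels) || length(dim(pixels)) != 4L)
    stop("'pixels' must be a 4-d array (frame, channel, row, col)")
  if (any(pixels < 0)) stop("pixel intensities must be non-negative")
  nf <- dim(pixels)[1]
  if (length(frame_times) != nf)
    stop("'frame_times' length must equal the number of frames")
  if (nf > 1 && any(diff(frame_times) <= 0))
    stop("'frame_times' must be strictly increasing")
  roles <- c("chlorophyll", "eyfp")
  if (!all(roles %in% names(channel_roles)) ||
      anyDuplicated(channel_roles[roles]) ||
      any(!channel_roles[roles] %in% seq_len(dim(pixels)[2])))
    stop("'channel_roles' must map 'chlorophyll' and 'eyfp' to distinct channels")
  illumination <- match.arg(illumination, c("dark", "light"), several.ok = TRUE)
  if (length(illumination) == 1L) illumination <- rep(illumination, nf)
  if (length(illumination) != nf)
    stop("'illumination' must have one flag per frame")
  structure(
    list(pixels = pixels, frame_times = as.numeric(frame_times),
         channel_roles = channel_roles[roles], illumination = illumination),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d frame(s), %d channel(s), %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  time %.2f .. %.2f s | %d dark, %d light frame(s)\n",
              min(x$frame_times), max(x$frame_times),
              sum(x$illumination == "dark"), sum(x$illumination == "light")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

n_frames <- function(stack) dim(stack$pixels)[1]

#' Extract one channel plane of one frame
#'
#' @param stack an [image_stack()].
#' @param frame frame index.
#' @param channel `"chlorophyll"` or `"eyfp"`.
#' @return Numeric matrix (row, col).
#' @export
get_plane <- function(stack, frame, channel = c("chlorophyll", "eyfp")) {
  channel <- match.arg(channel)
  ch <- stack$channel_roles[[channel]]
  stack$pixels[frame, ch, , , drop = TRUE]
}

#' Maximum-intensity projection of one channel
#'
#' Computes the per-pixel maximum across all frames of the chosen channel,
#' the standard reduction applied to chlorophyll Z-stacks or time-lapses
#' before segmentation.
#'
#' @inheritParams get_plane
#' @return Numeric matrix (row, col) of per-pixel maxima.
#' @export
max_project <- function(stack, channel = c("chlorophyll", "eyfp")) {
  channel <- match.arg(channel)
  if (!inherits(stack, "image_stack")) stop("'stack' must be an image_stack")
  if (n_frames(stack) == 0L) stop("empty stack")
  ch <- stack$channel_roles[[channel]]
  planes <- stack$pixels[, ch, , , drop = FALSE]
  apply(planes, c(3, 4), max)
}
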
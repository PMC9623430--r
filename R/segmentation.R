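#' Labeled cell mask
#'
#' Integer label image over one plane: 0 is background, k > 0 is cell k.
#' Labels are contiguous 1..n_cells and each region is 4-connected.
#'
#' @param labels integer matrix (row, col).
#' @return An object of class `labeled_mask` with fields `labels`, `n_cells`.
#' @export
labeled_mask <- function(labels) {
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  u <- sort(unique(labels[labels > 0]))
  if (length(u) > 0 && !identical(u, seq_along(u)))
    stop("labels must be contiguous 1..n_cells")
  structure(list(labels = labels, n_cells = length(u)), class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d x %d px, %d cell(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_cells))
  invisible(x)
}

# Otsu threshold on the image rescaled to [0,1]; rescaling makes the
# threshold exactly invariant to multiplying the image by a positive constant.
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(Inf)           # blank image: nothing foreground
  scaled <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(scaled, range = c(0, 1), levels = 256L)
  th * diff(rng) + rng[1]
}

#' Segment cells from a chlorophyll image
#'
#' Deterministic replacement for a trained pixel classifier: global automatic
#' (Otsu) or fixed thresholding of the chlorophyll channel, 4-connected
#' component labeling, and an area filter. Surviving regions are relabeled
#' 1..n in raster order of their top-left pixel (first region pixel met in a
#' row-major scan). Touching cells are not split.
#'
#' @param chl_image numeric matrix, e.g. from [max_project()].
#' @param min_area minimum region area in pixels (default 50).
#' @param threshold_method `"otsu"` for the automatic relative threshold or
#'   `"fixed"` to use `threshold` as an absolute cutoff.
#' @param threshold absolute intensity cutoff when `threshold_method = "fixed"`.
#' @return A [labeled_mask()]. A blank image yields `n_cells = 0`.
#' @export
segment_cells <- function(chl_image, min_area = 50,
                          threshold_method = c("otsu", "fixed"),
                          threshold = NULL) {
  if (!is.matrix(chl_image) || length(chl_image) == 0)
    stop("'chl_image' must be a non-empty matrix")
  threshold_method <- match.arg(threshold_method)
  th <- switch(threshold_method,
               otsu = otsu_threshold(chl_image),
               fixed = {
                 if (is.null(threshold)) stop("fixed method needs 'threshold'")
                 threshold
               })
  fg <- chl_image > th
  if (!any(fg)) return(labeled_mask(matrix(0L, nrow(chl_image), ncol(chl_image))))
  lab <- EBImage::bwlabel(fg)                # 4-connected components
  lab <- matrix(as.integer(lab), nrow(chl_image), ncol(chl_image))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep) > 0) {
    nr <- nrow(lab)
    # raster (row-major) key of each region's first pixel
    first_key <- vapply(keep, function(k) {
      idx <- which(lab == k)
      r <- (idx - 1L) %% nr + 1L
      cc <- (idx - 1L) %/% nr + 1L
      min((r - 1L) * ncol(lab) + (cc - 1L))
    }, numeric(1))
    for (i in seq_along(keep)) {
      k <- keep[order(first_key)][i]
      out[lab == k] <- i
    }
  }
  labeled_mask(out)
}

#' Region property table of a labeled mask
#'
#' @param mask a [labeled_mask()].
#' @return data.frame with columns `label`, `area`, `centroid_row`,
#'   `centroid_col`.
#' @export
region_table <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  lab <- mask$labels
  nr <- nrow(lab)
  idx <- which(lab > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  k <- lab[idx]
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  data.frame(
    label = sort(unique(k)),
    area = as.integer(tabulate(k, nbins = mask$n_cells)),
    centroid_row = as.numeric(tapply(r, k, mean)),
    centroid_col = as.numeric(tapply(cc, k, mean))
  )
}

#' Jaccard overlap between a mask label and a reference pixel set
#'
#' @param mask a [labeled_mask()].
#' @param label label index in the mask.
#' @param ref_idx linear pixel indices of the reference region.
#' @return Intersection-over-union in \[0,1\].
#' @export
jaccard_overlap <- function(mask, label, ref_idx) {
  got <- which(mask$labels == label)
  length(intersect(got, ref_idx)) / length(union(got, ref_idx))
}
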
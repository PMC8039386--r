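#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|` over pixels.  Raises an error when both
#' masks are empty (0/0 is undefined rather than 0 or 1).
#'
#' @param pred,truth Binary (0/1 or logical) matrices of identical shape.
#' @return A fraction in `[0, 1]`.
#' @examples
#' a <- matrix(0L, 10, 10); a[2:5, 2:5] <- 1L
#' iou(a, a)
#' @export
iou <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    abort("masks must have identical dimensions")
  a <- pred > 0
  b <- truth > 0
  uni <- sum(a | b)
  if (uni == 0)
    abort("IoU undefined: both masks are empty", class = "gastrolayer_empty_iou")
  sum(a & b) / uni
}

#' Rectangular region of interest
#'
#' 1-based inclusive pixel bounds of a rectangular crop.
#'
#' @param row_min,row_max,col_min,col_max Integer bounds, inclusive.
#' @return An object of class `roi`.
#' @export
roi <- function(row_min, row_max, col_min, col_max) {
  stopifnot(row_min >= 1, col_min >= 1, row_max >= row_min, col_max >= col_min)
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows %d..%d, cols %d..%d\n",
              x$row_min, x$row_max, x$col_min, x$col_max))
  invisible(x)
}

#' Bounding-box ROI of the largest connected mask component
#'
#' A noisy predicted mask can contain several blobs; the ROI passed to
#' stratification is the tight bounding box of the largest 8-connected
#' component, expanded by `margin` pixels on every side and clipped to the
#' image bounds.
#'
#' @param mask Binary matrix.
#' @param margin Expansion in pixels (default 0).
#' @return An [roi()].
#' @export
mask_to_roi <- function(mask, margin = 0L) {
  stopifnot_matrix(mask, "mask")
  if (sum(mask > 0) == 0)
    abort("no wall detected: mask is empty", class = "gastrolayer_empty_mask")
  lab <- EBImage::imageData(EBImage::bwlabel(mask > 0))
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  idx <- which(lab == keep, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1L]) - margin)
  r1 <- min(nrow(mask), max(idx[, 1L]) + margin)
  c0 <- max(1L, min(idx[, 2L]) - margin)
  c1 <- min(ncol(mask), max(idx[, 2L]) + margin)
  roi(r0, r1, c0, c1)
}

#' Crop an image (or mask) to an ROI
#'
#' @param image Numeric matrix.
#' @param region An [roi()].
#' @return The cropped matrix.
#' @export
crop_roi <- function(image, region) {
  stopifnot(inherits(region, "roi"))
  if (region$row_max > nrow(image) || region$col_max > ncol(image))
    abort("ROI exceeds image bounds")
  image[region$row_min:region$row_max, region$col_min:region$col_max, drop = FALSE]
}
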
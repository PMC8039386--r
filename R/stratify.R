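#' Sobel gradient of an ROI image
#'
#' Standard 3x3 Sobel kernels with replicated borders; returns the horizontal
#' derivative `gx` (across columns), the vertical derivative `gy` (across
#' rows) and the magnitude `sqrt(gx^2 + gy^2)`.
#'
#' @param image Numeric matrix, at least 3x3.
#' @return List with components `gx`, `gy`, `magnitude` (matrices matching
#'   `image`).
#' @export
sobel_gradient <- function(image) {
  stopifnot_matrix(image)
  if (nrow(image) < 3L || ncol(image) < 3L)
    abort("image smaller than the 3x3 Sobel kernel")
  u <- shift_up(image); d <- shift_down(image)
  l <- shift_left(image); r <- shift_right(image)
  ul <- shift_left(u); ur <- shift_right(u)
  dl <- shift_left(d); dr <- shift_right(d)
  gx <- (ur + 2 * r + dr) - (ul + 2 * l + dl)
  gy <- (dl + 2 * d + dr) - (ul + 2 * u + ur)
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

# 1-D Gaussian smoothing with replicated ends (sigma in samples).
gaussian_smooth_1d <- function(v, sigma = 1) {
  if (sigma <= 0) return(v)
  rad <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(v)
  vp <- c(rep(v[1L], rad), v, rep(v[n], rad))
  as.numeric(stats::filter(vp, k, sides = 2L))[(rad + 1L):(rad + n)]
}

# Local maxima of a 1-D signal with plateau handling: a run of equal values
# higher than both neighbors counts once, at the (rounded-up) centre of the
# run.  Returns positions and heights.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(pos = integer(), height = numeric()))
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pos <- integer(); height <- numeric()
  for (i in seq_along(runs$values)) {
    left_ok <- i > 1L && runs$values[i] > runs$values[i - 1L]
    right_ok <- i < length(runs$values) && runs$values[i] > runs$values[i + 1L]
    if (left_ok && right_ok) {
      pos <- c(pos, ceiling((starts[i] + ends[i]) / 2))
      height <- c(height, runs$values[i])
    }
  }
  list(pos = pos, height = height)
}

# Merge peaks closer than min_separation, keeping the higher of each pair.
merge_peaks <- function(pos, height, min_separation) {
  if (length(pos) <= 1L) return(list(pos = pos, height = height))
  ord <- order(pos)
  pos <- pos[ord]; height <- height[ord]
  repeat {
    gaps <- diff(pos)
    close <- which(gaps < min_separation)
    if (length(close) == 0L) break
    i <- close[1L]
    drop <- if (height[i] >= height[i + 1L]) i + 1L else i
    pos <- pos[-drop]; height <- height[-drop]
  }
  list(pos = pos, height = height)
}

#' Detect layer boundaries along one ROI column
#'
#' Samples the Sobel gradient magnitude along a column of the (SRAD-filtered)
#' ROI, smooths it with a 1-D Gaussian, and picks gradient peaks.  The wall
#' extent is taken from `wall_extent` (mask-derived, preferred) or from the
#' outermost gradient peaks; the four largest remaining peaks strictly inside
#' the wall, at least `min_separation` rows apart, are the inter-layer edges.
#'
#' Row convention: `wall_top` is the first wall row, `wall_bottom` the row
#' just below the last wall row (half-open), and each inner edge is the first
#' row of the next layer, so consecutive differences of
#' `(wall_top, e1..e4, wall_bottom)` are the layer thicknesses.
#'
#' @param roi_image Numeric matrix (ROI crop with layers running across
#'   rows).
#' @param column_index Column to sample (1-based).
#' @param wall_extent Optional `c(top, bottom)` wall rows (half-open, ROI
#'   coordinates); when `NULL` the outermost gradient peaks are used.
#' @param min_separation Minimum row distance between retained peaks.
#' @param smooth_sigma Gaussian smoothing bandwidth (rows).
#' @return An object of class `boundary_set`: list with `column_index`,
#'   `wall_top`, `wall_bottom`, `inner_edges` (4 strictly increasing rows).
#' @export
detect_boundaries <- function(roi_image, column_index,
                              wall_extent = NULL,
                              min_separation = 3L,
                              smooth_sigma = 1) {
  stopifnot_matrix(roi_image, "roi_image")
  if (nrow(roi_image) < 10L)
    abort("ROI height must be at least 10 rows")
  if (column_index < 1L || column_index > ncol(roi_image))
    abort("`column_index` outside the ROI")
  g <- sobel_gradient(roi_image)$magnitude[, column_index]
  gs <- gaussian_smooth_1d(g, smooth_sigma)
  pk <- local_maxima(gs)
  pk <- merge_peaks(pk$pos, pk$height, min_separation)

  if (!is.null(wall_extent)) {
    wall_top <- wall_extent[1L]
    wall_bottom <- wall_extent[2L]
  } else {
    if (length(pk$pos) < 2L)
      abort_cannot_stratify(length(pk$pos), column_index)
    wall_top <- pk$pos[1L]
    wall_bottom <- pk$pos[length(pk$pos)]
    keep <- seq_along(pk$pos)[-c(1L, length(pk$pos))]
    pk <- list(pos = pk$pos[keep], height = pk$height[keep])
  }

  # the outer wall edges produce their own gradient peaks; peaks within
  # min_separation of them belong to those edges, not to interior layers
  inside <- pk$pos > wall_top + min_separation &
    pk$pos < wall_bottom - min_separation
  pos <- pk$pos[inside]; height <- pk$height[inside]
  if (length(pos) < 4L)
    abort_cannot_stratify(length(pos), column_index)
  top4 <- order(height, decreasing = TRUE)[1:4]
  inner <- sort(pos[top4])
  structure(list(column_index = as.integer(column_index),
                 wall_top = as.integer(wall_top),
                 wall_bottom = as.integer(wall_bottom),
                 inner_edges = as.integer(inner)),
            class = "boundary_set")
}

abort_cannot_stratify <- function(n_found, column_index) {
  abort(sprintf("cannot stratify column %d into five layers: %d interior edge(s) found, 4 required",
                column_index, n_found),
        class = "gastrolayer_cannot_stratify",
        n_found = n_found, column_index = column_index)
}

#' Layer proportions from a boundary set
#'
#' Thicknesses are consecutive differences of
#' `(wall_top, e1, e2, e3, e4, wall_bottom)`; proportions divide by the total
#' wall thickness and hence always sum to 1.
#'
#' @param b A [detect_boundaries()] result.
#' @return Numeric length-5 proportion vector.
#' @examples
#' b <- structure(list(column_index = 1L, wall_top = 0L, wall_bottom = 100L,
#'                     inner_edges = c(20L, 40L, 60L, 80L)),
#'                class = "boundary_set")
#' proportions_from_boundaries(b)
#' @export
proportions_from_boundaries <- function(b) {
  stopifnot(inherits(b, "boundary_set"))
  rows <- c(b$wall_top, b$inner_edges, b$wall_bottom)
  if (any(diff(rows) <= 0))
    abort("boundary rows must be strictly increasing")
  diff(rows) / (b$wall_bottom - b$wall_top)
}

#' Average per-column proportion vectors
#'
#' Component-wise arithmetic mean followed by renormalization to sum exactly
#' to 1 (pixel quantization can leave a small drift in the mean).
#'
#' @param x Matrix with one proportion vector per row (or a list of length-5
#'   vectors).
#' @return Numeric length-5 vector summing to 1.
#' @export
average_proportions <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  stopifnot(is.matrix(x), ncol(x) == 5L, nrow(x) >= 1L)
  m <- colMeans(x)
  m / sum(m)
}

#' Stratify an ROI by sampling several columns
#'
#' Runs [detect_boundaries()] on `n_columns` columns evenly spaced across the
#' middle 80% of the ROI width, converts each to a proportion vector, and
#' averages the successful columns ([average_proportions()]).  Columns that
#' cannot be divided into five layers are skipped and counted; if fewer than
#' `min_valid` succeed the ROI is reported unstratifiable.
#'
#' @param roi_image Numeric matrix (layers across rows).
#' @param n_columns Number of sampled columns (default 9).
#' @param roi_mask Optional binary mask aligned with `roi_image`; when given,
#'   each column's wall extent is read from the mask instead of the outermost
#'   gradient peaks.
#' @param min_valid Minimum number of stratifiable columns (default half,
#'   rounded up).
#' @param min_separation,smooth_sigma Passed to [detect_boundaries()].
#' @return An object of class `wall_stratification`: list with `x` (length-5
#'   proportion vector), `n_columns_used`, `per_column` (tibble of per-column
#'   diagnostics) and `boundaries` (list of `boundary_set`s).
#' @export
aggregate_columns <- function(roi_image,
                              n_columns = 9L,
                              roi_mask = NULL,
                              min_valid = NULL,
                              min_separation = 3L,
                              smooth_sigma = 1) {
  stopifnot_matrix(roi_image, "roi_image")
  if (n_columns < 1L) abort("`n_columns` must be >= 1")
  w <- ncol(roi_image)
  lo <- max(1, 0.1 * w)
  hi <- min(w, 0.9 * w)
  cols <- unique(as.integer(round_half_up(seq(lo, hi, length.out = n_columns))))
  min_valid <- min_valid %||% ceiling(length(cols) / 2)

  results <- lapply(cols, function(j) {
    extent <- NULL
    if (!is.null(roi_mask)) {
      rows <- which(roi_mask[, j] > 0)
      if (length(rows) >= 10L) extent <- c(min(rows), max(rows) + 1L)
    }
    tryCatch(
      detect_boundaries(roi_image, j, wall_extent = extent,
                        min_separation = min_separation,
                        smooth_sigma = smooth_sigma),
      gastrolayer_cannot_stratify = function(e) e
    )
  })
  ok <- vapply(results, inherits, logical(1L), "boundary_set")
  per_column <- tibble::tibble(
    column = cols,
    ok = ok,
    n_peaks_found = vapply(seq_along(results), function(i) {
      if (ok[i]) 4L else as.integer(results[[i]]$n_found %||% NA_integer_)
    }, integer(1L))
  )
  if (sum(ok) < min_valid)
    abort(sprintf("ROI unstratifiable: only %d of %d columns yielded five layers (min_valid = %d)",
                  sum(ok), length(cols), min_valid),
          class = "gastrolayer_unstratifiable",
          per_column = per_column)
  props <- t(vapply(results[ok], proportions_from_boundaries, numeric(5L)))
  x <- average_proportions(props)
  per_column <- dplyr::bind_cols(
    per_column,
    tibble::as_tibble(stats::setNames(as.data.frame(
      matrix(NA_real_, length(cols), 5L)), paste0("x", 1:5)))
  )
  per_column[ok, paste0("x", 1:5)] <- as.data.frame(props)
  structure(list(x = x,
                 n_columns_used = sum(ok),
                 per_column = per_column,
                 boundaries = results[ok]),
            class = "wall_stratification")
}

#' @export
print.wall_stratification <- function(x, ...) {
  cat(sprintf("<wall_stratification> %d column(s) used\n", x$n_columns_used))
  cat("x:", paste(sprintf("%.3f", x$x), collapse = " "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-column stratification diagnostics
#'
#' @param x A `wall_stratification`.
#' @param ... Unused.
#' @return A tibble with one row per sampled column: `column`, `ok`,
#'   `n_peaks_found`, `x1`..`x5`.
#' @export
tidy.wall_stratification <- function(x, ...) x$per_column

#' One-row stratification summary
#'
#' @param x A `wall_stratification`.
#' @param ... Unused.
#' @return A one-row tibble: `n_columns_used`, `x1`..`x5`.
#' @export
glance.wall_stratification <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(x$x, paste0("x", 1:5))))
  dplyr::bind_cols(tibble::tibble(n_columns_used = x$n_columns_used), out)
}
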
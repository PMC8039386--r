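#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_hline geom_col
#'   geom_jitter geom_point scale_fill_gradient labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a phantom with its ground-truth layer boundaries
#'
#' @param object A `phantom_truth`.
#' @param boundaries Overlay the true inter-layer boundaries.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phantom_truth <- function(object, boundaries = TRUE, ...) {
  img <- object$image
  df <- tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    intensity = as.vector(img)
  )
  p <- ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    labs(x = "column", y = "row", fill = "intensity",
         title = sprintf("phantom (%s)", object$label)) +
    theme_minimal()
  if (boundaries) {
    bd <- tibble::tibble(
      col = rep(seq_len(ncol(img)), times = 4L),
      row = as.vector(t(object$boundary_rows))
    )
    p <- p + geom_point(data = bd, aes(x = .data$col, y = .data$row),
                        inherit.aes = FALSE, color = "red", size = 0.1)
  }
  p
}

#' Plot recovered layer proportions
#'
#' @param object A `wall_stratification`.
#' @param truth Optional true proportion vector drawn alongside.
#' @param ... Unused.
#' @return A ggplot bar chart of the five layer fractions.
#' @export
autoplot.wall_stratification <- function(object, truth = NULL, ...) {
  df <- tibble::tibble(layer = factor(1:5), proportion = object$x,
                       source = "recovered")
  if (!is.null(truth))
    df <- dplyr::bind_rows(df, tibble::tibble(layer = factor(1:5),
                                              proportion = truth,
                                              source = "truth"))
  ggplot(df, aes(x = .data$layer, y = .data$proportion, fill = .data$source)) +
    geom_col(position = "dodge") +
    labs(x = "layer (1 = innermost)", y = "thickness fraction") +
    theme_minimal()
}

#' Plot the distance statistic by class with the decision threshold
#'
#' @param object A `pipeline_evaluation`.
#' @param ... Unused.
#' @return A ggplot of per-case `d` values, split by true label and
#'   train/test set, with the fitted threshold as a horizontal line.
#' @export
autoplot.pipeline_evaluation <- function(object, ...) {
  ggplot(object$records,
         aes(x = .data$label, y = .data$d, color = .data$set)) +
    geom_jitter(width = 0.15, height = 0) +
    geom_hline(yintercept = object$model$threshold, linetype = "dashed") +
    labs(x = "true label", y = "distance d to the normal standard",
         caption = "dashed line: fitted threshold (abnormal iff d ≥ threshold)") +
    theme_minimal()
}
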
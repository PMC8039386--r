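#' Standard (normal-wall) proportion vector
#'
#' Component-wise arithmetic mean of the layer-proportion vectors of a
#' reference cohort, with no renormalization — the published normal-wall
#' standard `s = (0.278, 0.133, 0.154, 0.154, 0.280)` itself sums to 0.999,
#' so the mean is reported as computed.
#'
#' @param x Matrix or data frame with one proportion vector per row (columns
#'   `x1`..`x5` if a data frame), or a list of length-5 vectors.
#' @return Numeric length-5 vector.
#' @export
estimate_standard_vector <- function(x) {
  x <- as_x_matrix(x)
  if (nrow(x) == 0L) abort("cannot estimate the standard vector from an empty cohort")
  colMeans(x)
}

as_x_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  if (is.data.frame(x)) {
    cols <- paste0("x", 1:5)
    if (!all(cols %in% names(x)))
      abort("data frame must contain columns x1..x5")
    x <- as.matrix(x[, cols])
  }
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 5L) abort("proportion vectors must have 5 components")
  x
}

#' Distance between a wall's proportion vector and the standard
#'
#' The screening statistic
#' `d = sqrt((x1-s1)^2 + (x2-s2)^2 + (x3-s3)^2 + (x4-s4)^2)`: a Euclidean
#' distance over the first four layer proportions only.  The fifth component
#' is deliberately excluded, matching the published form of the statistic
#' (set `include_fifth = TRUE` for the full 5-term distance).  A large `d`
#' indicates a wall whose layering departs from the normal standard.
#'
#' @param x Length-5 proportion vector, or a matrix/data frame of them (one
#'   per row).
#' @param s Standard vector (length 5).
#' @param include_fifth Include the `(x5-s5)^2` term (default `FALSE`).
#' @return Nonnegative scalar, or a vector with one `d` per row of `x`.
#' @examples
#' s <- c(0.278, 0.133, 0.154, 0.154, 0.280)
#' wall_distance(c(0.358, 0.189, 0.116, 0.2, 0.137), s)
#' @export
wall_distance <- function(x, s, include_fifth = FALSE) {
  x <- as_x_matrix(x)
  if (length(s) != 5L) abort("`s` must have 5 components")
  k <- if (include_fifth) 1:5 else 1:4
  d <- sqrt(rowSums((x[, k, drop = FALSE] -
                       matrix(s[k], nrow(x), length(k), byrow = TRUE))^2))
  unname(d)
}

#' Stratified random train/test split
#'
#' Randomly assigns `train_fraction` of the records of each class to the
#' training set and the rest to the test set (the published protocol is a
#' random 70/30 split).  Errors if either class would be absent from either
#' side.
#'
#' @param data Data frame with a label column.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed RNG seed; the split is reproducible under it.
#' @param label_col Name of the label column (default `"label"`).
#' @return List with tibbles `train` and `test`; together they partition
#'   `data`.
#' @export
split_cohort <- function(data, train_fraction = 0.7, seed = NULL,
                         label_col = "label") {
  stopifnot(is.data.frame(data))
  if (!label_col %in% names(data)) abort(sprintf("no column `%s`", label_col))
  labs <- data[[label_col]]
  classes <- unique(labs)
  if (length(classes) < 2L) abort("both classes must be present to split")
  # per-class largest-remainder allocation so the train total is exactly
  # round(train_fraction * n) while every class stays on both sides
  n_by_class <- vapply(classes, function(cl) sum(labs == cl), integer(1L))
  target <- round_half_up(train_fraction * length(labs))
  n_tr <- floor(train_fraction * n_by_class)
  rem <- train_fraction * n_by_class - n_tr
  extra <- target - sum(n_tr)
  if (extra > 0)
    n_tr[order(rem, decreasing = TRUE)[seq_len(extra)]] <-
      n_tr[order(rem, decreasing = TRUE)[seq_len(extra)]] + 1L
  if (any(n_tr < 1L) || any(n_tr >= n_by_class))
    abort(sprintf("class `%s` would be absent from the train or test set at fraction %.2f",
                  classes[which(n_tr < 1L | n_tr >= n_by_class)[1L]],
                  train_fraction))
  idx_train <- with_local_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      sample(which(labs == classes[k]), n_tr[k])
    }))
  })
  list(train = tibble::as_tibble(data[sort(idx_train), , drop = FALSE]),
       test = tibble::as_tibble(data[setdiff(seq_len(nrow(data)), idx_train), ,
                                     drop = FALSE]))
}

#' Fit the screening threshold on training distances
#'
#' Enumerates candidate thresholds at the midpoints between consecutive
#' distinct sorted `d` values (plus below-minimum and above-maximum
#' sentinels) and picks the one maximizing training accuracy under the rule
#' "abnormal iff `d >= threshold`"; ties are broken towards the smaller
#' threshold, favoring sensitivity.
#'
#' @param d Numeric training distances.
#' @param labels Labels aligned with `d` (`"normal"` / `"abnormal"`).
#' @param positive The abnormal label (default `"abnormal"`).
#' @return The threshold, with the achieved training accuracy attached as
#'   attribute `"train_accuracy"`.
#' @export
fit_threshold <- function(d, labels, positive = "abnormal") {
  stopifnot(length(d) == length(labels))
  y <- labels == positive
  if (all(y) || !any(y)) abort("both classes must be present to fit a threshold")
  u <- sort(unique(d))
  cand <- c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  acc <- vapply(cand, function(t) mean((d >= t) == y), numeric(1L))
  best <- cand[which.max(acc)]           # which.max takes the first (smallest) tie
  structure(best, train_accuracy = max(acc))
}

#' Classify a wall from its distance statistic
#'
#' @param d Numeric distance(s).
#' @param model A [screening_model()] (or a bare threshold).
#' @return Character vector, `"abnormal"` iff `d >= threshold` (the boundary
#'   itself classifies as abnormal, favoring sensitivity).
#' @export
classify_wall <- function(d, model) {
  thr <- if (inherits(model, "screening_model")) model$threshold else model
  ifelse(d >= thr, "abnormal", "normal")
}

#' Screening model: standard vector plus decision threshold
#'
#' @param s Standard proportion vector (length 5, nonnegative, summing to
#'   about 1).
#' @param threshold Nonnegative decision threshold on the `d` scale.
#' @param include_fifth Whether distances use the fifth component.
#' @return An object of class `screening_model`.
#' @seealso [fit_screening_model()]
#' @export
screening_model <- function(s, threshold, include_fifth = FALSE) {
  if (length(s) != 5L || any(s < 0) || sum(s) < 0.99 || sum(s) > 1.01)
    abort("`s` must be 5 nonnegative fractions summing to about 1")
  if (threshold < 0) abort("`threshold` must be nonnegative")
  structure(list(s = as.numeric(s), threshold = as.numeric(threshold),
                 include_fifth = include_fifth,
                 train_accuracy = NA_real_),
            class = "screening_model")
}

#' Fit the screening model on a training cohort
#'
#' Estimates the standard vector `s` from the training records (by default
#' the normal ones only: a "standard" wall should be a normal wall; set
#' `use_all_for_s = TRUE` to average over all training records), computes
#' each record's distance `d`, and fits the decision threshold with
#' [fit_threshold()].
#'
#' @param train Data frame with columns `x1`..`x5` and `label`.
#' @param use_all_for_s Average `s` over all records instead of normals only.
#' @param include_fifth Use the 5-term distance.
#' @return A `screening_model` with `train_accuracy` filled in.
#' @export
fit_screening_model <- function(train, use_all_for_s = FALSE,
                                include_fifth = FALSE) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  ref <- if (use_all_for_s) train else train[train$label == "normal", , drop = FALSE]
  if (nrow(ref) == 0L) abort("no records available to estimate the standard vector")
  s <- estimate_standard_vector(ref)
  d <- wall_distance(train, s, include_fifth)
  thr <- fit_threshold(d, train$label)
  m <- screening_model(s, as.numeric(thr), include_fifth)
  m$train_accuracy <- attr(thr, "train_accuracy")
  m
}

#' @export
print.screening_model <- function(x, ...) {
  cat("<screening_model>\n")
  cat("  s:", paste(sprintf("%.3f", x$s), collapse = " "), "\n")
  cat(sprintf("  threshold: %.4f (abnormal iff d >= threshold)\n", x$threshold))
  if (!is.na(x$train_accuracy))
    cat(sprintf("  training accuracy: %.3f\n", x$train_accuracy))
  invisible(x)
}

#' @rdname tidy.wall_stratification
#' @export
tidy.screening_model <- function(x, ...) {
  tibble::tibble(term = c(paste0("s", 1:5), "threshold"),
                 estimate = c(x$s, x$threshold))
}

#' @rdname glance.wall_stratification
#' @export
glance.screening_model <- function(x, ...) {
  tibble::tibble(threshold = x$threshold,
                 train_accuracy = x$train_accuracy,
                 include_fifth = x$include_fifth)
}

#' Confusion counts of a labeled prediction set
#'
#' @param predicted,actual Character vectors of labels.
#' @param positive The positive (abnormal) label.
#' @return Named list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, actual, positive = "abnormal") {
  stopifnot(length(predicted) == length(actual))
  p <- predicted == positive
  a <- actual == positive
  list(TP = sum(p & a), TN = sum(!p & !a), FP = sum(p & !a), FN = sum(!p & a))
}

#' Classification metrics from confusion counts
#'
#' Computes ACC, SENS (recall), SPEC, PPV (precision), NPV, MCC and F1 from
#' `TP`, `TN`, `FP`, `FN` by their standard formulas.  A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts List with `TP`, `TN`, `FP`, `FN` (e.g. from
#'   [confusion_counts()]).
#' @return One-row tibble with columns `ACC`, `SENS`, `SPEC`, `PPV`, `NPV`,
#'   `MCC`, `F1`.
#' @examples
#' compute_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  total <- tp + tn + fp + fn
  if (total == 0) abort("all confusion counts are zero")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  tibble::tibble(
    ACC = (tp + tn) / total,
    SENS = safe_div(tp, tp + fn),
    SPEC = safe_div(tn, tn + fp),
    PPV = safe_div(tp, tp + fp),
    NPV = safe_div(tn, tn + fn),
    MCC = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
    F1 = safe_div(2 * tp, 2 * tp + fp + fn)
  )
}

#' ROC area under the curve of the distance statistic
#'
#' AUC of the family of classifiers "abnormal iff `d >= t`", computed as the
#' Mann-Whitney probability that an abnormal case has a larger `d` than a
#' normal one, with half credit for ties (equivalent to the trapezoidal area
#' over the empirical ROC).
#'
#' @param d Numeric distances.
#' @param labels Labels aligned with `d`.
#' @param positive The abnormal label.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(d, labels, positive = "abnormal") {
  stopifnot(length(d) == length(labels))
  y <- labels == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute AUC")
  r <- rank(d)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank-sum comparison of distance distributions
#'
#' Convenience wrapper around the two-sided Wilcoxon rank-sum test comparing
#' `d` between the two classes.
#'
#' @inheritParams roc_auc
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
d_rank_test <- function(d, labels, positive = "abnormal") {
  y <- labels == positive
  if (!any(y) || all(y)) abort("both classes must be present")
  stats::wilcox.test(d[y], d[!y], exact = FALSE)
}
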
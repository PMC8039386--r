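#' Pipeline configuration
#'
#' Collects the tunable parameters of the full analysis chain: ROI margin,
#' SRAD settings, column sampling for stratification, and the screening
#' split/fit options.
#'
#' @param roi_margin Pixels of context added around the detected wall when
#'   cropping the ROI; the lumen rows inside this margin provide the
#'   homogeneous window for the SRAD speckle scale.
#' @param srad_iterations,srad_time_step,srad_variant SRAD settings (see
#'   [srad_params()]); `srad_iterations = 0` disables filtering.
#' @param n_columns,min_separation,smooth_sigma Stratification settings (see
#'   [aggregate_columns()]).
#' @param train_fraction Train share of the cohort split (default 0.7).
#' @param use_truth_masks Use ground-truth wall masks (oracle mode) instead
#'   of a trained detector.
#' @param detector Optional trained [build_unet()] model used when
#'   `use_truth_masks = FALSE`.
#' @param use_all_for_s,include_fifth Screening-model options (see
#'   [fit_screening_model()]).
#' @param seed Seed for the train/test split.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(roi_margin = 20L,
                            srad_iterations = 100L,
                            srad_time_step = 0.05,
                            srad_variant = "reciprocal",
                            n_columns = 9L,
                            min_separation = 3L,
                            smooth_sigma = 1,
                            train_fraction = 0.7,
                            use_truth_masks = TRUE,
                            detector = NULL,
                            use_all_for_s = FALSE,
                            include_fifth = FALSE,
                            seed = 1L) {
  structure(list(roi_margin = as.integer(roi_margin),
                 srad_iterations = as.integer(srad_iterations),
                 srad_time_step = srad_time_step,
                 srad_variant = srad_variant,
                 n_columns = as.integer(n_columns),
                 min_separation = as.integer(min_separation),
                 smooth_sigma = smooth_sigma,
                 train_fraction = train_fraction,
                 use_truth_masks = use_truth_masks,
                 detector = detector,
                 use_all_for_s = use_all_for_s,
                 include_fifth = include_fifth,
                 seed = seed),
            class = "pipeline_config")
}

# Homogeneous lumen window inside an ROI crop: the rows above the wall mask,
# inset from the borders.  NULL when the margin left too few lumen rows.
lumen_window <- function(crop_mask) {
  first_wall <- suppressWarnings(min(which(rowSums(crop_mask > 0) > 0)))
  if (!is.finite(first_wall) || first_wall < 8L) return(NULL)
  c(2L, first_wall - 4L, 2L, max(2L, ncol(crop_mask) - 1L))
}

#' Measure one wall: ROI crop, SRAD, column stratification
#'
#' The single-image path of the pipeline: derive the ROI from the wall mask
#' ([mask_to_roi()]), crop, filter the crop with SRAD (speckle scale measured
#' in the lumen rows above the wall inside the crop), and stratify the result
#' ([aggregate_columns()], with per-column wall extents read from the mask).
#'
#' @param image Positive image matrix.
#' @param mask Binary wall mask aligned with `image` (ground truth or a
#'   detector prediction).
#' @param config A [pipeline_config()].
#' @return A `wall_stratification` (see [aggregate_columns()]); errors with
#'   class `gastrolayer_unstratifiable` if too few columns show five layers.
#' @export
stratify_wall <- function(image, mask, config = pipeline_config()) {
  box <- mask_to_roi(mask, margin = config$roi_margin)
  crop <- crop_roi(image, box)
  crop_mask <- crop_roi(mask, box)
  if (config$srad_iterations > 0L) {
    win <- lumen_window(crop_mask)
    if (!is.null(win)) {
      params <- srad_params(time_step = config$srad_time_step,
                            n_iterations = config$srad_iterations,
                            variant = config$srad_variant,
                            homog_window = win)
      crop <- srad_filter(crop, params)
    }
  }
  aggregate_columns(crop,
                    n_columns = config$n_columns,
                    roi_mask = crop_mask,
                    min_separation = config$min_separation,
                    smooth_sigma = config$smooth_sigma)
}

#' Run the full screening pipeline on a labeled cohort
#'
#' For every phantom (or image/mask pair): obtain the wall mask (ground truth
#' in oracle mode, otherwise the U-net prediction), measure the
#' layer-proportion vector with [stratify_wall()], then split the cohort,
#' fit the screening model on the training set and evaluate it on the test
#' set ([compute_metrics()] plus [roc_auc()]).  Unstratifiable images are
#' excluded and counted.
#'
#' @param cohort List of `phantom_truth` objects (see [generate_cohort()]),
#'   or any list of lists with elements `image`, `wall_mask`, `label` and
#'   optionally `id`.
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_evaluation`: list with `records`
#'   (per-case tibble: id, label, x1..x5, set, d, prediction), `model`
#'   (the fitted [screening_model()]), `metrics` (one-row tibble including
#'   `AUC` and the test confusion counts), `n_excluded` and `excluded_ids`.
#' @export
evaluate_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(length(cohort) >= 4L)
  if (!config$use_truth_masks && is.null(config$detector))
    abort("`config$detector` is required when use_truth_masks = FALSE")

  rows <- vector("list", length(cohort))
  excluded <- character()
  for (i in seq_along(cohort)) {
    case <- cohort[[i]]
    id <- case$id %||% sprintf("case_%03d", i)
    mask <- if (config$use_truth_masks) case$wall_mask
            else predict_mask(config$detector, case$image)
    strat <- tryCatch(
      stratify_wall(case$image, mask, config),
      gastrolayer_unstratifiable = function(e) e,
      gastrolayer_empty_mask = function(e) e
    )
    if (!inherits(strat, "wall_stratification")) {
      excluded <- c(excluded, id)
      next
    }
    rows[[i]] <- tibble::tibble(id = id, label = case$label,
                                !!!stats::setNames(as.list(strat$x), paste0("x", 1:5)),
                                n_columns_used = strat$n_columns_used)
  }
  records <- dplyr::bind_rows(rows)
  if (nrow(records) < 4L)
    abort("too few stratifiable cases to evaluate the pipeline")

  halves <- split_cohort(records, config$train_fraction, seed = config$seed)
  model <- fit_screening_model(halves$train,
                               use_all_for_s = config$use_all_for_s,
                               include_fifth = config$include_fifth)
  records <- dplyr::bind_rows(
    dplyr::mutate(halves$train, set = "train"),
    dplyr::mutate(halves$test, set = "test")
  )
  records$d <- wall_distance(records, model$s, model$include_fifth)
  records$prediction <- classify_wall(records$d, model)

  test <- records[records$set == "test", , drop = FALSE]
  counts <- confusion_counts(test$prediction, test$label)
  metrics <- compute_metrics(counts)
  metrics$AUC <- roc_auc(test$d, test$label)
  metrics <- dplyr::bind_cols(metrics, tibble::as_tibble(counts),
                              tibble::tibble(n_train = nrow(halves$train),
                                             n_test = nrow(test),
                                             n_excluded = length(excluded)))
  structure(list(records = records, model = model, metrics = metrics,
                 n_excluded = length(excluded), excluded_ids = excluded,
                 config = config),
            class = "pipeline_evaluation")
}

#' @export
print.pipeline_evaluation <- function(x, ...) {
  cat(sprintf("<pipeline_evaluation> %d cases (%d excluded), threshold %.4f\n",
              nrow(x$records), x$n_excluded, x$model$threshold))
  print(x$metrics)
  invisible(x)
}

#' @rdname tidy.wall_stratification
#' @export
tidy.pipeline_evaluation <- function(x, ...) x$records

#' @rdname glance.wall_stratification
#' @export
glance.pipeline_evaluation <- function(x, ...) x$metrics
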
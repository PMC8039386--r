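#' Read a grayscale image
#'
#' Reads an 8-bit PNG (values rescaled to 0..255) or a 16-bit TIFF (native
#' integer values).  Multi-channel files are accepted only when all channels
#' are identical (gray stored as RGB).  Zero-valued pixels are raised to a
#' small positive epsilon with a warning, since the SRAD filter requires
#' strictly positive intensities.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param epsilon Replacement value for zero pixels (default `1e-3`).
#' @return Numeric matrix of positive intensities.
#' @export
read_image <- function(path, epsilon = 1e-3) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    abort(sprintf("unsupported image format `%s` (use PNG or TIFF)", ext))
  )
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    same <- all(vapply(seq_len(ch)[-1L],
                       function(k) identical(img[, , 1L], img[, , k]),
                       logical(1L)))
    if (!same)
      abort("multi-channel image with differing channels: cannot interpret as grayscale")
    img <- img[, , 1L]
  }
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (any(img <= 0)) {
    warn(sprintf("%d nonpositive pixel(s) raised to %g (SRAD requires positive intensities)",
                 sum(img <= 0), epsilon))
    img[img <= 0] <- epsilon
  }
  img
}

#' Write a grayscale image
#'
#' PNG output is 8-bit (values clipped to 0..255); TIFF output is 16-bit
#' (values rounded and clipped to 0..65535), so integer-valued images
#' round-trip exactly through [read_image()].
#'
#' @param image Numeric matrix.
#' @param path Destination ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot_matrix(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(pmin(pmax(round_half_up(image), 0), 255) / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(pmin(pmax(round_half_up(image), 0), 65535) / 65535,
                           path, bits.per.sample = 16L),
    abort(sprintf("unsupported image format `%s` (use PNG or TIFF)", ext))
  )
  invisible(path)
}

#' Read / write a binary mask as PNG (0/255)
#'
#' @param mask Binary matrix.
#' @param path PNG file path.
#' @return `read_mask` returns a 0/1 integer matrix; `write_mask` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot_matrix(mask, "mask")
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Write a phantom with its ground-truth sidecar
#'
#' Stores the image as 16-bit TIFF, the wall mask as PNG, and the ground
#' truth (boundary rows, proportions, label, seed) as a JSON sidecar, under
#' a common stem.
#'
#' @param truth A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @param id File stem.
#' @return The sidecar path, invisibly.
#' @export
write_phantom <- function(truth, dir, id) {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(truth$image, file.path(dir, paste0(id, ".tiff")))
  write_mask(truth$wall_mask, file.path(dir, paste0(id, "_mask.png")))
  sidecar <- file.path(dir, paste0(id, ".json"))
  jsonlite::write_json(
    list(id = id, label = truth$label,
         proportions = truth$proportions,
         wall_top_rows = truth$wall_top_rows,
         boundary_rows = truth$boundary_rows,
         wall_thickness = truth$spec$wall_thickness,
         seed = truth$spec$seed),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a directory of phantoms written by [write_phantom()]
#'
#' @param dir Directory containing `<id>.tiff`, `<id>_mask.png`, `<id>.json`
#'   triples.
#' @return A list of cohort cases usable by [evaluate_pipeline()].
#' @export
read_phantom_dir <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(sidecars) == 0L) abort(sprintf("no phantom sidecars found in %s", dir))
  lapply(sidecars, function(sc) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    stem <- file.path(dir, meta$id)
    list(id = meta$id,
         label = meta$label,
         image = suppressWarnings(read_image(paste0(stem, ".tiff"))),
         wall_mask = read_mask(paste0(stem, "_mask.png")),
         proportions = meta$proportions,
         boundary_rows = meta$boundary_rows)
  })
}

## ---- config-driven runner --------------------------------------------------

config_keys <- list(
  top = c("seed", "out_dir", "stages", "simulate", "evaluate"),
  simulate = c("n_normal", "n_abnormal", "effect_layer", "effect_factor",
               "effect_delta", "height", "width", "wall_top_row",
               "thickness_min", "thickness_max", "speckle_looks",
               "curvature", "jitter_sd"),
  evaluate = c("phantom_dir", "roi_margin", "srad_iterations",
               "srad_time_step", "srad_variant", "n_columns",
               "train_fraction", "use_all_for_s", "include_fifth")
)

check_config_keys <- function(cfg, allowed, where) {
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0L)
    abort(sprintf("invalid config key `%s` in %s", bad[1L], where))
  invisible(cfg)
}

#' Run pipeline stages from a configuration file
#'
#' Reads a YAML configuration and executes the requested stages in pipeline
#' order.  Stage `simulate` generates a phantom cohort and writes it (images,
#' masks, JSON ground truth) to `<out_dir>/phantoms`; stage `evaluate` loads
#' the cohort (from `evaluate$phantom_dir` or the simulated one) and runs
#' [evaluate_pipeline()], writing `report.json` (config hash, seed, standard
#' vector, threshold and all metrics) and `records.csv` to `out_dir`.
#' Re-running an identical configuration reproduces identical outputs.
#'
#' @param config_path Path to a YAML config file.  Recognized keys: `seed`,
#'   `out_dir`, `stages`, and per-stage blocks `simulate` / `evaluate`;
#'   unknown keys raise an error naming the key.
#' @return Invisibly, a list with the artifact paths and (if evaluated) the
#'   `pipeline_evaluation`.
#' @export
run_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  check_config_keys(cfg, config_keys$top, "top level")
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir %||% "."
  stages <- cfg$stages %||% c("simulate", "evaluate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config_hash <- unname(tools::md5sum(config_path))
  artifacts <- list()

  cohort <- NULL
  if ("simulate" %in% stages) {
    sim <- cfg$simulate %||% list()
    check_config_keys(sim, config_keys$simulate, "simulate")
    base <- phantom_spec(
      height = sim$height %||% 256L, width = sim$width %||% 256L,
      wall_top_row = sim$wall_top_row %||% 60L,
      speckle_looks = sim$speckle_looks %||% 4,
      curvature = sim$curvature %||% 0
    )
    effect <- list(layer = sim$effect_layer %||% 1L)
    if (!is.null(sim$effect_delta)) effect$delta <- sim$effect_delta
    else effect$factor <- sim$effect_factor %||% 2
    cohort <- generate_cohort(
      n_normal = sim$n_normal %||% 10L, n_abnormal = sim$n_abnormal %||% 10L,
      abnormal_effect = effect, base_spec = base,
      thickness_range = c(sim$thickness_min %||% 100L, sim$thickness_max %||% 140L),
      jitter_sd = sim$jitter_sd %||% 0.05, seed = seed
    )
    pdir <- file.path(out_dir, "phantoms")
    for (i in seq_along(cohort)) {
      cohort[[i]]$id <- sprintf("phantom_%03d", i)
      write_phantom(cohort[[i]], pdir, cohort[[i]]$id)
    }
    artifacts$phantom_dir <- pdir
  }

  if ("evaluate" %in% stages) {
    ev <- cfg$evaluate %||% list()
    check_config_keys(ev, config_keys$evaluate, "evaluate")
    if (is.null(cohort)) {
      pdir <- ev$phantom_dir %||% file.path(out_dir, "phantoms")
      cohort <- read_phantom_dir(pdir)
    }
    pcfg <- pipeline_config(
      roi_margin = ev$roi_margin %||% 20L,
      srad_iterations = ev$srad_iterations %||% 100L,
      srad_time_step = ev$srad_time_step %||% 0.05,
      srad_variant = ev$srad_variant %||% "reciprocal",
      n_columns = ev$n_columns %||% 9L,
      train_fraction = ev$train_fraction %||% 0.7,
      use_all_for_s = ev$use_all_for_s %||% FALSE,
      include_fifth = ev$include_fifth %||% FALSE,
      seed = seed
    )
    result <- tryCatch(evaluate_pipeline(cohort, pcfg), error = function(e) {
      abort(sprintf("stage `evaluate` failed: %s", conditionMessage(e)),
            parent = e)
    })
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(config_hash = config_hash, seed = seed,
           s = result$model$s, threshold = result$model$threshold,
           train_accuracy = result$model$train_accuracy,
           metrics = as.list(result$metrics),
           n_excluded = result$n_excluded),
      report_path, auto_unbox = TRUE, digits = 10)
    utils::write.csv(result$records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    artifacts$report <- report_path
    artifacts$records <- file.path(out_dir, "records.csv")
    artifacts$evaluation <- result
  }
  invisible(artifacts)
}
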
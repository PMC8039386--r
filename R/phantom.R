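#' Phantom specification for a layered gastric wall
#'
#' Describes the geometry, echogenicity and speckle statistics of a synthetic
#' oral contrast-enhanced ultrasound image: a five-band wall of alternating
#' bright/dark echogenicity embedded in a darker lumen, with multiplicative
#' fully-developed speckle.  The phantom is the test bed for every downstream
#' stage (detection, SRAD filtering, stratification, screening) since the
#' layered geometry and the per-layer proportions are known exactly.
#'
#' @param height,width Image size in pixels.
#' @param wall_top_row First image row (1-based) occupied by the wall at the
#'   left edge of the image.
#' @param wall_thickness Total wall thickness in pixels.
#' @param proportions Numeric length-5 vector of per-layer thickness fractions;
#'   must be nonnegative and sum to 1 (within 1e-9).  The default is the
#'   normal-wall template `c(0.278, 0.133, 0.154, 0.154, 0.280)` renormalized
#'   to sum exactly to 1.
#' @param layer_levels Mean echogenicity of each layer, alternating
#'   bright/dark/bright/dark/bright by default.  All must be positive (the
#'   SRAD filter requires strictly positive intensities).
#' @param background_level Mean echogenicity of the lumen/background; positive.
#' @param speckle_looks Number of looks of the multiplicative gamma speckle;
#'   the per-pixel noise has unit mean and variance `1/speckle_looks`.  Use
#'   `Inf` for a noise-free phantom.
#' @param curvature Maximum downward bowing of the wall, in pixels, following
#'   a half-sine across the image width (0 = flat wall).
#' @param seed RNG seed used when the phantom is generated; `NULL` draws from
#'   the current RNG stream.
#'
#' @return An object of class `phantom_spec` (a validated list).
#' @examples
#' spec <- phantom_spec(wall_thickness = 100, speckle_looks = Inf)
#' truth <- generate_phantom(spec)
#' truth$proportions
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(height = 256L,
                         width = 256L,
                         wall_top_row = 60L,
                         wall_thickness = 100L,
                         proportions = normal_wall_template(),
                         layer_levels = c(180, 60, 150, 50, 170),
                         background_level = 25,
                         speckle_looks = 4,
                         curvature = 0,
                         seed = NULL) {
  spec <- list(
    height = as.integer(height), width = as.integer(width),
    wall_top_row = as.integer(wall_top_row),
    wall_thickness = as.integer(wall_thickness),
    proportions = as.numeric(proportions),
    layer_levels = as.numeric(layer_levels),
    background_level = as.numeric(background_level),
    speckle_looks = speckle_looks,
    curvature = as.numeric(curvature),
    seed = seed
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

#' Normal-wall layer-proportion template
#'
#' The five-layer thickness fractions of a normal gastric wall
#' (mucosa, muscularis mucosa, submucosa, muscularis propria, serosa)
#' used as the default phantom template, renormalized to sum exactly to 1.
#'
#' @return Numeric vector of length 5 summing to 1.
#' @export
normal_wall_template <- function() {
  s <- c(0.278, 0.133, 0.154, 0.154, 0.280)
  s / sum(s)
}

validate_phantom_spec <- function(spec) {
  p <- spec$proportions
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    abort("`proportions` must be 5 nonnegative fractions summing to 1 (within 1e-9)")
  if (length(spec$layer_levels) != 5L || any(spec$layer_levels <= 0))
    abort("`layer_levels` must be 5 positive echogenicities")
  if (spec$background_level <= 0)
    abort("`background_level` must be positive")
  if (!(is.infinite(spec$speckle_looks) || spec$speckle_looks >= 1))
    abort("`speckle_looks` must be >= 1 (or Inf for noise-free)")
  if (spec$curvature < 0) abort("`curvature` must be nonnegative")
  if (spec$wall_top_row < 1L)
    abort("`wall_top_row` must be >= 1")
  if (spec$wall_top_row + spec$wall_thickness + ceiling(spec$curvature) - 1L > spec$height)
    abort("wall (including curvature) must fit inside the image: wall_top_row + wall_thickness + curvature <= height")
  invisible(spec)
}

# Integer per-layer thicknesses: half-up rounding for layers 1-4, remainder
# pixels assigned to the deepest layer.
layer_thicknesses <- function(proportions, wall_thickness) {
  t14 <- round_half_up(proportions[1:4] * wall_thickness)
  t5 <- wall_thickness - sum(t14)
  t <- c(t14, t5)
  if (any(t <= 0))
    abort("layer too thin: a layer rounds to 0 pixels at this wall thickness",
          class = "gastrolayer_layer_too_thin")
  as.integer(t)
}

# Column-wise vertical offset of the wall: half-sine bow, 0 at both image
# edges, `curvature` pixels at the centre.
curvature_offsets <- function(width, curvature) {
  if (curvature == 0) return(integer(width))
  j <- seq_len(width) - 1L
  as.integer(round_half_up(curvature * sin(pi * j / (width - 1L))))
}

#' Generate a synthetic layered-wall ultrasound phantom
#'
#' Renders the noise-free piecewise-constant template described by `spec`
#' (five horizontal, possibly bowed, bands of alternating echogenicity over a
#' darker background), then applies unit-mean multiplicative gamma speckle
#' with variance `1/speckle_looks`.  The returned ground truth records the
#' wall mask, the per-column positions of the four inter-layer boundaries and
#' the exact proportion vector implied by the integer band thicknesses.
#'
#' Boundary convention: `boundary_rows[k, j]` is the first image row (1-based)
#' of layer `k + 1` in column `j`, so consecutive differences of
#' `(wall_top, boundaries, wall_top + wall_thickness)` reproduce the band
#' thicknesses exactly.
#'
#' @param spec A [phantom_spec()].
#' @param label Class label attached to the phantom (`"normal"` or
#'   `"abnormal"`).
#' @return An object of class `phantom_truth`: a list with elements `image`
#'   (numeric matrix), `template` (noise-free image), `wall_mask` (0/1 integer
#'   matrix), `boundary_rows` (4 x width integer matrix), `wall_top_rows`
#'   (per-column first wall row), `proportions` (quantized to the integer band
#'   thicknesses), `label` and `spec`.
#' @examples
#' truth <- generate_phantom(phantom_spec(wall_thickness = 100,
#'                                        speckle_looks = Inf))
#' diff(c(60, truth$boundary_rows[, 1], 160)) / 100  # recovers proportions
#' @export
generate_phantom <- function(spec, label = "normal") {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  t_layers <- layer_thicknesses(spec$proportions, spec$wall_thickness)
  offs <- curvature_offsets(w, spec$curvature)

  template <- matrix(spec$background_level, nrow = h, ncol = w)
  mask <- matrix(0L, nrow = h, ncol = w)
  boundary_rows <- matrix(0L, nrow = 4L, ncol = w)
  wall_top_rows <- spec$wall_top_row + offs
  starts <- cumsum(c(0L, t_layers))       # layer k occupies [starts[k], starts[k+1]) below wall top
  for (j in seq_len(w)) {
    top <- wall_top_rows[j]
    for (k in 1:5) {
      rows <- (top + starts[k]):(top + starts[k + 1L] - 1L)
      template[rows, j] <- spec$layer_levels[k]
    }
    mask[top:(top + spec$wall_thickness - 1L), j] <- 1L
    boundary_rows[, j] <- top + starts[2:5]
  }

  image <- apply_speckle(template, looks = spec$speckle_looks, seed = spec$seed)

  structure(list(
    image = image,
    template = template,
    wall_mask = mask,
    boundary_rows = boundary_rows,
    wall_top_rows = as.integer(wall_top_rows),
    proportions = t_layers / spec$wall_thickness,
    label = label,
    spec = spec
  ), class = "phantom_truth")
}

#' Apply multiplicative speckle noise
#'
#' Multiplies every pixel by an independent gamma variate with unit mean and
#' variance `1/looks` (shape = rate = `looks`), the standard fully-developed
#' speckle model for an L-look amplitude image.  The output is strictly
#' positive whenever the input is.
#'
#' @param image Strictly positive numeric matrix.
#' @param looks Number of looks; `Inf` returns the input unchanged.
#' @param seed Optional RNG seed; the caller's RNG state is preserved.
#' @return Noisy image, same dimensions.
#' @examples
#' img <- matrix(100, 50, 50)
#' noisy <- apply_speckle(img, looks = 4, seed = 1)
#' sd(noisy) / mean(noisy)   # ~ 1/sqrt(4)
#' @export
apply_speckle <- function(image, looks, seed = NULL) {
  check_positive_image(image)
  if (is.infinite(looks)) return(image)
  if (!is.numeric(looks) || looks < 1)
    abort("`looks` must be >= 1 (or Inf for no noise)")
  noise <- with_local_seed(seed, {
    matrix(rgamma(length(image), shape = looks, rate = looks),
           nrow = nrow(image), ncol = ncol(image))
  })
  image * noise
}

#' Derive a training label mask from phantom ground truth
#'
#' Emulates the three annotation styles used when outlining the gastric wall:
#' a single axis-aligned rectangle inside the wall band, two such rectangles
#' covering more of the wall, or the full wall region.  On a flat wall the
#' single rectangle coincides with the band; on a bowed wall the rectangles
#' under-cover it, which is what makes the labeling styles distinguishable in
#' detector training.
#'
#' @param truth A [generate_phantom()] result.
#' @param mode `"one_rect"`, `"two_rect"` or `"full"`.
#' @return 0/1 integer matrix of the same size as the phantom image.
#' @export
make_labels <- function(truth, mode = c("full", "one_rect", "two_rect")) {
  stopifnot(inherits(truth, "phantom_truth"))
  mode <- match.arg(mode)
  if (mode == "full") return(truth$wall_mask)
  tops <- truth$wall_top_rows
  bots <- tops + truth$spec$wall_thickness - 1L   # last wall row per column
  w <- ncol(truth$wall_mask)
  mask <- matrix(0L, nrow = nrow(truth$wall_mask), ncol = w)
  if (mode == "one_rect") {
    r <- largest_inscribed_rect(tops, bots, 1L, w)
    mask[r$top:r$bottom, r$left:r$right] <- 1L
  } else {
    half <- w %/% 2L
    r1 <- largest_inscribed_rect(tops, bots, 1L, half)
    r2 <- largest_inscribed_rect(tops, bots, half + 1L, w)
    mask[r1$top:r1$bottom, r1$left:r1$right] <- 1L
    mask[r2$top:r2$bottom, r2$left:r2$right] <- 1L
  }
  mask
}

# Largest axis-aligned rectangle contained in the band {rows tops[j]..bots[j]}
# over a contiguous column range [j0, j1].  O(W^2) scan over start columns
# with running max/min of the band limits.
largest_inscribed_rect <- function(tops, bots, j0, j1) {
  best <- list(area = -1L)
  for (a in j0:j1) {
    run_top <- tops[a]; run_bot <- bots[a]
    for (b in a:j1) {
      run_top <- max(run_top, tops[b])
      run_bot <- min(run_bot, bots[b])
      hgt <- run_bot - run_top + 1L
      if (hgt <= 0L) break
      area <- hgt * (b - a + 1L)
      if (area > best$area)
        best <- list(area = area, top = run_top, bottom = run_bot,
                     left = a, right = b)
    }
  }
  best
}

#' Generate a labeled phantom cohort
#'
#' Draws `n_normal` phantoms whose layer proportions jitter around the normal
#' template and `n_abnormal` phantoms around a shifted template in which one
#' layer's fraction is scaled by `abnormal_effect$factor` (or shifted by
#' `abnormal_effect$delta`) and the vector renormalized — emulating, e.g.,
#' mucosal thickening.  Jitter is multiplicative log-normal on the simplex
#' (`p * exp(N(0, jitter_sd))`, renormalized), so proportions stay positive
#' and sum to 1.  Wall thickness is drawn uniformly over `thickness_range`.
#'
#' @param n_normal,n_abnormal Cohort sizes.
#' @param abnormal_effect List with `layer` (1-5) and either `factor`
#'   (multiplicative, default 2) or `delta` (additive on the fraction).
#'   `factor = 1` / `delta = 0` produces a null cohort with no class signal.
#' @param base_spec Template [phantom_spec()] supplying geometry, echogenicity
#'   and speckle settings shared by all phantoms.
#' @param thickness_range Length-2 integer range of wall thickness in pixels.
#' @param jitter_sd Standard deviation of the log-normal proportion jitter.
#' @param seed RNG seed making the whole cohort reproducible.
#' @return A list of `phantom_truth` objects with `label` set, of length
#'   `n_normal + n_abnormal`.
#' @examples
#' cohort <- generate_cohort(3, 2, seed = 1,
#'                           base_spec = phantom_spec(speckle_looks = Inf))
#' vapply(cohort, function(p) p$label, "")
#' @export
generate_cohort <- function(n_normal,
                            n_abnormal,
                            abnormal_effect = list(layer = 1L, factor = 2),
                            base_spec = phantom_spec(),
                            thickness_range = c(100L, 140L),
                            jitter_sd = 0.05,
                            seed = NULL) {
  stopifnot(n_normal >= 0, n_abnormal >= 0, n_normal + n_abnormal > 0)
  template <- base_spec$proportions
  abnormal_template <- shift_proportions(template, abnormal_effect)
  with_local_seed(seed, {
    labels <- c(rep("normal", n_normal), rep("abnormal", n_abnormal))
    lapply(seq_along(labels), function(i) {
      tmpl <- if (labels[i] == "normal") template else abnormal_template
      p <- tmpl * exp(rnorm(5L, 0, jitter_sd))
      p <- p / sum(p)
      thick <- as.integer(round_half_up(runif(1L, thickness_range[1], thickness_range[2])))
      spec <- base_spec
      spec$proportions <- p
      spec$wall_thickness <- thick
      spec$seed <- sample.int(.Machine$integer.max, 1L)
      validate_phantom_spec(spec)
      generate_phantom(spec, label = labels[i])
    })
  })
}

# Shift a proportion template by the abnormal effect and renormalize.
shift_proportions <- function(p, effect) {
  if (is.null(effect)) return(p)
  layer <- effect$layer %||% 1L
  stopifnot(layer %in% 1:5)
  if (!is.null(effect$delta)) {
    p[layer] <- p[layer] + effect$delta
  } else {
    p[layer] <- p[layer] * (effect$factor %||% 2)
  }
  if (any(p < 0))
    abort("abnormal effect produces a negative layer proportion")
  p / sum(p)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %dx%d, wall %d px at row %d, label=%s\n",
              nrow(x$image), ncol(x$image), x$spec$wall_thickness,
              x$spec$wall_top_row, x$label))
  cat("proportions:", paste(sprintf("%.3f", x$proportions), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d, wall %d px, looks=%s, curvature=%g\n",
              x$height, x$width, x$wall_thickness,
              format(x$speckle_looks), x$curvature))
  invisible(x)
}
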
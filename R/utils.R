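#' @importFrom stats rnorm rgamma runif sd quantile
#' @importFrom rlang abort warn .data
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the RNG stream alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic half-up rounding (round() in R rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

stopifnot_matrix <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    abort(sprintf("`%s` must be a numeric matrix", arg))
  invisible(x)
}

check_positive_image <- function(x, arg = "image") {
  stopifnot_matrix(x, arg)
  if (any(!is.finite(x)) || any(x <= 0))
    abort("SRAD requires positive intensities: image contains nonpositive or non-finite values",
          class = "gastrolayer_nonpositive_image")
  invisible(x)
}

# Shift a matrix by one pixel towards each compass direction, replicating the
# edge row/column (Neumann / zero-flux boundary handling).
shift_up    <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_down  <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
shift_left  <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shift_right <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

`%||%` <- function(a, b) if (is.null(a)) b else a
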
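#' U-net detector configuration
#'
#' A compact encoder-decoder segmentation network: the encoder applies 3x3
#' convolutions (ReLU) and 2x2 max pooling `depth` times, doubling the number
#' of feature channels at each stage; the decoder upsamples `depth` times by
#' 2x2 transposed convolution, halving the channels and concatenating the
#' encoder feature map of the same scale (skip connection), and a final 1x1
#' convolution with per-pixel softmax yields the background/wall probability
#' map.  With the default `depth = 4` the contracting path contains ten 3x3
#' convolutions and four poolings.
#'
#' @param input_size `c(rows, cols)` the image is resized to before the
#'   forward pass; both must be divisible by `2^depth`.
#' @param depth Number of pooling stages (default 4).
#' @param base_channels Feature channels at the first encoder stage; doubled
#'   at every stage.
#' @param epochs,batch_size,learning_rate Training schedule (Adam, per-image
#'   steps; `batch_size` is kept at 1 in this implementation).
#' @param intensity_scale Intensities are divided by this constant before the
#'   forward pass (default 255, the 8-bit white level).
#' @param seed Seed for weight initialization and epoch shuffling.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(input_size = c(256L, 256L),
                        depth = 4L,
                        base_channels = 16L,
                        epochs = 30L,
                        batch_size = 1L,
                        learning_rate = 1e-3,
                        intensity_scale = 255,
                        seed = 1L) {
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  if (length(input_size) != 2L || any(input_size < 2^depth))
    abort("`input_size` must be two positive integers >= 2^depth")
  if (any(input_size %% 2L^depth != 0L))
    abort("`input_size` must be divisible by 2^depth")
  structure(list(input_size = input_size, depth = depth,
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 intensity_scale = intensity_scale,
                 seed = seed),
            class = "unet_config")
}

## ---- low-level layers (H x W x C arrays, column-major) ---------------------

# im2col for a 3x3 'same' zero-padded convolution: columns ordered with the
# kernel offset outermost (k = 1..9, row offset fastest) and the input
# channel innermost, matching the weight-matrix row layout.
im2col3 <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  P <- array(0, c(H + 2L, W + 2L, C))
  P[2:(H + 1L), 2:(W + 1L), ] <- x
  M <- matrix(0, H * W, 9L * C)
  for (k in 1:9) {
    di <- (k - 1L) %% 3L
    dj <- (k - 1L) %/% 3L
    M[, ((k - 1L) * C + 1L):(k * C)] <-
      P[(1L + di):(H + di), (1L + dj):(W + dj), , drop = FALSE]
  }
  M
}

conv3_fwd <- function(x, layer) {
  d <- dim(x)
  M <- im2col3(x)
  Y <- M %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  list(out = array(Y, c(d[1L], d[2L], length(layer$b))), M = M)
}

# Gradient of the same-padded 3x3 convolution: dX is the same-padded
# convolution of dY with the 180-degree-rotated, channel-transposed kernel.
conv3_bwd <- function(dy, layer, cache, xdim) {
  cin <- xdim[3L]; cout <- dim(dy)[3L]
  DY <- matrix(dy, ncol = cout)
  dW <- crossprod(cache$M, DY)
  db <- colSums(DY)
  A <- array(layer$W, c(cin, 9L, cout))
  B <- aperm(A[, 9:1, , drop = FALSE], c(3L, 2L, 1L))
  Wb <- matrix(B, nrow = 9L * cout, ncol = cin)
  dx <- array(im2col3(dy) %*% Wb, xdim)
  list(dx = dx, dW = dW, db = db)
}

conv1_fwd <- function(x, layer) {
  d <- dim(x)
  Xm <- matrix(x, ncol = d[3L])
  Y <- Xm %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  list(out = array(Y, c(d[1L], d[2L], length(layer$b))), Xm = Xm)
}

conv1_bwd <- function(dy, layer, cache, xdim) {
  DY <- matrix(dy, ncol = dim(dy)[3L])
  list(dx = array(DY %*% t(layer$W), xdim),
       dW = crossprod(cache$Xm, DY),
       db = colSums(DY))
}

maxpool_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2L], 2L); j2 <- j1 + 1L
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; dd <- x[i2, j2, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(out = y, masks = list(m1, m2, m3, m4), xdim = d)
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$xdim
  i1 <- seq(1L, d[1L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2L], 2L); j2 <- j1 + 1L
  dx <- array(0, d)
  dx[i1, j1, ] <- dy * cache$masks[[1L]]
  dx[i2, j1, ] <- dy * cache$masks[[2L]]
  dx[i1, j2, ] <- dy * cache$masks[[3L]]
  dx[i2, j2, ] <- dy * cache$masks[[4L]]
  dx
}

# 2x2 stride-2 transposed convolution ("deconvolution"): each input pixel
# paints a 2x2 output block.  Weight matrix is (Cin, 4*Cout) with the block
# offset outermost; offsets d = 1..4 map to (row, col) = (0,0),(1,0),(0,1),(1,1).
upconv_fwd <- function(x, layer) {
  d <- dim(x); h <- d[1L]; w <- d[2L]
  cout <- length(layer$b)
  Xm <- matrix(x, ncol = d[3L])
  Ym <- Xm %*% layer$W
  y <- array(0, c(2L * h, 2L * w, cout))
  i1 <- seq(1L, 2L * h, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * w, 2L); j2 <- j1 + 1L
  blk <- function(dd) array(Ym[, ((dd - 1L) * cout + 1L):(dd * cout)], c(h, w, cout))
  y[i1, j1, ] <- blk(1L); y[i2, j1, ] <- blk(2L)
  y[i1, j2, ] <- blk(3L); y[i2, j2, ] <- blk(4L)
  y <- y + rep(layer$b, each = 4L * h * w)
  list(out = y, Xm = Xm)
}

upconv_bwd <- function(dy, layer, cache, xdim) {
  h <- xdim[1L]; w <- xdim[2L]
  cout <- dim(dy)[3L]
  i1 <- seq(1L, 2L * h, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * w, 2L); j2 <- j1 + 1L
  G <- cbind(matrix(dy[i1, j1, , drop = FALSE], ncol = cout),
             matrix(dy[i2, j1, , drop = FALSE], ncol = cout),
             matrix(dy[i1, j2, , drop = FALSE], ncol = cout),
             matrix(dy[i2, j2, , drop = FALSE], ncol = cout))
  list(dx = array(G %*% t(layer$W), xdim),
       dW = crossprod(cache$Xm, G),
       db = colSums(matrix(dy, ncol = cout)))
}

relu <- function(x) pmax(x, 0)

## ---- parameter initialization ----------------------------------------------

he_layer <- function(fan_rows, cout, fan_in) {
  list(W = matrix(rnorm(fan_rows * cout, sd = sqrt(2 / fan_in)), fan_rows, cout),
       b = numeric(cout))
}

init_unet_params <- function(cfg) {
  with_local_seed(cfg$seed, {
    ch <- cfg$base_channels * 2L^(0:cfg$depth)   # stage channels incl. bottleneck
    enc <- vector("list", cfg$depth)
    cin <- 1L
    for (i in seq_len(cfg$depth)) {
      enc[[i]] <- list(c1 = he_layer(9L * cin, ch[i], 9L * cin),
                       c2 = he_layer(9L * ch[i], ch[i], 9L * ch[i]))
      cin <- ch[i]
    }
    bott <- list(c1 = he_layer(9L * ch[cfg$depth], ch[cfg$depth + 1L], 9L * ch[cfg$depth]),
                 c2 = he_layer(9L * ch[cfg$depth + 1L], ch[cfg$depth + 1L],
                               9L * ch[cfg$depth + 1L]))
    dec <- vector("list", cfg$depth)
    for (i in seq_len(cfg$depth)) {       # dec[[i]] restores the scale of enc stage i
      cup <- ch[i + 1L]                   # channels entering the up-conv
      dec[[i]] <- list(up = list(W = matrix(rnorm(cup * 4L * ch[i], sd = sqrt(2 / cup)),
                                            cup, 4L * ch[i]),
                                 b = numeric(ch[i])),
                       c1 = he_layer(9L * 2L * ch[i], ch[i], 9L * 2L * ch[i]),
                       c2 = he_layer(9L * ch[i], ch[i], 9L * ch[i]))
    }
    out <- list(W = matrix(rnorm(ch[1L] * 2L, sd = sqrt(2 / ch[1L])), ch[1L], 2L),
                b = numeric(2L))
    list(enc = enc, bott = bott, dec = dec, out = out)
  })
}

## ---- forward / backward ----------------------------------------------------

unet_forward <- function(params, x, depth, keep_cache = FALSE) {
  a <- if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
  cache <- list(enc = vector("list", depth), dec = vector("list", depth))
  skips <- vector("list", depth)
  for (i in seq_len(depth)) {
    st <- list(xdim1 = dim(a))
    f1 <- conv3_fwd(a, params$enc[[i]]$c1); st$M1 <- f1$M; st$pre1 <- f1$out
    a1 <- relu(f1$out)
    st$xdim2 <- dim(a1)
    f2 <- conv3_fwd(a1, params$enc[[i]]$c2); st$M2 <- f2$M; st$pre2 <- f2$out
    s <- relu(f2$out)
    skips[[i]] <- s
    pl <- maxpool_fwd(s)
    st$pool <- pl[c("masks", "xdim")]
    a <- pl$out
    cache$enc[[i]] <- st
  }
  cache$bott <- list(xdim1 = dim(a))
  f1 <- conv3_fwd(a, params$bott$c1); cache$bott$M1 <- f1$M; cache$bott$pre1 <- f1$out
  a1 <- relu(f1$out)
  cache$bott$xdim2 <- dim(a1)
  f2 <- conv3_fwd(a1, params$bott$c2); cache$bott$M2 <- f2$M; cache$bott$pre2 <- f2$out
  a <- relu(f2$out)
  for (i in rev(seq_len(depth))) {
    st <- list(updim = dim(a))
    up <- upconv_fwd(a, params$dec[[i]]$up); st$upXm <- up$Xm
    u <- up$out
    cat_in <- array(c(u, skips[[i]]), c(dim(u)[1:2], dim(u)[3L] * 2L))
    st$xdim1 <- dim(cat_in)
    f1 <- conv3_fwd(cat_in, params$dec[[i]]$c1); st$M1 <- f1$M; st$pre1 <- f1$out
    a1 <- relu(f1$out)
    st$xdim2 <- dim(a1)
    f2 <- conv3_fwd(a1, params$dec[[i]]$c2); st$M2 <- f2$M; st$pre2 <- f2$out
    a <- relu(f2$out)
    cache$dec[[i]] <- st
  }
  cache$outdim <- dim(a)
  fo <- conv1_fwd(a, params$out); cache$outXm <- fo$Xm
  logits <- fo$out
  if (keep_cache) list(logits = logits, cache = cache) else list(logits = logits)
}

# Per-pixel 2-class softmax over the channel dimension.
softmax2 <- function(logits) {
  m <- pmax(logits[, , 1L], logits[, , 2L])
  e1 <- exp(logits[, , 1L] - m)
  e2 <- exp(logits[, , 2L] - m)
  p2 <- e2 / (e1 + e2)
  array(c(1 - p2, p2), dim(logits))
}

# Mean pixel-wise cross-entropy and its gradient w.r.t. the logits.
ce_loss_grad <- function(logits, target) {
  p <- softmax2(logits)
  pw <- p[, , 2L]
  eps <- 1e-12
  loss <- -mean(target * log(pw + eps) + (1 - target) * log(1 - pw + eps))
  n <- length(target)
  d2 <- (pw - target) / n
  list(loss = loss, dlogits = array(c(-d2, d2), dim(logits)))
}

unet_backward <- function(params, cache, dlogits, depth) {
  g <- list(enc = vector("list", depth), dec = vector("list", depth))
  bo <- conv1_bwd(dlogits, params$out, list(Xm = cache$outXm), cache$outdim)
  g$out <- list(W = bo$dW, b = bo$db)
  da <- bo$dx
  for (i in seq_len(depth)) {           # decoder stages, innermost (i = 1) first
    st <- cache$dec[[i]]
    d2 <- da * (st$pre2 > 0)
    b2 <- conv3_bwd(d2, params$dec[[i]]$c2, list(M = st$M2), st$xdim2)
    d1 <- b2$dx * (st$pre1 > 0)
    b1 <- conv3_bwd(d1, params$dec[[i]]$c1, list(M = st$M1), st$xdim1)
    half <- st$xdim1[3L] %/% 2L
    du <- b1$dx[, , seq_len(half), drop = FALSE]
    dskip <- b1$dx[, , half + seq_len(half), drop = FALSE]
    bu <- upconv_bwd(du, params$dec[[i]]$up, list(Xm = st$upXm), st$updim)
    g$dec[[i]] <- list(up = list(W = bu$dW, b = bu$db),
                       c1 = list(W = b1$dW, b = b1$db),
                       c2 = list(W = b2$dW, b = b2$db))
    g$dec[[i]]$dskip <- dskip
    da <- bu$dx
  }
  st <- cache$bott
  d2 <- da * (st$pre2 > 0)
  b2 <- conv3_bwd(d2, params$bott$c2, list(M = st$M2), st$xdim2)
  d1 <- b2$dx * (st$pre1 > 0)
  b1 <- conv3_bwd(d1, params$bott$c1, list(M = st$M1), st$xdim1)
  g$bott <- list(c1 = list(W = b1$dW, b = b1$db),
                 c2 = list(W = b2$dW, b = b2$db))
  da <- b1$dx
  for (i in rev(seq_len(depth))) {      # encoder stages, deepest first
    st <- cache$enc[[i]]
    ds <- maxpool_bwd(da, st$pool) + g$dec[[i]]$dskip
    g$dec[[i]]$dskip <- NULL
    d2 <- ds * (st$pre2 > 0)
    b2 <- conv3_bwd(d2, params$enc[[i]]$c2, list(M = st$M2), st$xdim2)
    d1 <- b2$dx * (st$pre1 > 0)
    b1 <- conv3_bwd(d1, params$enc[[i]]$c1, list(M = st$M1), st$xdim1)
    g$enc[[i]] <- list(c1 = list(W = b1$dW, b = b1$db),
                       c2 = list(W = b2$dW, b = b2$db))
    da <- b1$dx
  }
  g
}

# Apply fn(param_leaf, grad_leaf, state_leaf) over parallel nested lists of
# numeric leaves (W matrices and b vectors).
tree_map <- function(p, g, s, fn) {
  if (is.numeric(p)) return(fn(p, g, s))
  out <- p
  for (nm in names(p)) out[[nm]] <- tree_map(p[[nm]], g[[nm]], s[[nm]], fn)
  out
}

tree_zero <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, tree_zero)
}

## ---- user-facing detector --------------------------------------------------

#' Build an untrained wall-detection U-net
#'
#' Initializes the network weights (He-normal, seeded from the config) and
#' returns a detector that can be trained with [train_detector()] or applied
#' directly with [predict_mask()] / [predict_prob()].
#'
#' @param cfg A [unet_config()].
#' @return An object of class `wall_detector`.
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  structure(list(cfg = cfg,
                 params = init_unet_params(cfg),
                 history = tibble::tibble(epoch = integer(), loss = numeric())),
            class = "wall_detector")
}

resize_image <- function(m, size, filter = "bilinear") {
  if (all(dim(m) == size)) return(m)
  EBImage::resize(m, w = size[1L], h = size[2L], filter = filter)
}

prepare_pair <- function(image, mask, cfg) {
  if (!all(dim(image) == dim(mask)))
    abort("image and mask dimensions differ")
  list(x = resize_image(image, cfg$input_size) / cfg$intensity_scale,
       t = resize_image(mask, cfg$input_size, filter = "none"))
}

#' Train the wall detector
#'
#' Minimizes mean per-pixel softmax cross-entropy with Adam, one image per
#' step, shuffling the image order each epoch.  Training is deterministic for
#' a fixed config seed on one machine.
#'
#' @param images List of numeric image matrices.
#' @param masks List of 0/1 mask matrices aligned with `images`.
#' @param cfg A [unet_config()].
#' @param model Optional detector from [build_unet()] to continue training;
#'   by default a fresh one is initialized from `cfg`.
#' @return A trained `wall_detector`; `$history` holds the per-epoch mean
#'   loss.
#' @export
train_detector <- function(images, masks, cfg, model = NULL) {
  stopifnot(inherits(cfg, "unet_config"))
  if (length(images) == 0L) abort("empty training set")
  if (length(images) != length(masks)) abort("images and masks differ in length")
  pairs <- lapply(seq_along(images), function(i)
    prepare_pair(images[[i]], masks[[i]], cfg))
  if (is.null(model)) model <- build_unet(cfg)
  params <- model$params
  mstate <- tree_zero(params)
  vstate <- tree_zero(params)
  lr <- cfg$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_local_seed(cfg$seed + ep, sample(length(pairs)))
    ep_loss <- 0
    for (i in ord) {
      fw <- unet_forward(params, pairs[[i]]$x, cfg$depth, keep_cache = TRUE)
      lg <- ce_loss_grad(fw$logits, pairs[[i]]$t)
      ep_loss <- ep_loss + lg$loss
      grads <- unet_backward(params, fw$cache, lg$dlogits, cfg$depth)
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      mstate <- tree_map(mstate, grads, NULL, function(m, g, s) b1 * m + (1 - b1) * g)
      vstate <- tree_map(vstate, grads, NULL, function(v, g, s) b2 * v + (1 - b2) * g^2)
      params <- tree_map(params, mstate, vstate,
                         function(p, m, v) p - lr * corr * m / (sqrt(v) + eps))
    }
    losses[ep] <- ep_loss / length(pairs)
  }
  model$params <- params
  model$history <- dplyr::bind_rows(model$history,
                                    tibble::tibble(epoch = seq_len(cfg$epochs),
                                                   loss = losses))
  model
}

#' Per-pixel class-probability map
#'
#' Runs the forward pass at the configured input size and returns the
#' two-channel softmax output (background, wall), resized back to the input
#' image's shape; the two channels sum to 1 at every pixel.
#'
#' @param model A `wall_detector`.
#' @param image Numeric image matrix.
#' @return Array `c(nrow(image), ncol(image), 2)` of probabilities.
#' @export
predict_prob <- function(model, image) {
  stopifnot(inherits(model, "wall_detector"))
  if (length(dim(image)) != 2L) abort("`image` must be a 2-D matrix")
  cfg <- model$cfg
  x <- resize_image(image, cfg$input_size) / cfg$intensity_scale
  p <- softmax2(unet_forward(model$params, x, cfg$depth)$logits)
  pw <- resize_image(p[, , 2L], dim(image))
  pw <- pmin(pmax(pw, 0), 1)
  array(c(1 - pw, pw), c(dim(image), 2L))
}

#' Predict a binary wall mask
#'
#' Argmax of the softmax output (wall probability >= 0.5), resized back to
#' the original image shape with nearest-neighbor interpolation.
#'
#' @inheritParams predict_prob
#' @return 0/1 integer matrix matching `dim(image)`.
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "wall_detector"))
  if (length(dim(image)) != 2L) abort("`image` must be a 2-D matrix")
  cfg <- model$cfg
  x <- resize_image(image, cfg$input_size) / cfg$intensity_scale
  p <- softmax2(unet_forward(model$params, x, cfg$depth)$logits)
  m <- (p[, , 2L] >= 0.5) * 1
  out <- resize_image(m, dim(image), filter = "none")
  matrix(as.integer(out >= 0.5), nrow(image), ncol(image))
}

#' @export
print.wall_detector <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<wall_detector> input %dx%d, depth %d, base %d channels, %d epochs trained\n",
              cfg$input_size[1], cfg$input_size[2], cfg$depth,
              cfg$base_channels, nrow(x$history)))
  invisible(x)
}
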
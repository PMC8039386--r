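# Shared fixtures and independent oracles used across test files.

# Flat noise-free five-band phantom with known geometry.
flat_phantom <- function(height = 200L, width = 64L, wall_top = 50L,
                         thickness = 100L, proportions = rep(0.2, 5),
                         looks = Inf, seed = 1L, curvature = 0) {
  generate_phantom(phantom_spec(
    height = height, width = width, wall_top_row = wall_top,
    wall_thickness = thickness, proportions = proportions,
    speckle_looks = looks, curvature = curvature, seed = seed
  ))
}

# Naive 1-D SRAD reference: explicit loops, replicated ends, arithmetic-mean
# edge diffusivities — written independently of the package's vectorized
# implementation.
srad_1d_oracle <- function(v, n_iter, dt, window_idx, variant = "reciprocal",
                           clamp = TRUE) {
  n <- length(v)
  for (it in seq_len(n_iter)) {
    left <- function(i) if (i == 1L) 1L else i - 1L
    right <- function(i) if (i == n) n else i + 1L
    q <- numeric(n)
    for (i in seq_len(n)) {
      vl <- v[left(i)]; vr <- v[right(i)]
      g <- (vr - vl) / 2
      lap <- vl + vr - 2 * v[i]
      num <- 0.5 * (g / v[i])^2 - (1 / 16) * (lap / v[i])^2
      if (num < 0) num <- 0
      den <- (1 + 0.25 * lap / v[i])^2
      if (den < 1e-12) den <- 1e-12
      q[i] <- sqrt(num / den)
    }
    w <- v[window_idx]
    q0 <- sqrt(mean((w - mean(w))^2)) / mean(w)
    cfun <- function(qq) {
      if (q0 == 0) return(1)
      r <- (qq^2 - q0^2) / (q0^2 * (1 + q0^2))
      cc <- if (variant == "reciprocal") 1 / (1 + r) else exp(-r)
      if (clamp) cc <- min(max(cc, 0), 1)
      cc
    }
    cf <- vapply(q, cfun, numeric(1))
    v_new <- numeric(n)
    for (i in seq_len(n)) {
      div <- 0.5 * (cf[i] + cf[left(i)]) * (v[left(i)] - v[i]) +
             0.5 * (cf[i] + cf[right(i)]) * (v[right(i)] - v[i])
      v_new[i] <- v[i] + dt * div
    }
    v <- pmax(v_new, 1e-12 * mean(v))
  }
  v
}

# Mann-Whitney pair-counting AUC oracle: fraction of (abnormal, normal)
# pairs ordered correctly, half credit for ties.
auc_pair_oracle <- function(d, labels, positive = "abnormal") {
  da <- d[labels == positive]
  dn <- d[labels != positive]
  tot <- 0
  for (a in da) for (b in dn) tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(da) * length(dn))
}

# Brute-force threshold sweep: best accuracy of "abnormal iff d >= t" over a
# dense grid of candidate thresholds.
threshold_sweep_oracle <- function(d, labels, n_grid = 1000L,
                                   positive = "abnormal") {
  y <- labels == positive
  grid <- seq(min(d) - 1, max(d) + 1, length.out = n_grid)
  max(vapply(grid, function(t) mean((d >= t) == y), numeric(1)))
}

# Direct evaluation of the printed metric formulas, independent of
# compute_metrics().
metrics_direct <- function(tp, tn, fp, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  mden <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  list(
    ACC = (tp + tn) / (tp + tn + fp + fn),
    SENS = rec,
    SPEC = div(tn, tn + fp),
    PPV = prec,
    NPV = div(tn, tn + fn),
    MCC = if (mden == 0) NA_real_ else (tp * tn - fp * fn) / mden,
    F1 = 2 * prec * rec / (prec + rec)
  )
}
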
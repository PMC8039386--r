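test_that("ICOV is zero on constant images and invariant to intensity scaling", {
  expect_equal(icov(matrix(5, 10, 10)), matrix(0, 10, 10))
  set.seed(1)
  img <- matrix(runif(200, 10, 200), 10, 20)
  expect_equal(icov(3.7 * img), icov(img), tolerance = 1e-12)
  expect_error(icov(matrix(c(1, 0, 1, 1), 2, 2)),
               class = "gastrolayer_nonpositive_image")
})

test_that("ICOV on a 1-D step profile matches hand-evaluated finite differences", {
  a <- 10; b <- 30
  v <- c(a, a, a, a, b, b, b, b)
  q <- icov(matrix(v, nrow = 1))[1, ]
  # interior flat samples (replicated ends): gradient and Laplacian are 0
  expect_equal(q[c(2, 7)], c(0, 0))
  # at i = 4: g = (b - a)/2, lap = b - a; hand-evaluate the formula
  g <- (b - a) / 2; lap <- b - a
  num <- max(0.5 * (g / a)^2 - (1 / 16) * (lap / a)^2, 0)
  den <- (1 + 0.25 * lap / a)^2
  expect_equal(q[4], sqrt(num / den), tolerance = 1e-12)
  # at i = 5 the same with intensity b and lap = -(b - a)
  num5 <- max(0.5 * (g / b)^2 - (1 / 16) * (lap / b)^2, 0)
  den5 <- (1 - 0.25 * lap / b)^2
  expect_equal(q[5], sqrt(num5 / den5), tolerance = 1e-12)
  # edge dominates the flat region
  expect_gt(min(q[4:5]), max(q[c(2, 7)]))
})

test_that("speckle scale is the window's coefficient of variation", {
  expect_equal(speckle_scale(matrix(7, 5, 5), c(1, 3, 1, 3)), 0)
  expect_equal(speckle_scale(matrix(c(1, 1, 3, 3), 2, 2), c(1, 2, 1, 2)), 0.5)
  set.seed(2)
  img <- matrix(runif(100, 1, 9), 10, 10)
  expect_equal(speckle_scale(5 * img, c(2, 8, 2, 8)),
               speckle_scale(img, c(2, 8, 2, 8)), tolerance = 1e-12)
  expect_error(speckle_scale(img, c(1, 20, 1, 5)), "inside")
})

test_that("diffusion coefficient equals 1 at q = q0 and vanishes for large q", {
  q0 <- 0.4
  qm <- matrix(q0, 3, 3)
  expect_equal(diffusion_coefficient(qm, q0, "reciprocal"), matrix(1, 3, 3))
  expect_equal(diffusion_coefficient(qm, q0, "exponential"), matrix(1, 3, 3))
  big <- matrix(1e4, 2, 2)
  expect_lt(max(diffusion_coefficient(big, q0, "reciprocal")), 1e-6)
  expect_lt(max(diffusion_coefficient(big, q0, "exponential")), 1e-6)
  # hand-computed value, no clamping
  expect_equal(diffusion_coefficient(matrix(2, 1, 1), 1, "reciprocal",
                                     clamp_c = FALSE)[1, 1], 0.4)
  # clamping keeps c in [0, 1] where q < q0
  small <- diffusion_coefficient(matrix(0.1, 2, 2), 1, "reciprocal")
  expect_true(all(small >= 0 & small <= 1))
  # degenerate q0 = 0: everything diffuses
  expect_equal(diffusion_coefficient(matrix(2, 2, 2), 0), matrix(1, 2, 2))
})

test_that("one SRAD step fixes constants, respects c = 0, and conserves mass", {
  img <- matrix(42, 8, 8)
  expect_equal(srad_step(img, matrix(1, 8, 8), 0.1), img)
  set.seed(3)
  rnd <- matrix(runif(256, 50, 150), 16, 16)
  expect_equal(srad_step(rnd, matrix(0, 16, 16), 0.1), rnd)
  cf <- diffusion_coefficient(icov(rnd), 0.3)
  expect_equal(mean(srad_step(rnd, cf, 0.1)), mean(rnd), tolerance = 1e-12)
  expect_error(srad_step(rnd, cf, 0.3), "time_step")
})

test_that("full filter is the identity at 0 iterations and scale-invariant", {
  set.seed(4)
  img <- matrix(runif(400, 20, 220), 20, 20)
  p0 <- srad_params(n_iterations = 0, homog_window = c(2, 8, 2, 8))
  expect_identical(srad_filter(img, p0), img)
  p <- srad_params(n_iterations = 25, homog_window = c(2, 8, 2, 8))
  f1 <- srad_filter(img, p)
  fk <- srad_filter(7.3 * img, p)
  expect_lt(max(abs(fk - 7.3 * f1) / (7.3 * f1)), 1e-6)
  # constant image is a fixed point at every iteration
  cimg <- matrix(9, 12, 12)
  expect_equal(srad_filter(cimg, p), cimg)
})

test_that("SRAD on a 1-D profile matches the loop-based reference step by step", {
  v <- c(80, 82, 79, 81, 160, 158, 161, 159)
  win <- c(1, 1, 1, 4)
  for (k in 1:5) {
    for (variant in c("reciprocal", "exponential")) {
      ours <- srad_filter(matrix(v, nrow = 1),
                          srad_params(time_step = 0.1, n_iterations = k,
                                      variant = variant, homog_window = win))
      ref <- srad_1d_oracle(v, k, 0.1, 1:4, variant = variant)
      expect_equal(ours[1, ], ref, tolerance = 1e-10)
    }
  }
})

test_that("SRAD smooths speckle inside bands while keeping the edge in place", {
  # two-band phantom, levels 100/200, multiplicative speckle with 4 looks
  set.seed(8)
  template <- rbind(matrix(100, 30, 64), matrix(200, 30, 64))
  noisy <- apply_speckle(template, looks = 4, seed = 8)
  p <- srad_params(time_step = 0.1, n_iterations = 50,
                   homog_window = c(5, 25, 5, 60))
  filtered <- srad_filter(noisy, p)
  cv <- function(m) sd(m) / mean(m)
  expect_lt(cv(filtered[5:25, ]), 0.5 * cv(noisy[5:25, ]))
  expect_lt(cv(filtered[35:55, ]), 0.5 * cv(noisy[35:55, ]))
  # band boundary from the maximum vertical gradient of the column means
  edge_of <- function(m) {
    prof <- rowMeans(m)
    which.max(abs(diff(prof)))
  }
  expect_lte(abs(edge_of(filtered) - 30), 1)
  # homogeneous-region and edge behavior of the diffusivity
  q <- icov(filtered)
  cf <- diffusion_coefficient(q, speckle_scale(filtered, c(5, 25, 5, 60)))
  expect_gt(mean(cf[c(5:25, 35:55), ]), 0.8)
  expect_lt(mean(cf[30:31, ]), mean(cf[c(5:25, 35:55), ]))
})
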
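# Composite loss: voxel-wise L2, slice-sampled perceptual distance,
# combination and gradients.

test_that("l2 loss matches its definition and a loop oracle", {
  p <- with_seed_test(1, array(runif(6^3), c(6, 6, 6)))
  expect_identical(l2_loss(p, p), 0)
  expect_equal(l2_loss(p + 0.1, p), 0.01, tolerance = 1e-12)
  t <- with_seed_test(2, array(runif(6^3), c(6, 6, 6)))
  # brute-force voxel loop
  acc <- 0
  for (i in seq_along(p)) acc <- acc + (p[i] - t[i])^2
  expect_equal(l2_loss(p, t), acc / length(p), tolerance = 1e-6)
  expect_error(l2_loss(p, array(0, c(5, 5, 5))), "mismatch")
})

test_that("slice distance is zero at identity and symmetric", {
  fx <- tiny_fx()
  x <- with_seed_test(3, matrix(runif(24^2), 24, 24))
  y <- with_seed_test(4, matrix(runif(24^2), 24, 24))
  expect_identical(lpips_2d(x, x, fx), 0)
  expect_equal(lpips_2d(x, y, fx), lpips_2d(y, x, fx))
  expect_gt(lpips_2d(x, y, fx), 0)
  expect_error(lpips_2d(x, matrix(0, 3, 3), fx), "shape")
  expect_error(lpips_2d(x * NA, y, fx), "finite")
})

test_that("slice distance equals a hand-rolled recomputation from raw activations", {
  # independent oracle: evaluate the definition directly on the cached
  # feature maps of a 2-layer extractor
  fx <- feature_extractor(n_layers = 2L, widths = c(4L, 5L),
                          strides = c(2L, 2L), seed = 9L)
  x <- with_seed_test(5, matrix(runif(20^2), 20, 20))
  y <- with_seed_test(6, matrix(runif(20^2), 20, 20))
  ax <- mosr:::fx_forward(fx, mosr:::slice_to_input(x))$acts
  ay <- mosr:::fx_forward(fx, mosr:::slice_to_input(y))$acts
  oracle <- 0
  for (l in 1:2) {
    zx <- ax[[l]]; zy <- ay[[l]]
    d <- dim(zx)
    lsum <- 0
    for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
      vx <- zx[1, h, w, ]; vy <- zy[1, h, w, ]
      vx <- vx / sqrt(sum(vx^2) + 1e-10)
      vy <- vy / sqrt(sum(vy^2) + 1e-10)
      wl <- fx$layers[[l]]$w_chan
      lsum <- lsum + sum((wl * (vx - vy))^2)
    }
    oracle <- oracle + lsum / (d[2] * d[3])
  }
  expect_equal(lpips_2d(x, y, fx), oracle, tolerance = 1e-6)
})

test_that("volume loss is deterministic under seed and zero at identity", {
  fx <- tiny_fx()
  cfg <- loss_config(n_slices = 4L, seed = 17L)
  p <- with_seed_test(7, array(runif(20^3), c(20, 20, 20)))
  t <- with_seed_test(8, array(runif(20^3), c(20, 20, 20)))
  expect_identical(lpips_volume(p, p, cfg, fx), 0)
  expect_identical(lpips_volume(p, p, cfg, fx, seed = 999L), 0)
  v1 <- lpips_volume(p, t, cfg, fx)
  expect_identical(v1, lpips_volume(p, t, cfg, fx))
  expect_false(identical(v1, lpips_volume(p, t, cfg, fx, seed = 31L)))
  # S larger than the available band errors
  expect_error(lpips_volume(p, t, loss_config(n_slices = 40L, axes = 3L,
                                              slice_axes_policy = "uniform"),
                            fx), "available")
})

test_that("restricting sampling to one full axis equals the plain slice mean", {
  fx <- tiny_fx()
  n <- 20
  p <- with_seed_test(9, array(runif(n^3), c(n, n, n)))
  t <- with_seed_test(10, array(runif(n^3), c(n, n, n)))
  margin <- floor(n * 0.1)
  band <- (margin + 1):(n - margin)
  cfg <- loss_config(n_slices = length(band), slice_axes_policy = "uniform",
                     axes = 3L, seed = 13L)
  v <- lpips_volume(p, t, cfg, fx)
  oracle <- mean(vapply(band, function(i) lpips_2d(p[, , i], t[, , i], fx),
                        numeric(1)))
  expect_equal(v, oracle, tolerance = 1e-12)
})

test_that("total loss composes its addends and vanishes at identity", {
  fx <- tiny_fx()
  cfg <- loss_config(n_slices = 3L, seed = 5L)
  p <- with_seed_test(11, array(runif(16^3), c(16, 16, 16)))
  t <- with_seed_test(12, array(runif(16^3), c(16, 16, 16)))
  tl <- total_loss(p, t, cfg, fx)
  expect_equal(tl$total, tl$lpips + cfg$lambda_l2 * tl$l2, tolerance = 1e-12)
  expect_identical(total_loss(p, p, cfg, fx)$total, 0)
  # composition arithmetic: lpips 0.2 + lambda 100 * l2 0.001 = 0.3
  expect_equal(0.2 + 100 * 0.001, 0.3)
})

test_that("analytic gradient agrees with central finite differences", {
  fx <- tiny_fx()
  cfg <- loss_config(n_slices = 3L, seed = 21L)
  p <- with_seed_test(13, array(runif(16^3), c(16, 16, 16)))
  t <- with_seed_test(14, array(runif(16^3), c(16, 16, 16)))
  g <- total_loss_grad(p, t, cfg, fx)
  idx <- with_seed_test(15, sample(length(p), 25))
  eps <- 1e-5
  for (i in idx) {
    pp <- pm <- p
    pp[i] <- pp[i] + eps; pm[i] <- pm[i] - eps
    fd <- (total_loss(pp, t, cfg, fx)$total -
           total_loss(pm, t, cfg, fx)$total) / (2 * eps)
    expect_lt(abs(fd - g$dx[i]) / (abs(fd) + 1e-8), 1e-3)
  }
})

test_that("both loss terms grow monotonically with noise amplitude", {
  fx <- tiny_fx()
  cfg <- loss_config(n_slices = 3L, seed = 3L)
  t <- tiny_phantom(seed = 2L, side = 24L)$volume$data
  amps <- c(0.02, 0.08, 0.3)
  res <- sapply(1:20, function(s) {
    vals <- vapply(amps, function(a) {
      p <- t + with_seed_test(1000 + s, array(rnorm(length(t), 0, a), dim(t)))
      tl <- total_loss(p, t, cfg, fx)
      c(tl$lpips, tl$l2)
    }, numeric(2))
    c(all(diff(vals[1, ]) > 0), all(diff(vals[2, ]) > 0))
  })
  # monotone in expectation: require the overwhelming majority of seeds
  expect_gte(mean(res[1, ]), 0.9)
  expect_identical(mean(res[2, ]), 1)
})

test_that("the l2 term is strictly variant under affine intensity rescaling", {
  t <- tiny_phantom(seed = 2L, side = 24L)$volume$data
  p <- 0.8 * t + 0.05
  expect_gt(l2_loss(p, t), 0)
})
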
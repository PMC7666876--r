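# Perfusion models: single-exposure indices, the training-set generator,
# the network, and the temporal utilities.

norm_cube <- function(k2) {
  melsci:::new_contrast_cube(k2, matrix(1000, dim(k2)[1], dim(k2)[2]),
                             c(1, 2, 4, 8, 16, 32, 64), 1,
                             state = "normalized", block = 4L)
}

test_that("single-exposure indices obey their defining identities", {
  set.seed(1)
  k2 <- array(runif(4 * 4 * 7, 0.05, 1), c(4, 4, 7))
  cube <- norm_cube(k2)
  p2 <- perfusion_k2(cube, T = 8)
  pk <- perfusion_k(cube, T = 8)
  expect_equal(unclass(p2), 1 / k2[, , 4], ignore_attr = TRUE)
  expect_equal(unclass(pk), 1 / sqrt(k2[, , 4]) - 1, ignore_attr = TRUE)
  # P_K2 = (P_K + 1)^2 pixelwise
  expect_equal(unclass(p2), (unclass(pk) + 1)^2, ignore_attr = TRUE)
  # K = 1 (static) maps to P_K = 0 and P_K2 = 1
  one <- norm_cube(array(1, c(2, 2, 7)))
  expect_equal(as.numeric(unclass(perfusion_k(one))), rep(0, 4))
  expect_equal(as.numeric(unclass(perfusion_k2(one))), rep(1, 4))
  # K2 = 0.25 -> P_K2 = 4, P_K = 1
  q <- norm_cube(array(0.25, c(2, 2, 7)))
  expect_equal(as.numeric(unclass(perfusion_k2(q))), rep(4, 4))
  expect_equal(as.numeric(unclass(perfusion_k(q))), rep(1, 4))
})

test_that("tiny and invalid contrast is flagged, not exploded", {
  k2 <- array(0.5, c(2, 2, 7))
  k2[1, 1, ] <- 1e-9         # below epsilon -> NA
  k2[2, 2, ] <- NA           # invalid pixel propagates
  cube <- norm_cube(k2)
  p <- perfusion_k2(cube)
  expect_true(is.na(p[1, 1]) && is.na(p[2, 2]))
  expect_false(anyNA(p[1, 2]))
  expect_error(perfusion_k2(cube, T = 3), "not in cube")
})

test_that("perfusion models require a normalized cube", {
  raw <- norm_cube(array(0.5, c(2, 2, 7))); raw$state <- "raw"
  expect_error(perfusion_k2(raw), "normalized")
  expect_error(perfusion_k(raw), "normalized")
  net <- train_perfusion_net(generate_training_set(300, seed = 1),
                             epochs = 2L, seed = 1)
  expect_error(predict_perfusion(net, raw), "normalized")
})

test_that("training sets follow the documented generative model", {
  ts <- generate_training_set(500, seed = 3)
  expect_identical(ts$features,
                   generate_training_set(500, seed = 3)$features)
  expect_false(identical(ts$features,
                         generate_training_set(500, seed = 4)$features))
  # targets are the anchored proxy: 250 PU at rho = 0.5, tau = 10 ms
  expect_equal(ts$targets, 250 / (0.5 / 10) * ts$rho / ts$tau)
  # features are the closed-form contrast of the drawn states
  i <- 17
  expect_equal(unname(ts$features[i, ]),
               theoretical_contrast(ts$tau[i], c(1, 2, 4, 8, 16, 32, 64),
                                    ts$rho[i]))
  # noisy sets stay non-negative and actually differ
  tn <- generate_training_set(500, noise_sd = TRUE, seed = 3)
  expect_true(all(tn$features >= 0))
  expect_false(identical(tn$features, ts$features))
  expect_error(generate_training_set(0), "'n'")
  expect_error(generate_training_set(10, tau_range = c(-1, 5)), "tau_range")
  expect_error(generate_training_set(10, rho_range = c(0, 2)), "rho_range")
  expect_error(generate_training_set(10, noise_sd = 1:3), "per exposure")
  expect_error(generate_training_set(10, noise_sd = TRUE, noise_common = 2),
               "noise_common")
})

test_that("feature-noise profile is positive and decreasing in exposure", {
  fn <- default_feature_noise()
  expect_length(fn, 7L)
  expect_true(all(fn > 0))
  expect_true(all(diff(fn) <= 0))
  # window scaling: default is the single-cube profile over sqrt(31)
  expect_equal(default_feature_noise(1) / sqrt(31), fn)
  expect_error(default_feature_noise(0), "smoothing_frames")
})

test_that("network gradients match finite differences", {
  set.seed(2)
  par <- melsci:::mlp_init(3, c(5, 4), seed = 2)
  X <- matrix(rnorm(18), 6, 3)
  y <- rnorm(6)
  acts <- melsci:::mlp_forward(par, X)
  g <- melsci:::mlp_grad(par, acts, y)
  eps <- 1e-6
  for (l in 1:3) {
    for (idx in c(1, length(par$w[[l]]))) {
      pp <- par; pp$w[[l]][idx] <- pp$w[[l]][idx] + eps
      pm <- par; pm$w[[l]][idx] <- pm$w[[l]][idx] - eps
      fd <- (melsci:::mlp_loss(pp, X, y) - melsci:::mlp_loss(pm, X, y)) /
        (2 * eps)
      expect_equal(g$w[[l]][idx], fd, tolerance = 1e-5)
    }
    pp <- par; pp$b[[l]][1] <- pp$b[[l]][1] + eps
    pm <- par; pm$b[[l]][1] <- pm$b[[l]][1] - eps
    fd <- (melsci:::mlp_loss(pp, X, y) - melsci:::mlp_loss(pm, X, y)) /
      (2 * eps)
    expect_equal(g$b[[l]][1], fd, tolerance = 1e-5)
  }
})

test_that("training is deterministic and rejects degenerate targets", {
  ts <- generate_training_set(400, seed = 5)
  n1 <- train_perfusion_net(ts, epochs = 3L, seed = 9)
  n2 <- train_perfusion_net(ts, epochs = 3L, seed = 9)
  expect_identical(n1$par, n2$par)
  expect_identical(n1$history, n2$history)
  bad <- generate_training_set(50, rho_range = c(0, 0), seed = 1)  # all 0
  expect_error(train_perfusion_net(bad), "degenerate")
  expect_error(train_perfusion_net(list()), "generate_training_set")
})

test_that("prediction is non-negative, NA-propagating and learns the map", {
  ts <- generate_training_set(3000, seed = 6)
  net <- train_perfusion_net(ts, epochs = 120L, seed = 6)
  expect_gt(net$metrics$r2, 0.9)
  feats <- ts$features[1:50, ]
  pred <- predict(net, feats)
  expect_true(all(pred >= 0))
  feats[3, 2] <- NA
  expect_true(is.na(predict(net, feats)[3]))
  expect_error(predict(net, feats[, 1:5]), "feature columns")
  # per-pixel image inference agrees with matrix inference
  k2 <- array(rep(ts$features[7, ], each = 4), c(2, 2, 7))
  cube <- norm_cube(k2)
  m <- predict_perfusion(net, cube)
  expect_equal(as.numeric(unclass(m)), rep(pred[7], 4))
  # exposure mismatch is refused
  cube2 <- cube; cube2$exposures <- c(1, 2, 4, 8, 16, 32, 128)
  expect_error(predict_perfusion(net, cube2), "exposures")
})

test_that("temporal smoothing uses a 31-sample window at the native rate", {
  # floor(2 s * 15.625 cubes/s) = 31 cubes
  series <- lapply(1:40, function(i) matrix(i, 2, 2))
  sm <- temporal_smooth(series)
  # centre sample 20: window 5..35
  expect_equal(sm[[20]][1, 1], mean(5:35))
  # edges shrink the window
  expect_equal(sm[[1]][1, 1], mean(1:16))
  expect_equal(sm[[40]][1, 1], mean(25:40))
  # a window of one cube is the identity
  id <- temporal_smooth(series, window_s = 1 / 16)
  expect_equal(id[[7]], series[[7]])
  expect_error(temporal_smooth(list()), "empty")
  expect_error(temporal_smooth(series, window_s = 0), "window_s")
})

test_that("ROI traces average the requested pixels", {
  maps <- list(matrix(1:4, 2, 2), matrix(5:8, 2, 2))
  expect_equal(roi_trace(maps), c(2.5, 6.5))
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(roi_trace(maps, mask), c(2.5, 6.5))
  mask2 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(roi_trace(maps, mask2), c(1, 5))
  expect_error(roi_trace(maps, matrix(TRUE, 3, 3)), "dimensions")
  expect_error(roi_trace(maps, matrix(FALSE, 2, 2)), "empty")
  expect_error(roi_trace(list()), "empty")
})

test_that("a fully static scene predicts near-zero perfusion", {
  # the oracle features of a static object are all ones
  ts <- generate_training_set(3000, seed = 10)
  net <- train_perfusion_net(ts, epochs = 120L, seed = 10)
  p <- predict(net, matrix(1, 1, 7))
  expect_lt(p, 25)   # < 10% of the 250 PU anchor
})
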
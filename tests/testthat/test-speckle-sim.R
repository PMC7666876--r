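# Dynamic speckle simulator: statistics of the generated frames.

test_that("specs validate their arguments", {
  expect_error(scene_spec(0, 32, tau = 10), "dimensions")
  expect_error(scene_spec(32, 32, tau = 10, n_frames = 60), "power of two")
  expect_error(scene_spec(32, 32, tau = -1), "'tau'")
  expect_error(scene_spec(32, 32, tau = 10, rho = 1.5), "rho")
  expect_error(scene_spec(32, 32, tau = 10, mean_intensity = -5),
               "mean_intensity")
  expect_error(scene_spec(32, 32, tau = 10, n_substeps = 0), "n_substeps")
  expect_error(scene_spec(32, 32, tau = 10, noise = list()), "noise_spec")
  expect_error(noise_spec(n_shot = -1), "n_shot")
})

test_that("simulation is deterministic and seed-sensitive", {
  sp <- scene_spec(16, 16, tau = 10, seed = 123)
  a <- simulate_frame_stack(sp)
  b <- simulate_frame_stack(sp)
  expect_identical(a$frames, b$frames)
  sp2 <- scene_spec(16, 16, tau = 10, seed = 124)
  expect_false(identical(a$frames, simulate_frame_stack(sp2)$frames))
})

test_that("a static noise-free scene has zero temporal variance", {
  st <- simulate_frame_stack(static_target_spec(16, 16, seed = 9))
  d <- dim(st$frames)
  m <- matrix(st$frames, d[1] * d[2], d[3])
  expect_equal(apply(m, 1, var), rep(0, d[1] * d[2]), tolerance = 1e-20)
  # but nonzero spatial variance (frozen speckle)
  expect_gt(var(m[, 1]), 0)
})

test_that("single-speckle intensities are exponentially distributed", {
  # rho = 1, one substep: each frame sample is |E|^2 of a circular complex
  # Gaussian -> exponential with mean = sd = mean_intensity
  sp <- scene_spec(64, 64, tau = 10, mean_intensity = 100, n_substeps = 1L,
                   seed = 5)
  v <- as.numeric(simulate_frame_stack(sp)$frames[, , 1])
  n <- length(v)
  expect_equal(mean(v), 100, tolerance = 4 / sqrt(n))         # se = mu/sqrt(n)
  expect_equal(sd(v) / mean(v), 1, tolerance = 0.05)
  # quartile check of the exponential shape
  expect_equal(unname(quantile(v, 0.5)) / mean(v), log(2), tolerance = 0.05)
  expect_true(all(v >= 0))
})

test_that("field decorrelation follows exp(-2 dt / tau) in intensity", {
  # lag-k intensity autocorrelation of a rho = 1 scene is |g1|^2 =
  # exp(-2 k / tau) (Siegert); substeps = 1 avoids intra-frame blur
  tau <- 10
  sp <- scene_spec(64, 64, tau = tau, mean_intensity = 1, n_substeps = 1L,
                   seed = 21)
  st <- simulate_frame_stack(sp)
  d <- dim(st$frames)
  m <- matrix(st$frames, d[1] * d[2], d[3])
  # center on the known mean (1): subtracting the 64-frame sample mean of
  # a correlated series would bias the autocovariance low at long lags
  mc <- m - 1
  den <- mean(mc^2)
  for (k in c(1, 2, 5, 10)) {
    num <- mean(mc[, 1:(d[3] - k)] * mc[, (1 + k):d[3]])
    expect_lt(abs(num / den - exp(-2 * k / tau)), 0.02)
  }
})

test_that("camera noise variances add as specified at the base exposure", {
  # speckle-free homogeneous illumination: frame variance = n_shot * I +
  # n_dark (pattern off); averaged over 20 stacks
  I0 <- 800; ns <- 5; nd <- 20
  vs <- vapply(1:20, function(i) {
    sp <- static_target_spec(32, 32, mean_intensity = I0,
                             noise = noise_spec(ns, nd, 0, seed = 100 + i),
                             seed = 100 + i)
    sp$rho_map[] <- 0
    sp$mean_intensity_map[] <- I0
    st <- simulate_frame_stack(sp)
    # remove the frozen speckle by differencing consecutive frames:
    # Var[f2 - f1] = 2 * (n_shot I + n_dark)
    mean(apply(st$frames, c(1, 2), function(ts) var(diff(ts)) / 2))
  }, numeric(1))
  expect_equal(mean(vs), ns * I0 + nd, tolerance = 0.02)
})

test_that("the fixed pattern is stack-constant and scales as T^2", {
  nsp <- noise_spec(0, 0, pattern_amplitude = 2, seed = 7)
  sp <- scene_spec(32, 32, tau = 10, mean_intensity = 0, noise = nsp,
                   seed = 7)
  st <- simulate_frame_stack(sp)
  # every frame equals the sensor pattern exactly
  pat <- sensor_pattern(32, 32, nsp)
  for (f in c(1, 17, 64)) expect_equal(st$frames[, , f], pat)
  # summed exposures: block variance at T equals T^2 times that at 1 ms
  pyr <- synthesize_exposures(st)
  v1 <- block_variance(pyr$levels[[1]][, , 1])
  v64 <- block_variance(pyr$levels[[7]][, , 1])
  expect_equal(v64, 64^2 * v1, tolerance = 1e-12)
})

test_that("speckle averaging reduces contrast as beta = 1/M", {
  k2m <- vapply(c(1L, 4L), function(M) {
    vals <- vapply(1:6, function(i) {
      sp <- static_target_spec(64, 64, mean_intensity = 1000,
                               n_speckle_avg = M, seed = 300 + 10 * M + i)
      cb <- compute_contrast_cube(simulate_frame_stack(sp))
      mean(cb$k2[, , 1])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_equal(k2m[1] / k2m[2], 4, tolerance = 0.1)
})

test_that("flow sweep varies tau and records the rho/tau truth", {
  tpl <- scene_spec(16, 16, tau = 1, rho = 0.5, seed = 2)
  fl <- simulate_flow_sweep(c(2, 8, 32), tpl)
  expect_length(fl$stacks, 3L)
  expect_equal(fl$truth, 0.5 / c(2, 8, 32))
  # distinct stacks (different tau and seeds)
  expect_false(identical(fl$stacks[[1]]$frames, fl$stacks[[2]]$frames))
  expect_error(simulate_flow_sweep(numeric(0), tpl), "non-empty")
  expect_error(simulate_flow_sweep(c(1, -2), tpl), "positive")
})

test_that("intensity sweep is speckle-free with the requested levels", {
  sw <- simulate_intensity_sweep(levels = 3, stacks_per_level = 2,
                                 height = 16, width = 16,
                                 noise = noise_spec(), seed = 1)
  expect_s3_class(sw, "melsci_sweep")
  # noise-free sweep: perfectly flat frames, zero variance
  cb <- sw$data[[2]][[1]]
  expect_equal(max(abs(cb$k2)), 0)
  expect_equal(mean(cb$mean_intensity), sw$levels[2])
  expect_error(simulate_intensity_sweep(levels = 2), "at least 3")
})
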
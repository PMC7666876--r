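# Noise-model fitting, contrast correction, and normalization.

# Build sweep statistics directly from the forward model (no sampling
# noise), so the fit must recover the parameters exactly.
synthetic_stats <- function(n_shot, n_dark, e_const,
                            intensity = seq(50, 3000, length.out = 10),
                            Ts = c(1, 2, 4, 8, 16, 32, 64)) {
  vm <- outer(intensity, Ts,
              function(I, T) T * I * n_shot + T * n_dark + T^2 * e_const)
  structure(list(variance = vm, intensity = intensity, exposures = Ts,
                 n_cubes = rep(1L, length(intensity))),
            class = "melsci_sweep_stats")
}

test_that("exact synthetic statistics are recovered exactly", {
  for (p in list(c(5, 20, 4), c(0.5, 2.0, 0.01), c(12, 0.1, 50))) {
    fit <- fit_noise_model(synthetic_stats(p[1], p[2], p[3]))
    expect_equal(unname(coef(fit)), p, tolerance = 1e-8)
    # Nelder-Mead cross-check agrees to at least 4 significant figures
    expect_equal(unname(fit$simplex), unname(coef(fit)), tolerance = 1e-4)
    expect_lt(fit$rss, 1e-10)
  }
  # noiseless sensor: all-zero statistics give all-zero parameters
  fit0 <- fit_noise_model(synthetic_stats(0, 0, 0))
  expect_equal(unname(coef(fit0)), c(0, 0, 0), tolerance = 1e-12)
})

test_that("degenerate designs are rejected with a diagnosis", {
  s1 <- synthetic_stats(5, 20, 4, intensity = rep(1000, 5))
  expect_error(fit_noise_model(s1), "single intensity level")
  s2 <- synthetic_stats(5, 20, 4, Ts = 2)
  expect_error(fit_noise_model(s2), "three exposure times")
  expect_error(fit_noise_model(list()), "sweep_statistics")
})

test_that("predict() evaluates the fitted variance model", {
  fit <- fit_noise_model(synthetic_stats(5, 20, 4))
  expect_equal(predict(fit, intensity = 1000, exposure = 8),
               8 * 1000 * 5 + 8 * 20 + 64 * 4, tolerance = 1e-8)
})

test_that("sweep statistics invert the contrast definition exactly", {
  # raw cubes -> per-level mean variance: reconstructing sigma^2 =
  # K2 T^2 <I>^2 must reproduce the block variances of the frames
  sw <- simulate_intensity_sweep(levels = 3, stacks_per_level = 2,
                                 height = 16, width = 16,
                                 noise = noise_spec(3, 10, 1, seed = 6),
                                 seed = 6, collect = "stacks")
  stats <- sweep_statistics(sw)   # converts stacks to cubes internally
  st <- sw$data[[2]][[1]]
  mv <- mean_variance_per_exposure(synthesize_exposures(st))
  direct <- apply(mv, 3, mean)
  cubes <- lapply(sw$data[[2]], compute_contrast_cube)
  stats2 <- sweep_statistics(list(cubes, cubes, cubes))
  expect_equal(stats2$variance[1, ], stats$variance[2, ])
  # the first cube alone reproduces 'direct'
  cb <- cubes[[1]]
  rec <- vapply(1:7, function(k) {
    mean(cb$k2[, , k] * (cb$exposures[k] * cb$mean_intensity)^2)
  }, numeric(1))
  expect_equal(rec, direct)
})

test_that("sweep statistics demand raw cubes and enough levels", {
  sw <- simulate_intensity_sweep(levels = 3, stacks_per_level = 1,
                                 height = 16, width = 16,
                                 noise = noise_spec(3, 10, 1, seed = 2),
                                 seed = 2, collect = "cubes")
  expect_error(sweep_statistics(sw$data[1:2]), "at least 3")
  bad <- sw$data
  bad[[1]][[1]] <- correct_contrast(bad[[1]][[1]], c(n_shot = 3, n_dark = 10,
                                                     e_const = 1))
  expect_error(sweep_statistics(bad), "raw")
})

test_that("correct_contrast subtracts the noise model in contrast space", {
  sp <- scene_spec(16, 16, tau = 10, mean_intensity = 1000,
                   noise = noise_spec(5, 20, 2, seed = 3), seed = 3)
  cb <- compute_contrast_cube(simulate_frame_stack(sp))
  p <- c(n_shot = 5, n_dark = 20, e_const = 4)
  cc <- correct_contrast(cb, p, clamp = FALSE)
  expect_equal(cc$state, "corrected")
  # algebraic identity per block and exposure
  Ts <- cb$exposures
  for (k in c(1, 4, 7)) {
    expect_equal(cc$k2[, , k],
                 cb$k2[, , k] - 5 / (Ts[k] * cb$mean_intensity) -
                   20 / (Ts[k] * cb$mean_intensity^2) -
                   4 / cb$mean_intensity^2)
  }
  # equivalent variance-space subtraction
  k <- 7
  var_raw <- cb$k2[, , k] * (Ts[k] * cb$mean_intensity)^2
  var_corr <- cc$k2[, , k] * (Ts[k] * cb$mean_intensity)^2
  expect_equal(var_corr,
               var_raw - Ts[k] * cb$mean_intensity * 5 - Ts[k] * 20 -
                 Ts[k]^2 * 4)
  # zero parameters leave the cube unchanged (but advance the state)
  cc0 <- correct_contrast(cb, c(n_shot = 0, n_dark = 0, e_const = 0))
  expect_equal(cc0$k2, cb$k2)
})

test_that("clamping counts negatives; state machine is enforced", {
  # noise-only cube (speckle-free illumination): correction with the true
  # parameters pushes roughly half the blocks negative
  sw <- simulate_intensity_sweep(levels = 3, stacks_per_level = 1,
                                 height = 32, width = 32,
                                 noise = noise_spec(5, 20, 2, seed = 8),
                                 seed = 8, collect = "cubes")
  cb <- sw$data[[2]][[1]]
  p <- c(n_shot = 5, n_dark = 20, e_const = 4)
  cc <- correct_contrast(cb, p)
  expect_gt(cc$n_clamped, 0)
  expect_true(all(cc$k2 >= 0))
  ncc <- correct_contrast(cb, p, clamp = FALSE)
  expect_equal(ncc$n_clamped, 0L)
  expect_lt(min(ncc$k2), 0)
  # raw-only precondition
  expect_error(correct_contrast(cc, p), "raw")
  expect_error(correct_contrast(cb, c(n_shot = 1)), "n_dark")
})

test_that("measure_kmax averages the corrected 1-ms plane", {
  mk_cube <- function(val) {
    k2 <- array(0.5, c(4, 4, 7)); k2[, , 1] <- val
    melsci:::new_contrast_cube(k2, matrix(1000, 4, 4),
                               c(1, 2, 4, 8, 16, 32, 64), 1,
                               state = "corrected", block = 4L)
  }
  sc <- measure_kmax(list(mk_cube(0.9), mk_cube(1.0)))
  expect_equal(sc$k2_max, 0.95)
  expect_warning(measure_kmax(mk_cube(5)), "plausible")
  raw <- mk_cube(0.9); raw$state <- "raw"
  expect_error(measure_kmax(raw), "corrected")
  expect_error(measure_kmax(list()), "empty")
})

test_that("normalization divides by K2max and tracks the state", {
  k2 <- array(runif(4 * 4 * 7, 0, 0.9), c(4, 4, 7))
  cb <- melsci:::new_contrast_cube(k2, matrix(1000, 4, 4),
                                   c(1, 2, 4, 8, 16, 32, 64), 1,
                                   state = "corrected", block = 4L)
  nc <- normalize_contrast(cb, 0.9)
  expect_equal(nc$k2, k2 / 0.9)
  expect_equal(nc$state, "normalized")
  expect_error(normalize_contrast(nc, 0.9), "corrected")
  raw <- cb; raw$state <- "raw"
  expect_error(normalize_contrast(raw, 0.9), "corrected")
  expect_error(normalize_contrast(cb, -1), "positive")
  expect_error(normalize_contrast(cb, c(1, 2)), "positive")
})

test_that("a static target measures K2max near but below 1", {
  sp <- static_target_spec(64, 64, mean_intensity = 1000,
                           noise = noise_spec(5, 20, 2, seed = 14), seed = 14)
  cb <- correct_contrast(compute_contrast_cube(simulate_frame_stack(sp)),
                         c(n_shot = 5, n_dark = 20, e_const = 4))
  sc <- measure_kmax(cb)
  expect_gt(sc$k2_max, 0.9)
  expect_lt(sc$k2_max, 1.0)
})
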
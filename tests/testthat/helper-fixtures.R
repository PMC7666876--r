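# Shared expensive fixtures, built once per test run and cached.
#
# The default sensor used throughout: shot-noise slope 5 counts,
# dark-noise variance 20 counts^2, fixed-pattern sd 2 counts
# (e_const = 4), operating around 1000 counts mean intensity.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache, inherits = FALSE)
}

default_sensor_noise <- function(seed = 4L) {
  noise_spec(n_shot = 5, n_dark = 20, pattern_amplitude = 2, seed = seed)
}

true_noise_params <- c(n_shot = 5, n_dark = 20, e_const = 4)

# Full-scale calibration sweep (24 levels x 150 cubes, the acceptance
# design) and its fitted noise model.
fx_sweep <- function() {
  fixture("sweep", function() {
    simulate_intensity_sweep(noise = default_sensor_noise(), seed = 4,
                             collect = "cubes")
  })
}

fx_noise_fit <- function() {
  fixture("noise_fit", function() fit_noise_model(sweep_statistics(fx_sweep())))
}

# Static-target contrast scale (K2max) measured with the true parameters.
fx_kmax <- function() {
  fixture("kmax", function() {
    cubes <- lapply(1:8, function(i) {
      sp <- static_target_spec(64, 64, mean_intensity = 1000,
                               noise = default_sensor_noise(50L + i),
                               seed = 50L + i)
      correct_contrast(compute_contrast_cube(simulate_frame_stack(sp)),
                       true_noise_params)
    })
    measure_kmax(cubes)
  })
}

# Trained perfusion networks at the scaled-down corpus size (n = 10,000).
fx_net_clean <- function() {
  fixture("net_clean", function() {
    train_perfusion_net(generate_training_set(10000, seed = 11), seed = 11)
  })
}

fx_net_noisy <- function() {
  fixture("net_noisy", function() {
    train_perfusion_net(generate_training_set(10000, noise_sd = TRUE,
                                              seed = 12), seed = 12)
  })
}

# Network trained with the single-cube (unsmoothed) noise profile, for
# deployment on raw per-cube features as in the end-to-end flow sweep.
fx_net_cube <- function() {
  fixture("net_cube", function() {
    sd1 <- default_feature_noise(smoothing_frames = 1)
    train_perfusion_net(generate_training_set(10000, noise_sd = sd1,
                                              seed = 12), seed = 12)
  })
}

# A small noise-free dynamic stack reused by fast unit tests.
fx_small_stack <- function() {
  fixture("small_stack", function() {
    simulate_frame_stack(scene_spec(32, 32, tau = 10, rho = 1,
                                    mean_intensity = 1000,
                                    noise = noise_spec(), seed = 77))
  })
}
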
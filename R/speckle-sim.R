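# Dynamic speckle simulator: scene specification, frame-stack generation,
# calibration sweeps, flow sweeps, and the closed-form contrast oracle.

#' Camera noise specification
#'
#' Describes the stochastic camera model added to simulated frames: shot
#' noise with variance proportional to the signal, intensity-independent
#' dark noise, and a fixed per-pixel pattern that repeats identically in
#' every frame (the generative counterpart of the sensor's constant
#' inhomogeneities, e.g. per-pixel gain and per-column ADC offsets).
#'
#' All variances refer to a single 1-ms base frame, in squared camera
#' counts. Under pairwise frame summation the shot and dark contributions
#' grow linearly with exposure time while the fixed pattern, being
#' identical from frame to frame, grows quadratically.
#'
#' @param n_shot Shot-noise variance per unit intensity per base frame
#'   (counts). Gaussian approximation of photon noise.
#' @param n_dark Dark-noise variance per base frame (counts^2).
#' @param pattern_amplitude Standard deviation of the static per-pixel
#'   additive pattern (counts). Its spatial variance
#'   (`pattern_amplitude^2`) is the fixed-pattern term of the noise model.
#' @param seed Integer seed identifying the simulated sensor; the fixed
#'   pattern is drawn once per sensor from this seed.
#' @return An object of class `melsci_noise_spec`.
#' @seealso [scene_spec()], [fit_noise_model()]
#' @export
noise_spec <- function(n_shot = 0, n_dark = 0, pattern_amplitude = 0,
                       seed = 1L) {
  stopifnot_scalar_number(n_shot, "n_shot", min = 0)
  stopifnot_scalar_number(n_dark, "n_dark", min = 0)
  stopifnot_scalar_number(pattern_amplitude, "pattern_amplitude", min = 0)
  structure(list(n_shot = n_shot, n_dark = n_dark,
                 pattern_amplitude = pattern_amplitude,
                 seed = as.integer(seed)),
            class = "melsci_noise_spec")
}

#' Scene specification for the speckle simulator
#'
#' Ground truth for a simulated acquisition: per-pixel field decorrelation
#' time `tau` (ms; `Inf` marks static pixels), per-pixel dynamic fraction
#' `rho` (fraction of detected light scattered by moving particles), and
#' per-pixel expected 1-ms intensity in camera counts. The effective
#' speckle contrast normalization (the beta factor of speckle imaging) is
#' `1 / n_speckle_avg`: each recorded intensity is the average of
#' `n_speckle_avg` independent speckle realizations, emulating several
#' speckles per pixel.
#'
#' @param height,width Image dimensions in pixels.
#' @param tau Decorrelation time map, ms. Scalar or `height x width`
#'   matrix; entries must be positive, `Inf` allowed for static pixels.
#' @param rho Dynamic fraction map in `[0, 1]`. Scalar or matrix.
#' @param mean_intensity Expected 1-ms intensity map, counts (>= 0).
#' @param n_frames Number of consecutive base-exposure frames (a power of
#'   two; default 64).
#' @param base_exposure Base exposure time in ms (default 1).
#' @param n_speckle_avg Integer M >= 1; intensities are averages of M
#'   independent speckle realizations, giving an effective beta of 1/M.
#' @param n_substeps Sub-frame time steps per base exposure used to emulate
#'   intra-frame integration of the fluctuating intensity. The default (32)
#'   keeps the integration-discretization bias in squared contrast below
#'   about 2e-4 relative for tau >= 5 ms.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; identical specs with identical seeds produce
#'   bit-identical stacks.
#' @return An object of class `melsci_scene_spec`.
#' @export
scene_spec <- function(height, width, tau, rho = 1, mean_intensity = 1000,
                       n_frames = 64L, base_exposure = 1, n_speckle_avg = 1L,
                       n_substeps = 32L, noise = noise_spec(), seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("invalid scene dimensions")
  if (!is_power_of_two(n_frames)) {
    stop("'n_frames' must be a power of two (exposure synthesis halves the ",
         "image count at every level)")
  }
  tau_map <- as_map(tau, height, width, "tau")
  rho_map <- as_map(rho, height, width, "rho")
  int_map <- as_map(mean_intensity, height, width, "mean_intensity")
  if (anyNA(tau_map) || any(tau_map <= 0)) {
    stop("'tau' entries must be > 0 (use Inf for static pixels)")
  }
  if (anyNA(rho_map) || any(rho_map < 0 | rho_map > 1)) {
    stop("'rho' entries must lie in [0, 1]")
  }
  if (anyNA(int_map) || any(!is.finite(int_map)) || any(int_map < 0)) {
    stop("'mean_intensity' entries must be finite and >= 0")
  }
  stopifnot_scalar_number(base_exposure, "base_exposure", min = 1e-9)
  if (!inherits(noise, "melsci_noise_spec")) stop("'noise' must be a noise_spec()")
  n_speckle_avg <- as.integer(n_speckle_avg)
  n_substeps <- as.integer(n_substeps)
  if (n_speckle_avg < 1L) stop("'n_speckle_avg' must be >= 1")
  if (n_substeps < 1L) stop("'n_substeps' must be >= 1")
  structure(list(height = height, width = width, tau_map = tau_map,
                 rho_map = rho_map, mean_intensity_map = int_map,
                 n_frames = as.integer(n_frames),
                 base_exposure = base_exposure,
                 n_speckle_avg = n_speckle_avg, n_substeps = n_substeps,
                 noise = noise, seed = as.integer(seed)),
            class = "melsci_scene_spec")
}

#' Scene specification of a static homogeneous target
#'
#' Convenience wrapper for the calibration target used to measure the
#' maximum squared contrast: a diffusely scattering object with no moving
#' scatterers (`rho = 0`, infinite decorrelation time), illuminated
#' homogeneously by the laser.
#'
#' @inheritParams scene_spec
#' @return An object of class `melsci_scene_spec`.
#' @export
static_target_spec <- function(height, width, mean_intensity = 1000,
                               n_frames = 64L, base_exposure = 1,
                               n_speckle_avg = 1L, noise = noise_spec(),
                               seed = 1L) {
  scene_spec(height, width, tau = Inf, rho = 0,
             mean_intensity = mean_intensity, n_frames = n_frames,
             base_exposure = base_exposure, n_speckle_avg = n_speckle_avg,
             n_substeps = 1L, noise = noise, seed = seed)
}

#' @export
print.melsci_scene_spec <- function(x, ...) {
  cat(sprintf("MELSCI scene: %d x %d px, %d frames @ %g ms\n",
              x$height, x$width, x$n_frames, x$base_exposure))
  cat(sprintf("  tau [ms]: %s   rho: %s   <I> [counts]: %s\n",
              summary_range(x$tau_map), summary_range(x$rho_map),
              summary_range(x$mean_intensity_map)))
  cat(sprintf("  speckle averages M = %d (beta ~ %.3g), %d substeps, seed %d\n",
              x$n_speckle_avg, 1 / x$n_speckle_avg, x$n_substeps, x$seed))
  cat(sprintf("  noise: n_shot = %g, n_dark = %g, pattern sd = %g (sensor seed %d)\n",
              x$noise$n_shot, x$noise$n_dark, x$noise$pattern_amplitude,
              x$noise$seed))
  invisible(x)
}

summary_range <- function(m) {
  r <- range(m)
  if (r[1] == r[2]) sprintf("%g", r[1]) else sprintf("%g..%g", r[1], r[2])
}

#' Fixed sensor pattern
#'
#' The static per-pixel additive pattern of a simulated sensor, drawn once
#' per sensor seed and repeated identically in every frame.
#'
#' @param height,width Sensor dimensions.
#' @param noise A [noise_spec()].
#' @return A `height x width` matrix (all zeros if the amplitude is zero).
#' @export
sensor_pattern <- function(height, width, noise) {
  if (noise$pattern_amplitude == 0) return(matrix(0, height, width))
  p <- cpp_rnorm(height * width, noise$seed, STREAM_PATTERN)
  matrix(noise$pattern_amplitude * p, height, width)
}

#' Simulate a stack of consecutive speckle frames
#'
#' Generates `n_frames` consecutive base-exposure intensity frames of a
#' dynamic speckle pattern with the ground truth held in `spec`. Per pixel
#' the detected optical field is
#' `sqrt(rho) * E_dyn(t) + sqrt(1 - rho) * E_stat`, where `E_dyn` is a
#' stationary complex Gaussian process with field autocorrelation
#' `exp(-t / tau)` (sampled as an AR(1) sequence on a sub-frame grid) and
#' `E_stat` is fixed over the stack. Each frame integrates `|E|^2` over its
#' exposure, averages `n_speckle_avg` independent realizations, and is
#' scaled to the requested mean intensity. Camera noise is then added per
#' the scene's [noise_spec()]: Gaussian dark noise, Gaussian shot noise
#' with variance proportional to the signal (draws independent between
#' consecutive frames), and the stack-constant sensor pattern.
#'
#' @param spec A [scene_spec()].
#' @return A [frame_stack()] whose `metadata$scene` records the ground
#'   truth.
#' @seealso [theoretical_contrast()] for the closed-form expectation of the
#'   squared contrast of such scenes.
#' @export
simulate_frame_stack <- function(spec) {
  if (!inherits(spec, "melsci_scene_spec")) stop("'spec' must be a scene_spec()")
  frames <- cpp_sim_speckle(spec$height, spec$width, spec$n_frames,
                            spec$n_substeps, as.numeric(spec$tau_map),
                            as.numeric(spec$rho_map),
                            as.numeric(spec$mean_intensity_map),
                            spec$n_speckle_avg, spec$base_exposure,
                            spec$seed, STREAM_FIELD)
  ns <- spec$noise
  if (ns$n_shot > 0 || ns$n_dark > 0 || ns$pattern_amplitude > 0) {
    pat <- sensor_pattern(spec$height, spec$width, ns)
    frames <- cpp_add_camera_noise(frames, spec$height * spec$width,
                                   spec$n_frames, ns$n_shot, ns$n_dark,
                                   as.numeric(pat), spec$seed, STREAM_NOISE)
    dim(frames) <- c(spec$height, spec$width, spec$n_frames)
  }
  frame_stack(frames, base_exposure = spec$base_exposure,
              metadata = list(scene = spec))
}

#' Closed-form multi-exposure squared speckle contrast
#'
#' The standard two-component contrast model for exponential field
#' decorrelation: with `x = T / tau`,
#' \deqn{K^2(T) = \beta \left[ \rho^2 \frac{e^{-2x} - 1 + 2x}{2x^2}
#'   + 4\rho(1-\rho)\frac{e^{-x} - 1 + x}{x^2} + (1-\rho)^2 \right],}
#' the expectation of the squared spatial speckle contrast of an image
#' integrated over exposure time `T` when a fraction `rho` of the detected
#' field decorrelates as `exp(-t/tau)` and the remainder is static. The
#' `x -> 0` limit (no decorrelation within the exposure) is `beta`,
#' evaluated analytically by series expansion for small `x`.
#'
#' This is the validation oracle for [simulate_frame_stack()] plus the
#' contrast engine, and the forward model behind the neural-network
#' training set.
#'
#' @param tau Decorrelation time, ms (> 0; `Inf` allowed).
#' @param T Exposure time, ms (> 0). Vectorized with the usual recycling.
#' @param rho Dynamic fraction in `[0, 1]`.
#' @param beta Contrast normalization factor (> 0), e.g. `1/M` for `M`
#'   averaged speckles per pixel.
#' @return Squared contrast values (dimensionless).
#' @export
theoretical_contrast <- function(tau, T, rho = 1, beta = 1) {
  n <- max(length(tau), length(T), length(rho), length(beta))
  tau <- rep_len(as.numeric(tau), n); T <- rep_len(as.numeric(T), n)
  rho <- rep_len(as.numeric(rho), n); beta <- rep_len(as.numeric(beta), n)
  if (any(is.na(tau)) || any(tau <= 0)) stop("'tau' must be > 0")
  if (any(is.na(T)) || any(T <= 0) || any(!is.finite(T))) stop("'T' must be finite and > 0")
  if (any(is.na(rho)) || any(rho < 0 | rho > 1)) stop("'rho' must be in [0, 1]")
  if (any(is.na(beta)) || any(beta <= 0)) stop("'beta' must be > 0")
  x <- ifelse(is.finite(tau), T / tau, 0)
  # the heterodyne term of the documented formula is
  # 4 rho (1 - rho) (e^-x - 1 + x) / x^2 = 2 rho (1 - rho) g(x)
  beta * (rho^2 * blur_term(2 * x) + 2 * rho * (1 - rho) * blur_term(x) +
            (1 - rho)^2)
}

# g(y) = 2 * (exp(-y) - 1 + y) / y^2, the triangular-window blur integral;
# g(0) = 1. Series used for small y to avoid catastrophic cancellation.
blur_term <- function(y) {
  out <- numeric(length(y))
  small <- y < 1e-3
  ys <- y[small]
  out[small] <- 1 - ys / 3 + ys^2 / 12 - ys^3 / 60 + ys^4 / 360
  yl <- y[!small]
  out[!small] <- 2 * (exp(-yl) - 1 + yl) / yl^2
  out
}

# Exact expectation of the simulator's squared contrast (rho = 1, beta = 1)
# when each base frame is the mean of `substeps` midpoint samples of the
# AR(1) field and exposure T sums T/base consecutive frames: the discrete
# counterpart of theoretical_contrast, used to quantify integration-
# discretization bias. Converges to the continuous form as substeps grows.
contrast_discrete <- function(tau, T, substeps, base_exposure = 1) {
  n <- round(T / base_exposure) * substeps
  b <- exp(-2 * base_exposure / (substeps * tau))
  (n * (1 + b) / (1 - b) - 2 * b * (1 - b^n) / (1 - b)^2) / n^2
}

#' Simulate an intensity-sweep calibration measurement
#'
#' Emulates the integrating-sphere noise characterization: the sensor views
#' spatially homogeneous, incoherent (speckle-free) illumination at a
#' series of intensity levels, so that all measured variance is camera
#' noise. Default 24 levels spanning 1--80 percent of the sensor range and
#' 150 stacks per level.
#'
#' @param levels Number of intensity levels (>= 3; three noise parameters
#'   must be identifiable).
#' @param max_intensity Sensor full range in counts (default 4095, a 12-bit
#'   sensor).
#' @param intensity_range Fraction of `max_intensity` spanned by the sweep.
#'   The default starts at 1% of range: the intensity-independent dark and
#'   fixed-pattern terms are identified by extrapolating the
#'   variance-vs-intensity relation to darkness, so the sweep must anchor
#'   the low-intensity end or their estimates inflate with shot noise.
#' @param noise A [noise_spec()] describing the sensor under test.
#' @param stacks_per_level Repeated stacks recorded per level.
#' @param height,width,n_frames,base_exposure Acquisition geometry.
#' @param seed Integer seed.
#' @param collect `"cubes"` (default) converts every stack to a raw
#'   contrast cube immediately, which keeps memory modest; `"stacks"`
#'   returns the raw frame stacks.
#' @return An object of class `melsci_sweep`: a list with `levels` (nominal
#'   intensities) and per-level lists of cubes or stacks.
#' @seealso [sweep_statistics()], [fit_noise_model()]
#' @export
simulate_intensity_sweep <- function(levels = 24L, max_intensity = 4095,
                                     intensity_range = c(0.01, 0.80),
                                     noise = noise_spec(),
                                     stacks_per_level = 150L,
                                     height = 32L, width = 32L,
                                     n_frames = 64L, base_exposure = 1,
                                     seed = 1L,
                                     collect = c("cubes", "stacks")) {
  collect <- match.arg(collect)
  levels <- as.integer(levels)
  if (levels < 3L) {
    stop("at least 3 intensity levels are required to identify the three ",
         "noise parameters")
  }
  if (!is_power_of_two(n_frames)) stop("'n_frames' must be a power of two")
  intens <- seq(intensity_range[1], intensity_range[2],
                length.out = levels) * max_intensity
  npix <- as.integer(height) * as.integer(width)
  pat <- sensor_pattern(height, width, noise)
  out <- vector("list", levels)
  for (l in seq_len(levels)) {
    reps <- vector("list", stacks_per_level)
    for (r in seq_len(stacks_per_level)) {
      frames <- array(intens[l], dim = c(height, width, n_frames))
      if (noise$n_shot > 0 || noise$n_dark > 0 ||
          noise$pattern_amplitude > 0) {
        frames <- cpp_add_camera_noise(frames, npix, n_frames, noise$n_shot,
                                       noise$n_dark, as.numeric(pat), seed,
                                       rng_stream(STREAM_NOISE, r, l))
        dim(frames) <- c(height, width, n_frames)
      }
      st <- frame_stack(frames, base_exposure = base_exposure)
      reps[[r]] <- if (collect == "cubes") compute_contrast_cube(st) else st
    }
    out[[l]] <- reps
  }
  structure(list(levels = intens, data = out, collect = collect,
                 noise = noise, seed = as.integer(seed)),
            class = "melsci_sweep")
}

#' @export
print.melsci_sweep <- function(x, ...) {
  cat(sprintf("MELSCI intensity sweep: %d levels (%g..%g counts), %d %s per level\n",
              length(x$levels), min(x$levels), max(x$levels),
              length(x$data[[1]]), x$collect))
  invisible(x)
}

#' Simulate a flow sweep
#'
#' A controlled series of fully specified flow states, one stack per
#' decorrelation time, standing in for a Brownian-motion phantom whose
#' scatterer speed is varied. The recorded ground-truth perfusion proxy per
#' stack is `rho / tau` (concentration surrogate times speed surrogate).
#'
#' @param tau_values Positive decorrelation times, ms.
#' @param spec_template A [scene_spec()]; each stack reuses its geometry,
#'   `rho`, intensity, noise and speckle averaging, with `tau` replaced and
#'   the stack seed varied deterministically from the template seed.
#' @return An object of class `melsci_flow_sweep`: list with `stacks`,
#'   `tau`, and `truth` (the per-stack proxies).
#' @export
simulate_flow_sweep <- function(tau_values, spec_template) {
  if (length(tau_values) == 0) stop("'tau_values' must be non-empty")
  if (any(!is.finite(tau_values)) || any(tau_values <= 0)) {
    stop("'tau_values' must be positive and finite")
  }
  if (!inherits(spec_template, "melsci_scene_spec")) {
    stop("'spec_template' must be a scene_spec()")
  }
  stacks <- vector("list", length(tau_values))
  truth <- numeric(length(tau_values))
  for (i in seq_along(tau_values)) {
    sp <- spec_template
    sp$tau_map[] <- tau_values[i]
    sp$seed <- spec_template$seed + 977L * i
    stacks[[i]] <- simulate_frame_stack(sp)
    truth[i] <- mean(sp$rho_map) / tau_values[i]
  }
  structure(list(stacks = stacks, tau = as.numeric(tau_values),
                 truth = truth, template = spec_template),
            class = "melsci_flow_sweep")
}
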
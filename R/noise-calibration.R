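# Joint camera-noise model across exposure times, contrast correction, and
# normalization by the maximum contrast of a static target.
#
# In variance space the measured variance at exposure T (in units of the
# base exposure) is
#   sigma2_meas(T) = sigma2_speckle(T) + T * <I> * n_shot + T * n_dark
#                    + T^2 * e_const
# Shot and dark noise are independent between consecutive frames, so their
# contributions add linearly in T; the fixed pattern repeats identically in
# every frame, so its contribution grows as T^2. On speckle-free,
# homogeneous (incoherent) illumination sigma2_speckle = 0 and the three
# constants can be fitted jointly over all exposure times.

#' Spatiotemporal sweep statistics
#'
#' Reduce an intensity-sweep measurement to the global spatiotemporal
#' average of the variance for each exposure time and level, plus the
#' average intensity per level. Variances are recovered from raw contrast
#' cubes by inverting the contrast definition:
#' `sigma2(T) = K2(T) * (T <I>)^2` per pixel.
#'
#' @param sweep A [simulate_intensity_sweep()] result with cubes, or a list
#'   of lists of raw `melsci_cube`s grouped by intensity level.
#' @return An object of class `melsci_sweep_stats`: list with `variance`
#'   (levels x exposures matrix), `intensity` (length-levels vector),
#'   `exposures` (in units of the base exposure) and `n_cubes`.
#' @export
sweep_statistics <- function(sweep) {
  groups <- if (inherits(sweep, "melsci_sweep")) {
    if (sweep$collect != "cubes") {
      lapply(sweep$data, function(g) lapply(g, compute_contrast_cube))
    } else sweep$data
  } else sweep
  if (!is.list(groups) || length(groups) < 3L) {
    stop("at least 3 intensity levels are required")
  }
  first <- groups[[1]][[1]]
  if (!inherits(first, "melsci_cube")) stop("expected contrast cubes per level")
  Ts <- first$exposures / first$base_exposure
  nT <- length(Ts)
  nl <- length(groups)
  vmat <- matrix(NA_real_, nl, nT)
  ibar <- numeric(nl)
  for (l in seq_len(nl)) {
    cubes <- groups[[l]]
    states <- vapply(cubes, function(cb) cb$state, character(1))
    if (!all(states == "raw")) {
      stop("sweep statistics require cubes in 'raw' state (found: ",
           paste(unique(states), collapse = ", "), ")")
    }
    vs <- matrix(0, length(cubes), nT)
    is <- numeric(length(cubes))
    for (i in seq_along(cubes)) {
      cb <- cubes[[i]]
      mi2 <- cb$mean_intensity^2
      for (k in seq_len(nT)) {
        vs[i, k] <- mean(cb$k2[, , k] * Ts[k]^2 * mi2, na.rm = TRUE)
      }
      is[i] <- mean(cb$mean_intensity)
    }
    vmat[l, ] <- colMeans(vs)
    ibar[l] <- mean(is)
  }
  structure(list(variance = vmat, intensity = ibar, exposures = Ts,
                 n_cubes = vapply(groups, length, integer(1))),
            class = "melsci_sweep_stats")
}

#' @export
print.melsci_sweep_stats <- function(x, ...) {
  cat(sprintf("MELSCI sweep statistics: %d levels x %d exposures\n",
              nrow(x$variance), ncol(x$variance)))
  cat(sprintf("  <I> range: %.1f..%.1f counts\n",
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Fit the joint camera-noise model
#'
#' Fits `sigma2(T, I) = T I n_shot + T n_dark + T^2 e_const` to the sweep
#' statistics of speckle-free illumination, jointly over all exposure times
#' and intensity levels. The model is linear in the parameters and is
#' solved by weighted linear least squares: the sampling variance of an
#' averaged variance estimate scales with the squared true variance
#' (`Var[s^2] = 2 sigma^4 / n` for Gaussian data), so cells are weighted
#' by `1 / sigma^4` with `sigma^2` taken from the previous pass
#' (iteratively reweighted, ordinary least squares as the first pass).
#' Without the weights the near-collinearity of the `T` and `T I` columns
#' lets the high-intensity cells' large sampling noise leak into `n_dark`.
#' A derivative-free Nelder--Mead minimization of the same weighted
#' objective is run as a cross-check and stored alongside (the two agree
#' to numerical precision on well-conditioned sweeps).
#'
#' @param stats A [sweep_statistics()] result.
#' @return An object of class `melsci_noise_fit` with components
#'   `coefficients` (`n_shot`, `n_dark`, `e_const`), `simplex`
#'   (Nelder--Mead solution), `fitted`, `residuals`, and diagnostics.
#'   Negative fitted parameters trigger a warning (all three are physical
#'   variances) but are not constrained.
#' @export
fit_noise_model <- function(stats) {
  if (!inherits(stats, "melsci_sweep_stats")) {
    stop("'stats' must come from sweep_statistics()")
  }
  Ts <- stats$exposures
  I <- stats$intensity
  y <- as.numeric(stats$variance)           # levels x exposures, column-major
  Tcol <- rep(Ts, each = length(I))
  Icol <- rep(I, times = length(Ts))
  X <- cbind(n_shot = Tcol * Icol, n_dark = Tcol, e_const = Tcol^2)
  qx <- qr(X)
  if (qx$rank < 3L) {
    culprit <- if (length(unique(I)) < 2L) {
      "n_shot and n_dark are not separable from a single intensity level"
    } else if (length(unique(Ts)) < 3L) {
      "n_dark and e_const require at least three exposure times"
    } else "the design matrix is rank deficient"
    stop("noise model unidentifiable: ", culprit)
  }
  beta <- qr.coef(qx, y)
  # iteratively reweighted least squares, weights 1 / sigma^4
  w <- rep(1, length(y))
  if (max(abs(y)) > 0) {
    for (pass in 1:3) {
      pred <- pmax(as.numeric(X %*% beta), max(abs(y)) * 1e-9)
      w <- 1 / pred^2
      beta <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    }
  }
  fitted <- as.numeric(X %*% beta)
  res <- y - fitted

  # independent crude start for the simplex cross-check: per-exposure
  # regressions of variance on intensity
  sl <- stats::coef(lm(stats$variance[, 1] ~ I))
  init <- c(max(sl[2], 1e-8) / Ts[1], max(sl[1], 1e-8) / (2 * Ts[1]),
            max(sl[1], 1e-8) / (2 * Ts[1]^2))
  rss <- function(p) sum(w * (y - X %*% p)^2)
  nm <- optim(init, rss, method = "Nelder-Mead",
              control = list(maxit = 50000, reltol = 1e-15,
                             parscale = pmax(abs(init), 1e-10)))
  simplex <- nm$par
  names(simplex) <- colnames(X)
  if (any(beta < 0)) {
    warning("negative fitted noise parameter(s): ",
            paste(names(beta)[beta < 0], collapse = ", "),
            " (all three are physical variances)")
  }
  structure(list(coefficients = beta, simplex = simplex,
                 fitted = matrix(fitted, length(I), length(Ts)),
                 residuals = matrix(res, length(I), length(Ts)),
                 weights = matrix(w, length(I), length(Ts)),
                 rss = sum(w * res^2), simplex_rss = nm$value,
                 levels_used = length(I), exposures = Ts, intensity = I),
            class = "melsci_noise_fit")
}

#' @export
coef.melsci_noise_fit <- function(object, ...) object$coefficients

#' @export
print.melsci_noise_fit <- function(x, ...) {
  cat("MELSCI camera-noise model fit\n")
  cat(sprintf("  n_shot  = %.6g  (shot-noise variance per count per frame)\n",
              x$coefficients[["n_shot"]]))
  cat(sprintf("  n_dark  = %.6g  (dark-noise variance per frame)\n",
              x$coefficients[["n_dark"]]))
  cat(sprintf("  e_const = %.6g  (fixed-pattern variance, T^2 scaling)\n",
              x$coefficients[["e_const"]]))
  cat(sprintf("  %d levels, residual RMS %.4g; simplex agreement %.3g (rel.)\n",
              x$levels_used, sqrt(x$rss / length(x$residuals)),
              max(abs(x$simplex - x$coefficients) /
                    pmax(abs(x$coefficients), 1e-12))))
  invisible(x)
}

#' @export
summary.melsci_noise_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Model variance predicted by a noise fit
#'
#' @param object A `melsci_noise_fit`.
#' @param intensity Mean base-frame intensity (counts).
#' @param exposure Exposure time in units of the base exposure.
#' @param ... Unused.
#' @return Predicted noise variance (counts^2).
#' @export
predict.melsci_noise_fit <- function(object, intensity, exposure, ...) {
  b <- object$coefficients
  exposure * intensity * b[["n_shot"]] + exposure * b[["n_dark"]] +
    exposure^2 * b[["e_const"]]
}

#' Noise-correct a contrast cube
#'
#' Subtracts the fitted camera-noise contribution from each plane of a raw
#' contrast cube, working in contrast space:
#' `K2_corr(T) = K2(T) - n_shot / (T <I>) - n_dark / (T <I>^2)
#'  - e_const / <I>^2` (T in units of the base exposure). Slightly negative
#' corrected values, which arise from sampling noise, are clamped at zero
#' and counted in the result's `n_clamped` field.
#'
#' @param cube A raw `melsci_cube`.
#' @param fit A [fit_noise_model()] result, or a named vector with
#'   `n_shot`, `n_dark`, `e_const`.
#' @param clamp Clamp slightly negative corrected values at zero
#'   (default). Set to `FALSE` for diagnostics that need the signed
#'   residuals, e.g. checking that noise-only cubes correct to zero *on
#'   average*.
#' @return The corrected cube (state `"corrected"`).
#' @export
correct_contrast <- function(cube, fit, clamp = TRUE) {
  if (!inherits(cube, "melsci_cube")) stop("'cube' must be a melsci_cube")
  if (cube$state != "raw") {
    stop("noise correction must be applied to a raw cube (state is '",
         cube$state, "')")
  }
  p <- if (inherits(fit, "melsci_noise_fit")) coef(fit) else fit
  if (!all(c("n_shot", "n_dark", "e_const") %in% names(p))) {
    stop("'fit' must provide n_shot, n_dark and e_const")
  }
  Ts <- cube$exposures / cube$base_exposure
  mi <- cube$mean_intensity
  k2 <- cube$k2
  n_clamped <- 0L
  for (k in seq_along(Ts)) {
    corr <- p[["n_shot"]] / (Ts[k] * mi) + p[["n_dark"]] / (Ts[k] * mi^2) +
      p[["e_const"]] / mi^2
    plane <- k2[, , k] - corr
    if (clamp) {
      neg <- !is.na(plane) & plane < 0
      n_clamped <- n_clamped + sum(neg)
      plane[neg] <- 0
    }
    k2[, , k] <- plane
  }
  out <- cube
  out$k2 <- k2
  out$state <- "corrected"
  out$n_clamped <- n_clamped
  out$calibration <- p
  out
}

#' Measure the maximum squared contrast of a static target
#'
#' The spatiotemporal mean of the base-exposure (1-ms) squared-contrast
#' plane over a collection of noise-corrected cubes of a static
#' homogeneous object. This single value approximates the beta factor
#' (speckles per pixel and polarization) and is used to scale all exposure
#' times, deliberately avoiding per-exposure empirical corrections.
#'
#' @param static_cubes A list of corrected `melsci_cube`s (or one cube).
#' @return An object of class `melsci_contrast_scale` with field `k2_max`.
#' @export
measure_kmax <- function(static_cubes) {
  if (inherits(static_cubes, "melsci_cube")) static_cubes <- list(static_cubes)
  if (length(static_cubes) == 0L) stop("empty collection of static cubes")
  vals <- vapply(static_cubes, function(cb) {
    if (!inherits(cb, "melsci_cube")) stop("expected melsci_cube objects")
    if (cb$state != "corrected") {
      stop("K2max is measured on noise-corrected cubes (state is '",
           cb$state, "')")
    }
    mean(cb$k2[, , 1], na.rm = TRUE)
  }, numeric(1))
  k2_max <- mean(vals)
  if (!is.finite(k2_max) || k2_max <= 0 || k2_max > 1.1) {
    warning(sprintf("K2max(1 ms) = %.4g outside the plausible (0, 1.1] range",
                    k2_max))
  }
  structure(list(k2_max = k2_max, n_cubes = length(static_cubes)),
            class = "melsci_contrast_scale")
}

#' @export
print.melsci_contrast_scale <- function(x, ...) {
  cat(sprintf("MELSCI contrast scale: K2max(1 ms) = %.4f (from %d cubes)\n",
              x$k2_max, x$n_cubes))
  invisible(x)
}

#' Normalize a corrected contrast cube
#'
#' Scales all squared-contrast planes by the measured maximum contrast,
#' `K2(T) = K2_corr(T) / K2max(1 ms)`, mapping contrast to the nominal
#' range 0..1 (values slightly above 1 from sampling noise are not
#' clamped).
#'
#' @param cube A corrected `melsci_cube`.
#' @param scale A [measure_kmax()] result, or a single positive number.
#' @return The normalized cube (state `"normalized"`).
#' @export
normalize_contrast <- function(cube, scale) {
  if (!inherits(cube, "melsci_cube")) stop("'cube' must be a melsci_cube")
  if (cube$state != "corrected") {
    stop("normalization requires a noise-corrected cube (state is '",
         cube$state, "'); apply correct_contrast() first")
  }
  k2max <- if (inherits(scale, "melsci_contrast_scale")) scale$k2_max else scale
  if (!is.numeric(k2max) || length(k2max) != 1L || !is.finite(k2max) ||
      k2max <= 0) {
    stop("'scale' must give a positive K2max")
  }
  out <- cube
  out$k2 <- cube$k2 / k2max
  out$state <- "normalized"
  out$k2_max <- k2max
  out
}

#' One-shot sensor calibration from simulated measurements
#'
#' Convenience wrapper performing the full calibration of a simulated
#' sensor: run an intensity sweep and fit the noise model, then record a
#' static homogeneous target, noise-correct its cubes and measure the
#' maximum contrast. Calibration is performed once per sensor and reused
#' across measurements.
#'
#' @param noise The sensor's [noise_spec()].
#' @param sweep_levels,stacks_per_level Sweep design.
#' @param static_stacks Number of static-target stacks for K2max.
#' @param height,width Geometry of the calibration acquisitions.
#' @param n_speckle_avg Speckle averaging of the static-target measurement
#'   (must match the instrument's optical configuration).
#' @param static_intensity Mean intensity of the static target, counts.
#' @param seed Integer seed.
#' @return A list with `fit` (class `melsci_noise_fit`) and `scale` (class
#'   `melsci_contrast_scale`).
#' @export
calibrate_sensor <- function(noise, sweep_levels = 24L,
                             stacks_per_level = 150L, static_stacks = 20L,
                             height = 32L, width = 32L, n_speckle_avg = 1L,
                             static_intensity = 1000, seed = 1L) {
  sweep <- simulate_intensity_sweep(levels = sweep_levels, noise = noise,
                                    stacks_per_level = stacks_per_level,
                                    height = height, width = width,
                                    seed = seed, collect = "cubes")
  fit <- fit_noise_model(sweep_statistics(sweep))
  static_cubes <- lapply(seq_len(static_stacks), function(i) {
    sp <- static_target_spec(height, width, mean_intensity = static_intensity,
                             n_speckle_avg = n_speckle_avg, noise = noise,
                             seed = seed + 7919L * i)
    correct_contrast(compute_contrast_cube(simulate_frame_stack(sp)), fit)
  })
  list(fit = fit, scale = measure_kmax(static_cubes))
}
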
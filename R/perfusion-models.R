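# Perfusion estimation from normalized multi-exposure contrast: two
# single-exposure models (reciprocal squared contrast, and the
# reciprocal-contrast-minus-one model used by commercial single-exposure
# imagers) and a neural-network estimator using all seven exposures.

K2_EPSILON <- 1e-6

new_perfusion_map <- function(values, model, exposure = NA_real_,
                              index = NA_integer_) {
  structure(values, class = c("melsci_perfusion_map", "matrix", "array"),
            model = model, exposure = exposure, index = index)
}

#' @export
print.melsci_perfusion_map <- function(x, ...) {
  d <- dim(x)
  expo <- attr(x, "exposure")
  cat(sprintf("MELSCI perfusion map [%s%s]: %d x %d px, mean %.2f (%d invalid)\n",
              attr(x, "model"),
              if (is.finite(expo)) sprintf(", T = %g ms", expo) else "",
              d[1], d[2], mean(x, na.rm = TRUE), sum(is.na(x))))
  invisible(x)
}

#' Display a perfusion map
#'
#' @param x A `melsci_perfusion_map`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.melsci_perfusion_map <- function(x, ...) {
  m <- unclass(x)
  graphics::image(t(m[rev(seq_len(nrow(m))), ]), axes = FALSE,
                  main = sprintf("perfusion [%s]", attr(x, "model")), ...)
  invisible(x)
}

check_normalized <- function(cube) {
  if (!inherits(cube, "melsci_cube")) stop("'cube' must be a melsci_cube")
  if (cube$state != "normalized") {
    stop("perfusion models require a normalized cube (state is '",
         cube$state, "'); run correct_contrast() and normalize_contrast()")
  }
  invisible(cube)
}

get_plane <- function(cube, T) {
  idx <- match(T, cube$exposures)
  if (is.na(idx)) {
    stop("exposure ", T, " ms not in cube (available: ",
         paste(cube$exposures, collapse = ", "), ")")
  }
  cube$k2[, , idx]
}

#' Single-exposure perfusion: reciprocal squared contrast
#'
#' `P_K2(T) = 1 / K2(T)`, the simplified speckle flow index used by
#' single-exposure imagers. The calibration factor that commercial devices
#' apply is omitted (it only rescales the values). Squared contrast below
#' a small epsilon (1e-6) is flagged invalid rather than mapped to a huge
#' value.
#'
#' @param cube A normalized `melsci_cube`.
#' @param T Exposure time in ms (one of the cube's exposures).
#' @return A `melsci_perfusion_map`.
#' @export
perfusion_k2 <- function(cube, T = 8) {
  check_normalized(cube)
  k2 <- get_plane(cube, T)
  bad <- !is.na(k2) & k2 < K2_EPSILON
  out <- 1 / k2
  out[bad] <- NA_real_
  new_perfusion_map(out, "K2", exposure = T)
}

#' Single-exposure perfusion: reciprocal contrast minus one
#'
#' `P_K(T) = 1 / K(T) - 1` with `K = sqrt(K2)`; zero on a fully static
#' object (`K = 1`), as expected when no moving scatterers are present.
#'
#' @inheritParams perfusion_k2
#' @return A `melsci_perfusion_map`.
#' @export
perfusion_k <- function(cube, T = 8) {
  check_normalized(cube)
  k2 <- get_plane(cube, T)
  bad <- !is.na(k2) & k2 < K2_EPSILON
  k <- sqrt(pmax(k2, 0))
  out <- 1 / k - 1
  out[bad] <- NA_real_
  new_perfusion_map(out, "K", exposure = T)
}

#' Default feature-noise profile for training augmentation
#'
#' Standard deviation of normalized squared contrast per exposure time,
#' emulating the measurement noise of a block feature. The base values
#' were calibrated once against the simulator at the package's default
#' sensor settings (shot variance slope 5 counts, dark variance 20
#' counts^2, fixed-pattern sd 2 counts, mean intensity ~1000 counts):
#' the observed per-block standard deviation of single-cube normalized
#' K2(T), averaged over a 3 x 3 grid of scenes (tau in 2, 10, 50 ms; rho
#' in 0.3, 0.6, 0.9; 10 stacks each). It is dominated by speckle
#' sampling statistics of the 16-pixel blocks, not by camera noise.
#'
#' `smoothing_frames` divides the profile by `sqrt(smoothing_frames)`
#' for features averaged over a moving window before estimation. The
#' default, 31, matches the 2-s window of [temporal_smooth()] and is the
#' profile to train a trace estimator with; use `smoothing_frames = 1`
#' for a network deployed on raw per-cube features (as
#' [evaluate_flow_sweep()] does), which must tolerate the full
#' single-cube scatter.
#'
#' @param smoothing_frames Number of cubes averaged before the features
#'   reach the estimator (positive integer).
#' @return Named numeric vector of length 7 (exposures 1..64 ms).
#' @export
default_feature_noise <- function(smoothing_frames = 31L) {
  if (!is.numeric(smoothing_frames) || length(smoothing_frames) != 1L ||
      !is.finite(smoothing_frames) || smoothing_frames < 1) {
    stop("'smoothing_frames' must be a positive number")
  }
  base <- c(`1` = 0.2199, `2` = 0.2194, `4` = 0.2183, `8` = 0.2160,
            `16` = 0.2121, `32` = 0.2066, `64` = 0.1982)
  base / sqrt(smoothing_frames)
}

#' Generate a training set from the contrast forward model
#'
#' Draws flow states (decorrelation time `tau` log-uniform, dynamic
#' fraction `rho` uniform), computes the seven normalized squared-contrast
#' features with [theoretical_contrast()] (beta = 1 after normalization),
#' and records the perfusion proxy `rho / tau` as target, rescaled so a
#' mid-range reference state (`tau` 10 ms, `rho` 0.5) maps to 250
#' perfusion units. Optional Gaussian feature noise, with a standard
#' deviation profile decreasing in exposure time, emulates residual
#' measurement noise; noisy features are clamped at zero like corrected
#' contrast. The noise follows the one-factor structure measured on the
#' simulator: a single draw shared by all exposures (the frozen speckle
#' realization moves the whole contrast curve together) carries
#' `noise_common` of the variance, the rest is independent per exposure.
#'
#' @param n Number of samples.
#' @param tau_range Decorrelation-time range, ms (log-uniform).
#' @param rho_range Dynamic-fraction range (uniform).
#' @param noise_sd `NULL` for noise-free features, `TRUE` for
#'   [default_feature_noise()], or a numeric vector of 7 standard
#'   deviations.
#' @param noise_common Fraction of the noise variance carried by the
#'   common cross-exposure factor, in `[0, 1]`. The default 0.977 was
#'   calibrated together with [default_feature_noise()] (first principal
#'   component of the cross-exposure residual covariance).
#' @param seed Integer seed; regeneration is bit-identical.
#' @param anchor Perfusion units assigned to the reference state.
#' @param exposures Exposure times, ms.
#' @return An object of class `melsci_training_set` with `features`
#'   (n x 7), `targets`, and the generation settings.
#' @export
generate_training_set <- function(n, tau_range = c(0.05, 500),
                                  rho_range = c(0, 1), noise_sd = NULL,
                                  noise_common = 0.977,
                                  seed = 1L, anchor = 250,
                                  exposures = c(1, 2, 4, 8, 16, 32, 64)) {
  if (noise_common < 0 || noise_common > 1) {
    stop("'noise_common' must be in [0, 1]")
  }
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  if (tau_range[1] <= 0 || tau_range[2] < tau_range[1]) {
    stop("invalid 'tau_range'")
  }
  if (rho_range[1] < 0 || rho_range[2] > 1 || rho_range[2] < rho_range[1]) {
    stop("invalid 'rho_range'")
  }
  if (isTRUE(noise_sd)) noise_sd <- default_feature_noise()
  if (!is.null(noise_sd) && length(noise_sd) != length(exposures)) {
    stop("'noise_sd' must have one value per exposure")
  }
  scale <- anchor / (0.5 / 10)   # reference state rho = 0.5, tau = 10 ms
  with_seed(seed, {
    tau <- exp(runif(n, log(tau_range[1]), log(tau_range[2])))
    rho <- runif(n, rho_range[1], rho_range[2])
    feats <- sapply(exposures, function(T) theoretical_contrast(tau, T, rho))
    feats <- matrix(feats, n, length(exposures))
    if (!is.null(noise_sd)) {
      z_common <- rnorm(n)
      z_indep <- matrix(rnorm(n * length(exposures)), n)
      noise <- sqrt(noise_common) * z_common %o% rep(1, length(exposures)) +
        sqrt(1 - noise_common) * z_indep
      noise <- sweep(noise, 2L, as.numeric(noise_sd), `*`)
      feats <- pmax(feats + noise, 0)
    }
    colnames(feats) <- paste0("K2_", exposures)
    structure(list(features = feats, targets = scale * rho / tau,
                   tau = tau, rho = rho, noise_sd = noise_sd,
                   noise_common = if (!is.null(noise_sd)) noise_common,
                   exposures = exposures, anchor = anchor,
                   proxy_scale = scale, seed = as.integer(seed)),
              class = "melsci_training_set")
  })
}

#' @export
print.melsci_training_set <- function(x, ...) {
  cat(sprintf("MELSCI training set: %d samples, %s features\n",
              length(x$targets),
              if (is.null(x$noise_sd)) "noise-free" else "noise-augmented"))
  cat(sprintf("  tau %.3g..%.3g ms, rho %.2f..%.2f, target 0..%.1f PU\n",
              min(x$tau), max(x$tau), min(x$rho), max(x$rho),
              max(x$targets)))
  invisible(x)
}

#' Train the multi-exposure perfusion network
#'
#' Fits a small fully connected network (default 7-64-64-1, tanh hidden
#' units, linear output) mapping the seven normalized squared-contrast
#' values to the perfusion proxy. Targets are trained in `log1p` space and
#' exponentiated at inference, which balances the heavy-tailed proxy
#' distribution; inputs and transformed targets are standardized. Training
#' uses Adam on minibatches and is deterministic given the seed. A
#' held-out validation split is scored on the raw perfusion scale
#' (coefficient of determination and regression slope) and stored in the
#' model metadata.
#'
#' @param ts A [generate_training_set()] result.
#' @param hidden Hidden layer sizes.
#' @param epochs,batch_size,learning_rate Optimizer settings.
#' @param lr_decay Per-epoch geometric learning-rate decay factor;
#'   `NULL` (default) decays the rate to 1/30 of its initial value over
#'   the run.
#' @param validation_fraction Held-out fraction for the stored metrics.
#' @param seed Integer seed for initialization and shuffling.
#' @return An object of class `melsci_net`.
#' @export
train_perfusion_net <- function(ts, hidden = c(64L, 64L), epochs = 1200L,
                                batch_size = 128L, learning_rate = 2e-3,
                                lr_decay = NULL,
                                validation_fraction = 0.2, seed = 1L) {
  if (is.null(lr_decay)) {
    lr_decay <- if (epochs > 1L) (1 / 30)^(1 / (epochs - 1L)) else 1
  }
  if (!inherits(ts, "melsci_training_set")) {
    stop("'ts' must come from generate_training_set()")
  }
  y_raw <- ts$targets
  if (length(unique(y_raw)) < 2L) {
    stop("degenerate training set: all targets identical")
  }
  X <- ts$features
  n <- nrow(X)
  n_val <- max(1L, round(validation_fraction * n))
  idx_val <- with_seed(seed + 1L, sample.int(n, n_val))
  idx_tr <- setdiff(seq_len(n), idx_val)

  feat_center <- colMeans(X[idx_tr, , drop = FALSE])
  feat_scale <- pmax(apply(X[idx_tr, , drop = FALSE], 2L, sd), 1e-8)
  Xs <- sweep(sweep(X, 2L, feat_center), 2L, feat_scale, `/`)
  yl <- log1p(y_raw)
  y_center <- mean(yl[idx_tr]); y_scale <- max(sd(yl[idx_tr]), 1e-8)
  ys <- (yl - y_center) / y_scale

  par <- mlp_init(ncol(X), hidden, seed)
  fit <- mlp_train(par, Xs[idx_tr, , drop = FALSE], ys[idx_tr],
                   epochs = epochs, batch_size = batch_size,
                   lr = learning_rate, seed = seed + 2L,
                   Xval = Xs[idx_val, , drop = FALSE], yval = ys[idx_val],
                   lr_decay = lr_decay)

  net <- structure(list(par = fit$par, hidden = hidden,
                        feat_min = apply(X[idx_tr, , drop = FALSE], 2L, min),
                        feat_max = apply(X[idx_tr, , drop = FALSE], 2L, max),
                        feat_center = feat_center, feat_scale = feat_scale,
                        y_center = y_center, y_scale = y_scale,
                        exposures = ts$exposures, seed = as.integer(seed),
                        history = fit$history,
                        config = list(epochs = epochs,
                                      batch_size = batch_size,
                                      learning_rate = learning_rate,
                                      lr_decay = lr_decay,
                                      noise_sd = ts$noise_sd,
                                      proxy_scale = ts$proxy_scale)),
                   class = "melsci_net")
  pred_val <- predict(net, X[idx_val, , drop = FALSE])
  truth_val <- y_raw[idx_val]
  net$metrics <- regression_metrics(pred_val, truth_val)
  net$metrics$n_val <- n_val
  net
}

# R^2 (coefficient of determination of the linear fit) and slope of
# prediction vs truth
regression_metrics <- function(pred, truth) {
  ok <- is.finite(pred) & is.finite(truth)
  fit <- lm(pred[ok] ~ truth[ok])
  list(r2 = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' @export
print.melsci_net <- function(x, ...) {
  cat(sprintf("MELSCI perfusion network: 7-%s-1 (tanh), seed %d\n",
              paste(x$hidden, collapse = "-"), x$seed))
  if (!is.null(x$metrics)) {
    cat(sprintf("  held-out: R2 = %.4f, slope = %.3f (n = %d)\n",
                x$metrics$r2, x$metrics$slope, x$metrics$n_val))
  }
  cat(sprintf("  trained %s feature noise\n",
              if (is.null(x$config$noise_sd)) "without" else "with"))
  invisible(x)
}

#' Predict perfusion from contrast features
#'
#' Features are clipped column-wise to the range seen during training
#' before standardization: the network's log-scale output is unbounded and
#' extrapolates erratically on out-of-distribution contrast curves (e.g.
#' single noisy blocks whose normalized contrast exceeds 1 by several
#' standard deviations), so predictions outside the training envelope are
#' pinned to its boundary instead.
#'
#' @param object A `melsci_net`.
#' @param newdata An `n x 7` matrix of normalized squared contrast (columns
#'   in exposure order 1..64 ms).
#' @param ... Unused.
#' @return Numeric vector of non-negative perfusion values; rows with
#'   missing features give `NA`.
#' @export
predict.melsci_net <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$exposures)) {
    stop("expected ", length(object$exposures), " feature columns")
  }
  out <- rep(NA_real_, nrow(X))
  ok <- stats::complete.cases(X)
  if (any(ok)) {
    Xok <- X[ok, , drop = FALSE]
    if (!is.null(object$feat_min)) {
      for (j in seq_len(ncol(Xok))) {
        Xok[, j] <- pmin(pmax(Xok[, j], object$feat_min[j]),
                         object$feat_max[j])
      }
    }
    Xs <- sweep(sweep(Xok, 2L, object$feat_center), 2L,
                object$feat_scale, `/`)
    z <- mlp_forward(object$par, Xs)[[length(object$par$w) + 1L]]
    out[ok] <- pmax(expm1(as.numeric(z) * object$y_scale + object$y_center), 0)
  }
  out
}

#' Per-pixel neural-network perfusion image
#'
#' Applies the trained network to every pixel of a normalized contrast
#' cube: `P_ANN = ANN[K2(1 ms), K2(2 ms), ..., K2(64 ms)]`. Invalid pixels
#' propagate. Inference is vectorized over the whole image.
#'
#' @param net A [train_perfusion_net()] result.
#' @param cube A normalized `melsci_cube`.
#' @return A `melsci_perfusion_map`.
#' @export
predict_perfusion <- function(net, cube) {
  if (!inherits(net, "melsci_net")) stop("'net' must be a melsci_net")
  check_normalized(cube)
  if (!isTRUE(all.equal(cube$exposures / cube$base_exposure,
                        net$exposures))) {
    stop("cube exposures do not match the network's training exposures")
  }
  d <- dim(cube$k2)
  feats <- matrix(cube$k2, d[1] * d[2], d[3])
  vals <- predict(net, feats)
  new_perfusion_map(matrix(vals, d[1], d[2]), "ANN")
}

#' Moving-average smoothing of a perfusion time series
#'
#' Centered moving average over `floor(window_s * cube_rate)` frames
#' (e.g. 31 frames for a 2-s window at the 15.625 cubes/s output rate of a
#' 1000-fps, 64-frame system), typically used to remove the heartbeat
#' signal. Windows shrink symmetrically at the edges.
#'
#' @param series List of `melsci_perfusion_map`s (or matrices) at a
#'   constant rate.
#' @param window_s Window length in seconds (> 0).
#' @param cube_rate Frame rate of the series, per second.
#' @return List of smoothed maps, same length as the input.
#' @export
temporal_smooth <- function(series, window_s = 2, cube_rate = 1000 / 64) {
  if (length(series) == 0L) stop("empty series")
  if (window_s <= 0) stop("'window_s' must be > 0")
  wlen <- max(1L, floor(window_s * cube_rate))
  half <- (wlen - 1L) %/% 2L
  n <- length(series)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    acc <- 0; cnt <- 0L
    for (j in lo:hi) { acc <- acc + unclass(series[[j]]); cnt <- cnt + 1L }
    m <- acc / cnt
    out[[i]] <- if (inherits(series[[i]], "melsci_perfusion_map")) {
      new_perfusion_map(m, attr(series[[i]], "model"),
                        attr(series[[i]], "exposure"))
    } else m
  }
  out
}

#' Region-of-interest time trace
#'
#' Mean perfusion over the valid pixels of a region of interest, per
#' frame.
#'
#' @param series List of perfusion maps, or a single map.
#' @param roi_mask Logical matrix matching the map dimensions; `NULL`
#'   means the full image.
#' @return Numeric vector, one value per frame.
#' @export
roi_trace <- function(series, roi_mask = NULL) {
  if (inherits(series, "melsci_perfusion_map") || is.matrix(series)) {
    series <- list(series)
  }
  if (length(series) == 0L) stop("empty series")
  d <- dim(series[[1]])
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(roi_mask), d)) stop("ROI mask dimensions do not match")
  if (!any(roi_mask)) stop("empty ROI mask")
  tr <- vapply(series, function(m) {
    v <- unclass(m)[roi_mask]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  if (all(is.nan(tr))) stop("ROI contains no valid pixels")
  tr
}

#' Evaluate the perfusion models on a simulated flow sweep
#'
#' Runs the complete pipeline (contrast, noise correction, normalization)
#' on every stack of a flow sweep, computes the ROI-mean perfusion for the
#' network model and for the two single-exposure models at every exposure
#' time, and regresses each estimate against the ground-truth proxy
#' (`rho / tau`). Estimates and truth are normalized to their sweep means
#' before the slope fit, so a perfectly linear model has slope 1.
#'
#' @param flow A [simulate_flow_sweep()] result.
#' @param fit A [fit_noise_model()] result for the sweep's sensor.
#' @param scale A [measure_kmax()] result for the sweep's sensor.
#' @param net A trained [train_perfusion_net()].
#' @param roi_mask Optional ROI (block-grid resolution): a logical
#'   matrix, a list of logical matrices (probe-like ROIs whose traces
#'   are pooled into one regression, each contributing one point per
#'   stack), or `NULL` for the full image.
#' @return A list with `traces` (data.frame of per-stack, per-probe
#'   estimates) and `summary` (data.frame with columns `model`,
#'   `exposure_ms`, `r2`, `slope`).
#' @export
evaluate_flow_sweep <- function(flow, fit, scale, net, roi_mask = NULL) {
  if (!inherits(flow, "melsci_flow_sweep")) {
    stop("'flow' must come from simulate_flow_sweep()")
  }
  n <- length(flow$stacks)
  cubes <- lapply(flow$stacks, function(st) {
    normalize_contrast(correct_contrast(compute_contrast_cube(st), fit), scale)
  })
  Ts <- cubes[[1]]$exposures
  masks <- if (is.null(roi_mask) || is.matrix(roi_mask)) list(roi_mask)
           else roi_mask
  np <- length(masks)
  pooled <- function(map_fn) {
    unlist(lapply(masks, function(m) {
      vapply(cubes, function(cb) roi_trace(map_fn(cb), m), numeric(1))
    }))
  }
  traces <- data.frame(stack = rep(seq_len(n), times = np),
                       probe = rep(seq_len(np), each = n),
                       truth = rep(flow$truth, times = np),
                       ann = pooled(function(cb) predict_perfusion(net, cb)))
  for (T in Ts) {
    traces[[sprintf("k2_%g", T)]] <-
      pooled(function(cb) perfusion_k2(cb, T))
    traces[[sprintf("k_%g", T)]] <-
      pooled(function(cb) perfusion_k(cb, T))
  }
  norm_metrics <- function(est) {
    m <- regression_metrics(est / mean(est), traces$truth / mean(traces$truth))
    data.frame(r2 = m$r2, slope = m$slope)
  }
  rows <- list(cbind(model = "ANN", exposure_ms = NA_real_,
                     norm_metrics(traces$ann)))
  for (T in Ts) {
    rows <- c(rows, list(
      cbind(model = "K2", exposure_ms = T,
            norm_metrics(traces[[sprintf("k2_%g", T)]])),
      cbind(model = "K", exposure_ms = T,
            norm_metrics(traces[[sprintf("k_%g", T)]]))))
  }
  list(traces = traces, summary = do.call(rbind, rows))
}
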
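# Contrast engine: synthetic exposure synthesis by recursive pairwise
# summation, 4x4 block variance, average-intensity scaling, and squared
# speckle contrast K^2(T) = sigma^2(T) / (T^2 <I>^2).

#' Frame stack
#'
#' A set of consecutive base-exposure intensity frames, the unit of
#' acquisition. Synthetic exposure times are built from it by pairwise
#' summation, so the frame count must be a power of two.
#'
#' @param frames 3-D numeric array, `height x width x n_frames`, camera
#'   counts. Values must be finite (measured data may contain negative
#'   offsets, which are accepted).
#' @param base_exposure Exposure time of one frame, ms (nominally 1).
#' @param interframe_delay Gap between frames, ms (metadata only; assumed
#'   negligible by the summation).
#' @param metadata Free-form list (e.g. simulator ground truth).
#' @return An object of class `melsci_stack`.
#' @export
frame_stack <- function(frames, base_exposure = 1, interframe_delay = 0,
                        metadata = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("'frames' must be a height x width x n_frames array")
  }
  if (!is_power_of_two(dim(frames)[3])) {
    stop("frame count must be a power of two, got ", dim(frames)[3])
  }
  if (anyNA(frames) || !all(is.finite(frames))) {
    stop("'frames' must contain only finite values")
  }
  stopifnot_scalar_number(base_exposure, "base_exposure", min = 1e-9)
  structure(list(frames = frames, base_exposure = base_exposure,
                 interframe_delay = interframe_delay, metadata = metadata),
            class = "melsci_stack")
}

#' @export
print.melsci_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("MELSCI frame stack: %d x %d px, %d frames @ %g ms (%g..%g counts)\n",
              d[1], d[2], d[3], x$base_exposure, min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.melsci_stack <- function(x) dim(x$frames)

#' Synthesize the exposure pyramid by recursive pairwise summation
#'
#' Level 0 holds the raw base-exposure frames; each further level sums
#' temporally adjacent pairs pixelwise, doubling the exposure time, until a
#' single image at `n_frames * base_exposure` ms remains. For 64 frames
#' this yields 7 exposure times and 127 images in total.
#'
#' @param stack A [frame_stack()].
#' @return An object of class `melsci_pyramid`: list with `levels` (one
#'   `h x w x N` array per exposure), `exposures` (ms) and `base_exposure`.
#' @export
synthesize_exposures <- function(stack) {
  if (!inherits(stack, "melsci_stack")) stop("'stack' must be a frame_stack()")
  frames <- stack$frames
  n <- dim(frames)[3]
  n_levels <- as.integer(log2(n)) + 1L
  levels <- vector("list", n_levels)
  levels[[1]] <- frames
  cur <- frames
  for (k in seq_len(n_levels - 1L)) {
    m <- dim(cur)[3]
    cur <- cur[, , seq(1L, m, by = 2L), drop = FALSE] +
      cur[, , seq(2L, m, by = 2L), drop = FALSE]
    levels[[k + 1L]] <- cur
  }
  structure(list(levels = levels,
                 exposures = stack$base_exposure * 2^(0:(n_levels - 1L)),
                 base_exposure = stack$base_exposure),
            class = "melsci_pyramid")
}

#' @export
print.melsci_pyramid <- function(x, ...) {
  n <- vapply(x$levels, function(l) dim(l)[3], integer(1))
  cat(sprintf("MELSCI exposure pyramid: %d images total\n", sum(n)))
  cat(sprintf("  T [ms]: %s\n  N:      %s\n",
              paste(format(x$exposures), collapse = " "),
              paste(format(n), collapse = " ")))
  invisible(x)
}

#' Local variance in pixel blocks
#'
#' Variance of the intensity in non-overlapping `block x block` pixel
#' regions (default 4x4, reducing the pixel count by a factor 16), or in a
#' sliding window of the same size retaining full resolution. The unbiased
#' sample variance (denominator `block^2 - 1`) is used, computed two-pass.
#'
#' @param image Numeric matrix with dimensions divisible by `block` (crop
#'   first; see [compute_contrast_cube()]).
#' @param block Block edge in pixels.
#' @param sliding If `TRUE`, compute the variance in every (overlapping)
#'   `block x block` window; the result has `(h - block + 1) x
#'   (w - block + 1)` pixels.
#' @return Matrix of variances.
#' @export
block_variance <- function(image, block = 4L, sliding = FALSE) {
  image <- as.matrix(image)
  h <- nrow(image); w <- ncol(image); b <- as.integer(block)
  if (sliding) return(sliding_variance(image, b))
  if (h %% b != 0L || w %% b != 0L) {
    stop("image dimensions must be divisible by the block size")
  }
  a <- array(image, c(b, h %/% b, b, w %/% b))
  a <- aperm(a, c(1L, 3L, 2L, 4L))
  dim(a) <- c(b * b, (h %/% b) * (w %/% b))
  mu <- colMeans(a)
  v <- colSums((a - rep(mu, each = b * b))^2) / (b * b - 1)
  matrix(v, h %/% b, w %/% b)
}

# Sliding-window mean of a matrix with a b x b kernel via 2-D cumsum.
sliding_mean <- function(image, b) {
  h <- nrow(image); w <- ncol(image)
  cs <- apply(apply(image, 2L, cumsum), 1L, cumsum)  # transposed cumsum grid
  cs <- t(cs)
  z <- matrix(0, h + 1L, w + 1L)
  z[-1L, -1L] <- cs
  i <- seq_len(h - b + 1L); j <- seq_len(w - b + 1L)
  (z[i + b, j + b] - z[i, j + b] - z[i + b, j] + z[i, j]) / (b * b)
}

sliding_variance <- function(image, b) {
  n <- b * b
  m1 <- sliding_mean(image, b)
  m2 <- sliding_mean(image^2, b)
  (m2 - m1^2) * n / (n - 1)
}

#' Average block variance per exposure time
#'
#' For each exposure `T` of the pyramid, the mean of the block-variance
#' images of its `N = n_frames * base / T` summed images.
#'
#' @param pyramid A [synthesize_exposures()] result.
#' @param block Block edge in pixels.
#' @return An `h/block x w/block x n_exposures` array of variances.
#' @export
mean_variance_per_exposure <- function(pyramid, block = 4L) {
  if (!inherits(pyramid, "melsci_pyramid")) {
    stop("'pyramid' must come from synthesize_exposures()")
  }
  b <- as.integer(block)
  d <- dim(pyramid$levels[[1]])
  h4 <- d[1] %/% b; w4 <- d[2] %/% b
  out <- array(0, c(h4, w4, length(pyramid$levels)))
  for (k in seq_along(pyramid$levels)) {
    lev <- pyramid$levels[[k]]
    N <- dim(lev)[3]
    acc <- matrix(0, h4, w4)
    for (i in seq_len(N)) acc <- acc + block_variance(lev[, , i], b)
    out[, , k] <- acc / N
  }
  out
}

#' Average 1-ms intensity per block
#'
#' The mean intensity over each `block x block x n_frames` spatiotemporal
#' block: the average base-exposure intensity image. Longer-exposure means
#' are never computed directly; the algorithm scales this plane as
#' `<I(T)> = T <I>`, which is exact under pairwise summation.
#'
#' @param stack A [frame_stack()].
#' @param block Block edge in pixels.
#' @return Matrix of mean intensities at `1/block^2` the pixel count.
#' @export
average_intensity <- function(stack, block = 4L) {
  if (!inherits(stack, "melsci_stack")) stop("'stack' must be a frame_stack()")
  d <- dim(stack$frames)
  tm <- matrix(rowMeans(matrix(stack$frames, d[1] * d[2], d[3])), d[1], d[2])
  b <- as.integer(block)
  a <- array(tm, c(b, d[1] %/% b, b, d[2] %/% b))
  a <- aperm(a, c(1L, 3L, 2L, 4L))
  dim(a) <- c(b * b, (d[1] %/% b) * (d[2] %/% b))
  matrix(colMeans(a), d[1] %/% b, d[2] %/% b)
}

#' Compute the raw multi-exposure contrast cube
#'
#' Runs the full contrast algorithm on a frame stack: synthesize the
#' exposure pyramid, average the block variances per exposure, and divide
#' by the squared scaled mean intensity,
#' `K2(T) = sigma2(T) / (T^2 <I>^2)`. Pixels with zero mean intensity are
#' flagged invalid (`NA`) rather than infinite. Dimensions not divisible by
#' the block size are cropped at the bottom/right with a warning, matching
#' the fixed block grid of the hardware algorithm.
#'
#' @param stack A [frame_stack()].
#' @param block Block edge in pixels (default 4).
#' @param sliding If `TRUE`, use a sliding window instead of
#'   non-overlapping blocks, retaining (almost) full resolution. Off by
#'   default; non-overlapping blocks are the reference algorithm.
#' @return An object of class `melsci_cube` in state `"raw"`: list with
#'   `k2` (`h x w x n_exposures` array of squared contrast),
#'   `mean_intensity`, `exposures` (ms), `state`, and bookkeeping fields.
#' @export
compute_contrast_cube <- function(stack, block = 4L, sliding = FALSE) {
  if (!inherits(stack, "melsci_stack")) stop("'stack' must be a frame_stack()")
  b <- as.integer(block)
  d <- dim(stack$frames)
  if (!sliding && (d[1] %% b != 0L || d[2] %% b != 0L)) {
    h <- (d[1] %/% b) * b; w <- (d[2] %/% b) * b
    if (h < b || w < b) stop("image smaller than one block")
    warning(sprintf("cropping %d x %d frames to %d x %d (block grid of %d)",
                    d[1], d[2], h, w, b))
    stack <- frame_stack(stack$frames[seq_len(h), seq_len(w), , drop = FALSE],
                         base_exposure = stack$base_exposure,
                         interframe_delay = stack$interframe_delay,
                         metadata = stack$metadata)
    d <- dim(stack$frames)
  }
  pyr <- synthesize_exposures(stack)
  Ts <- pyr$exposures
  if (sliding) {
    hh <- d[1] - b + 1L; ww <- d[2] - b + 1L
    vars <- array(0, c(hh, ww, length(Ts)))
    for (k in seq_along(pyr$levels)) {
      lev <- pyr$levels[[k]]
      acc <- matrix(0, hh, ww)
      for (i in seq_len(dim(lev)[3])) acc <- acc + sliding_variance(lev[, , i], b)
      vars[, , k] <- acc / dim(lev)[3]
    }
    tm <- matrix(rowMeans(matrix(stack$frames, d[1] * d[2], d[3])), d[1], d[2])
    mi <- sliding_mean(tm, b)
  } else {
    vars <- mean_variance_per_exposure(pyr, b)
    mi <- average_intensity(stack, b)
  }
  # K2(T) = sigma^2(T) / (T <I>)^2 with the mean intensity of the summed
  # image obtained exactly by scaling: <I(T)> = (T / base) <I>. The base
  # exposure cancels, so T enters as the number of summed frames.
  tb <- stack$base_exposure
  k2 <- vars
  valid <- mi > 0
  if (!any(valid)) {
    stop("all-dark stack: every output pixel has zero mean intensity")
  }
  denom <- mi^2
  for (k in seq_along(Ts)) {
    plane <- k2[, , k]
    plane[valid] <- plane[valid] / ((Ts[k] / tb)^2 * denom[valid])
    plane[!valid] <- NA_real_
    k2[, , k] <- plane
  }
  new_contrast_cube(k2 = k2, mean_intensity = mi, exposures = Ts,
                    base_exposure = tb, state = "raw", block = b,
                    sliding = sliding)
}

new_contrast_cube <- function(k2, mean_intensity, exposures, base_exposure,
                              state, block, sliding = FALSE, n_clamped = 0L,
                              calibration = NULL, k2_max = NULL) {
  structure(list(k2 = k2, mean_intensity = mean_intensity,
                 exposures = exposures, base_exposure = base_exposure,
                 state = state, block = block, sliding = sliding,
                 n_clamped = n_clamped, calibration = calibration,
                 k2_max = k2_max,
                 format_version = "1.0"),
            class = "melsci_cube")
}

#' @export
print.melsci_cube <- function(x, ...) {
  d <- dim(x$k2)
  cat(sprintf("MELSCI contrast cube [%s]: %d x %d px, T = %s ms\n",
              x$state, d[1], d[2], paste(format(x$exposures), collapse = ",")))
  mk <- apply(x$k2, 3, mean, na.rm = TRUE)
  cat(sprintf("  mean K2(T): %s\n", paste(sprintf("%.4f", mk), collapse = " ")))
  cat(sprintf("  mean <I>: %.1f counts; invalid px: %d; clamped: %d\n",
              mean(x$mean_intensity), sum(is.na(x$k2[, , 1])), x$n_clamped))
  invisible(x)
}

#' Display the planes of a contrast cube
#'
#' @param x A `melsci_cube`.
#' @param exposure Which exposure plane (ms) to show; defaults to all.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.melsci_cube <- function(x, exposure = NULL, ...) {
  Ts <- if (is.null(exposure)) x$exposures else exposure
  idx <- match(Ts, x$exposures)
  if (anyNA(idx)) stop("unknown exposure; available: ",
                       paste(x$exposures, collapse = ", "))
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(idx)),
                      mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (k in idx) {
    graphics::image(t(x$k2[rev(seq_len(nrow(x$k2))), , k]), axes = FALSE,
                    main = sprintf("K2(%g ms)", x$exposures[k]), ...)
  }
  invisible(x)
}
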
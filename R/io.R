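# File formats: multi-page TIFF frame stacks (16-bit unsigned or 32-bit
# float with a sidecar scale), serialized contrast cubes, and JSON
# calibration / model files.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a frame stack as a multi-page TIFF
#'
#' One page per base-exposure frame. `"uint16"` (default) rounds counts to
#' 16-bit unsigned integers, the camera-native representation; integer
#' counts round-trip bit-exactly. `"float"` stores 32-bit floats scaled by
#' the stack maximum (recorded in the sidecar), preserving fractional
#' counts to single precision. A JSON sidecar (`<path>.json`) carries the
#' base exposure and format metadata.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @param format `"uint16"` or `"float"`.
#' @return Invisibly, `path`.
#' @export
write_frame_stack <- function(stack, path, format = c("uint16", "float")) {
  format <- match.arg(format)
  if (!inherits(stack, "melsci_stack")) stop("'stack' must be a frame_stack()")
  d <- dim(stack$frames)
  scale <- 1
  if (format == "uint16") {
    if (min(stack$frames) < 0 || max(stack$frames) > 65535) {
      stop("uint16 output requires counts in [0, 65535]")
    }
    pages <- lapply(seq_len(d[3]), function(f) {
      round(stack$frames[, , f]) / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else {
    scale <- max(stack$frames, 1e-12)
    pages <- lapply(seq_len(d[3]), function(f) stack$frames[, , f] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  }
  meta <- list(format = format, scale = scale,
               base_exposure_ms = stack$base_exposure,
               interframe_delay_ms = stack$interframe_delay,
               n_frames = d[3], height = d[1], width = d[2],
               writer = "melsci", format_version = "1.0")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF frame stack
#'
#' Accepts 8/16-bit unsigned integer TIFFs (returned as counts) and 32-bit
#' float TIFFs (rescaled by the sidecar's scale when present). All pages
#' must share one size; the page count must be a power of two.
#'
#' @param path TIFF path; a `<path>.json` sidecar is used when present.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("empty TIFF: ", path)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("mixed page dimensions in ", path)
  }
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  probe <- tiff::readTIFF(path, info = TRUE)
  is_float <- identical(attr(probe, "sample.format"), "float") ||
    identical(meta$format, "float")
  if (is_float) {
    # float samples must not be re-read "as is" (integer reinterpretation)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  scale <- if (is_float) (meta$scale %||% 1) else 1
  d <- dim(pages[[1]])
  frames <- array(0, c(d[1], d[2], length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]] * scale
  frame_stack(frames,
              base_exposure = meta$base_exposure_ms %||% 1,
              interframe_delay = meta$interframe_delay_ms %||% 0,
              metadata = list(source = path))
}

#' Write a contrast cube
#'
#' Serializes the cube (seven squared-contrast planes, the mean-intensity
#' plane, the exposure list, the processing state and calibration
#' bookkeeping) to a single self-describing container file.
#'
#' @param cube A `melsci_cube`.
#' @param path Output path (conventionally `.rds`).
#' @return Invisibly, `path`.
#' @export
write_contrast_cube <- function(cube, path) {
  if (!inherits(cube, "melsci_cube")) stop("'cube' must be a melsci_cube")
  saveRDS(cube, path)
  invisible(path)
}

#' Read a contrast cube
#'
#' Validates the container: the processing state must be one of `raw`,
#' `corrected`, `normalized` (a missing or tampered state is an error); a
#' newer minor format version elicits a warning, not an error.
#'
#' @param path Path written by [write_contrast_cube()].
#' @return A `melsci_cube`.
#' @export
read_contrast_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cube <- readRDS(path)
  if (!inherits(cube, "melsci_cube")) stop("not a contrast cube: ", path)
  if (is.null(cube$state) ||
      !cube$state %in% c("raw", "corrected", "normalized")) {
    stop("invalid or missing processing state in ", path, ": ",
         deparse(cube$state))
  }
  ver <- cube$format_version %||% "1.0"
  if (ver != "1.0") {
    warning("cube written by a newer format version (", ver,
            "); reading anyway")
  }
  cube
}

#' Write calibration (noise fit and contrast scale) to JSON
#'
#' @param fit A [fit_noise_model()] result.
#' @param path Output JSON path.
#' @param scale Optional [measure_kmax()] result.
#' @param sensor_seed Optional sensor seed recorded for provenance.
#' @return Invisibly, `path`.
#' @export
write_calibration <- function(fit, path, scale = NULL, sensor_seed = NULL) {
  obj <- list(noise = as.list(coef(fit)),
              simplex = as.list(fit$simplex),
              rss = fit$rss, levels_used = fit$levels_used,
              k2_max = if (!is.null(scale)) scale$k2_max,
              sensor_seed = sensor_seed, format_version = "1.0")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a calibration JSON file
#'
#' @param path Path written by [write_calibration()].
#' @return A list with `params` (named vector usable by
#'   [correct_contrast()]) and `k2_max` (or `NULL`).
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$noise)) stop("not a calibration file: ", path)
  params <- unlist(obj$noise)[c("n_shot", "n_dark", "e_const")]
  if (anyNA(params)) stop("calibration file misses noise parameters: ", path)
  list(params = params, k2_max = obj$k2_max, sensor_seed = obj$sensor_seed)
}

#' Write a trained perfusion network to JSON
#'
#' Self-describing model file: architecture, weights, input/output scaling
#' constants, training seed and held-out metrics, at full numeric
#' precision.
#'
#' @param net A `melsci_net`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_perfusion_net <- function(net, path) {
  if (!inherits(net, "melsci_net")) stop("'net' must be a melsci_net")
  obj <- list(hidden = net$hidden,
              weights = lapply(net$par$w, function(w) {
                list(dim = dim(w), values = as.numeric(w))
              }),
              biases = net$par$b,
              feat_min = net$feat_min, feat_max = net$feat_max,
              feat_center = net$feat_center, feat_scale = net$feat_scale,
              y_center = net$y_center, y_scale = net$y_scale,
              exposures = net$exposures, seed = net$seed,
              metrics = net$metrics, config = net$config,
              format_version = "1.0")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a perfusion network from JSON
#'
#' @param path Path written by [write_perfusion_net()].
#' @return A `melsci_net`.
#' @export
read_perfusion_net <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$weights)) stop("not a perfusion model file: ", path)
  w <- lapply(obj$weights, function(l) {
    matrix(unlist(l$values), unlist(l$dim)[1], unlist(l$dim)[2])
  })
  b <- lapply(obj$biases, as.numeric)
  structure(list(par = list(w = w, b = b), hidden = as.integer(obj$hidden),
                 feat_min = if (!is.null(obj$feat_min))
                   as.numeric(obj$feat_min),
                 feat_max = if (!is.null(obj$feat_max))
                   as.numeric(obj$feat_max),
                 feat_center = as.numeric(obj$feat_center),
                 feat_scale = as.numeric(obj$feat_scale),
                 y_center = obj$y_center, y_scale = obj$y_scale,
                 exposures = as.numeric(obj$exposures),
                 seed = obj$seed, metrics = obj$metrics,
                 config = obj$config),
            class = "melsci_net")
}
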
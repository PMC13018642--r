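#' Acquisition/storage profile of the ingestible imaging device
#'
#' Quantitative deployment profile of the wireless ingestible imaging
#' device: frame geometry, frame rate, procedure duration, compression
#' ratio and onboard storage. Decimal (SI) byte prefixes are used
#' throughout (1 kB = 1000 B, 1 GB = 1e9 B): the published 768 kB/s figure
#' only reconstructs under SI prefixes.
#'
#' @param width,height frame size in pixels.
#' @param bytes_per_pixel bytes per pixel (3 for RGB).
#' @param fps frames per second.
#' @param duration_h procedure duration in hours.
#' @param compression_ratio achieved compression, >= 1.
#' @param storage_capacity onboard storage in bytes.
#' @return object of class `deployment_profile`.
#' @export
deployment_profile <- function(width = 320, height = 320,
                               bytes_per_pixel = 3, fps = 2.5,
                               duration_h = 8, compression_ratio = 10,
                               storage_capacity = 16e9) {
  vals <- c(width, height, bytes_per_pixel, fps, duration_h,
            compression_ratio, storage_capacity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all profile fields must be positive")
  if (compression_ratio < 1) stop("compression_ratio must be >= 1")
  structure(list(width = width, height = height,
                 bytes_per_pixel = bytes_per_pixel, fps = fps,
                 duration_h = duration_h,
                 compression_ratio = compression_ratio,
                 storage_capacity = storage_capacity),
            class = "deployment_profile")
}

#' Raw acquisition rate
#'
#' `width * height * bytes_per_pixel * fps`, exactly multiplicative in each
#' factor.
#'
#' @param profile a [deployment_profile()].
#' @return list: `bytes_per_s` and `kB_per_s` (SI, 1 kB = 1000 B).
#' @export
raw_rate <- function(profile) {
  stopifnot(inherits(profile, "deployment_profile"))
  bps <- profile$width * profile$height * profile$bytes_per_pixel *
    profile$fps
  list(bytes_per_s = bps, kB_per_s = bps / 1000)
}

#' Per-procedure storage requirement
#'
#' Compressed bytes accumulated over the procedure,
#' `raw_rate * duration * 3600 / compression_ratio`, the frame count
#' `fps * duration * 3600`, and a pass/fail flag against the onboard
#' storage capacity.
#'
#' @param profile a [deployment_profile()].
#' @return list: `bytes`, `GB` (SI), `frame_count`, `raw_bytes`,
#'   `fits_storage`.
#' @export
procedure_storage <- function(profile) {
  stopifnot(inherits(profile, "deployment_profile"))
  raw <- raw_rate(profile)$bytes_per_s * profile$duration_h * 3600
  bytes <- raw / profile$compression_ratio
  list(bytes = bytes, GB = bytes / 1e9,
       frame_count = profile$fps * profile$duration_h * 3600,
       raw_bytes = raw,
       fits_storage = bytes <= profile$storage_capacity)
}
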
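#' Optical configuration for a lens-free in-line holographic microscope
#'
#' Single source of truth for the physical units of the instrument: the
#' illumination wavelength, the detector pixel pitch, the pixel
#' super-resolution upsampling factor and the axial (z) geometry. All lengths
#' are in micrometres; unit conversion happens only at the I/O boundary.
#'
#' The geometry is the Gabor in-line one: a quasi-plane wave illuminates a
#' thin sample placed close to the sensor, so the hologram magnification is
#' fixed to one. The source-to-sample distance is retained for documentation
#' and simulator realism only; propagation assumes plane-wave illumination.
#'
#' @param wavelength Illumination wavelength in um (default 0.532).
#' @param pixel_pitch Detector pixel pitch in um (default 1.67).
#' @param upsample_factor Integer pixel super-resolution factor (default 6).
#' @param z_sample_to_sensor Nominal sample-to-sensor distance in um
#'   (default 721).
#' @param z_source_to_sample Source-to-sample distance in um (default 80000,
#'   i.e. 80 mm; large enough that the illumination is effectively planar).
#' @param refractive_index Medium refractive index (default 1).
#'
#' @return An object of class \code{optical_config}.
#' @examples
#' cfg <- optical_config()
#' highres_pitch(cfg) # 1.67 / 6 = 0.2783 um
#' @export
optical_config <- function(wavelength = 0.532,
                           pixel_pitch = 1.67,
                           upsample_factor = 6L,
                           z_sample_to_sensor = 721,
                           z_source_to_sample = 80000,
                           refractive_index = 1.0) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0)
    stop("`wavelength` must be a single positive number (um)", call. = FALSE)
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0)
    stop("`pixel_pitch` must be a single positive number (um)", call. = FALSE)
  upsample_factor <- as.integer(upsample_factor)
  if (is.na(upsample_factor) || upsample_factor < 1L)
    stop("`upsample_factor` must be an integer >= 1", call. = FALSE)
  if (z_sample_to_sensor <= 0)
    stop("`z_sample_to_sensor` must be positive", call. = FALSE)
  if (refractive_index <= 0)
    stop("`refractive_index` must be positive", call. = FALSE)
  structure(
    list(
      wavelength = wavelength,
      pixel_pitch = pixel_pitch,
      upsample_factor = upsample_factor,
      z_sample_to_sensor = z_sample_to_sensor,
      z_source_to_sample = z_source_to_sample,
      refractive_index = refractive_index
    ),
    class = "optical_config"
  )
}

#' High-resolution grid pitch
#'
#' Pitch of the super-resolved grid: detector pitch divided by the upsampling
#' factor (0.278 um at the defaults).
#'
#' @param config An \code{optical_config}.
#' @return Pitch in um.
#' @export
highres_pitch <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  config$pixel_pitch / config$upsample_factor
}

#' Sensor field of view in square millimetres
#'
#' Unit-magnification holography images the full sensor area, so the field of
#' view is simply \code{(nx * pitch) * (ny * pitch)}.
#'
#' @param config An \code{optical_config} (or a \code{pipeline_config}; its
#'   optical block is used).
#' @param sensor_dims Integer pair \code{c(nx, ny)} of sensor pixels.
#' @param digits Decimal places for the reported value (default 2).
#' @return FOV area in mm^2, rounded to \code{digits}.
#' @examples
#' report_fov(optical_config(), c(3872, 2764)) # 29.85
#' @export
report_fov <- function(config, sensor_dims, digits = 2) {
  if (inherits(config, "pipeline_config")) config <- config$optical
  stopifnot(inherits(config, "optical_config"))
  sensor_dims <- as.numeric(sensor_dims)
  if (length(sensor_dims) != 2L || any(sensor_dims <= 0))
    stop("`sensor_dims` must be two positive integers", call. = FALSE)
  area_um2 <- prod(sensor_dims) * config$pixel_pitch^2
  round(area_um2 / 1e6, digits)
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration (lens-free in-line holography)\n")
  cat(sprintf("  wavelength          : %.4g um\n", x$wavelength))
  cat(sprintf("  detector pixel pitch: %.4g um\n", x$pixel_pitch))
  cat(sprintf("  upsample factor     : %d (high-res pitch %.4g um)\n",
              x$upsample_factor, highres_pitch(x)))
  cat(sprintf("  sample-to-sensor z  : %.4g um\n", x$z_sample_to_sensor))
  cat(sprintf("  source-to-sample z  : %.4g um\n", x$z_source_to_sample))
  invisible(x)
}
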
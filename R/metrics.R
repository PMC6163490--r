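# Quantitative metrics used to evaluate reconstructions: axial profiles,
# full width at half maximum, and background (out-of-focus) energy.

#' Axial intensity profile through a voxel column
#'
#' Squared magnitude along z at a fixed lateral position — the quantity the
#' axial-confinement comparison between a stacked reconstruction and its
#' deconvolution is made on.
#'
#' @param vol A \code{volume3d}.
#' @param row,col Lateral voxel indices.
#' @return Numeric vector of length nz.
#' @export
axial_profile <- function(vol, row, col) {
  stopifnot(inherits(vol, "volume3d"))
  Mod(vol$data[row, col, ])^2
}

#' Full width at half maximum of a sampled profile
#'
#' Peak width at half height above the profile minimum, with linear
#' interpolation of the two half-crossings flanking the global peak.
#' Returns \code{NA} when the profile never falls to half height on one
#' side (peak too close to the edge).
#'
#' @param y Nonnegative profile values.
#' @param x Sample coordinates (default: unit-spaced indices).
#' @return Width in the units of \code{x}, or \code{NA}.
#' @export
fwhm <- function(y, x = seq_along(y)) {
  if (length(y) != length(x)) stop("lengths differ", call. = FALSE)
  ipk <- which.max(y)
  half <- min(y) + (y[ipk] - min(y)) / 2
  left <- NA_real_
  for (i in seq(ipk, 2L)) {
    if (y[i - 1L] <= half) {
      left <- x[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) *
        (x[i] - x[i - 1L])
      break
    }
  }
  right <- NA_real_
  if (ipk < length(y)) for (i in seq(ipk, length(y) - 1L)) {
    if (y[i + 1L] <= half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i])
      break
    }
  }
  right - left
}

#' Energy of an image or volume over a region
#'
#' Sum of squared magnitudes over the voxels selected by \code{mask}
#' (default: everything). Used to quantify twin-image and out-of-focus
#' artifact energy over the background (the complement of the known object
#' support in simulations).
#'
#' @param x Numeric/complex array, matrix, \code{complex_field} or
#'   \code{volume3d}.
#' @param mask Logical array of the same shape, or NULL.
#' @return Nonnegative scalar.
#' @export
region_energy <- function(x, mask = NULL) {
  if (inherits(x, "complex_field")) x <- x$data
  if (inherits(x, "volume3d")) x <- x$data
  v <- Mod(x)^2
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(v))) stop("mask shape differs", call. = FALSE)
    v <- v[mask]
  }
  sum(v)
}
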
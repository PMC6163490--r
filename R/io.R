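# TIFF/CSV/JSON interchange.
#
# Images and volumes travel as 32-bit float TIFF with every page affinely
# normalized to [0, 1]; the per-page offsets/scales and the physical
# metadata (pitch, wavelength, z) live in a JSON sidecar written next to
# the TIFF (path + ".json"). Complex data uses paired pages
# (real, imaginary). Shift tables are plain CSV.

sidecar_path <- function(path) paste0(path, ".json")

# normalize pages to [0,1] for float TIFF storage; returns pages + transforms
.normalize_pages <- function(pages) {
  mins <- vapply(pages, min, numeric(1L))
  maxs <- vapply(pages, max, numeric(1L))
  scaled <- lapply(seq_along(pages), function(i) {
    rng <- maxs[i] - mins[i]
    if (rng <= 0) matrix(0, nrow(pages[[i]]), ncol(pages[[i]])) else
      (pages[[i]] - mins[i]) / rng
  })
  list(pages = scaled, mins = mins, maxs = maxs)
}

.write_pages <- function(pages, path, meta) {
  nm <- .normalize_pages(pages)
  tiff::writeTIFF(nm$pages, path, bits.per.sample = 32L)
  meta$page_min <- nm$mins
  meta$page_max <- nm$maxs
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.read_pages <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(sidecar_path(path)))
    stop("missing JSON sidecar: ", sidecar_path(path), call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  raw <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  pages <- lapply(seq_along(raw), function(i) {
    rng <- meta$page_max[i] - meta$page_min[i]
    raw[[i]] * rng + meta$page_min[i]
  })
  list(pages = pages, meta = meta)
}

#' Write a complex field as a paired-page float TIFF
#'
#' Page 1 holds the real part, page 2 the imaginary part; pitch, wavelength
#' and the z tag go to a JSON sidecar at \code{path + ".json"}.
#'
#' @param field A \code{complex_field}.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_complex_tiff <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  .write_pages(list(Re(field$data), Im(field$data)), path,
               list(type = "complex_field", pitch = field$pitch,
                    wavelength = field$wavelength,
                    z_position = field$z_position))
}

#' Read a complex field written by \code{write_complex_tiff}
#' @param path TIFF path (sidecar expected alongside).
#' @return A \code{complex_field}.
#' @export
read_complex_tiff <- function(path) {
  r <- .read_pages(path)
  if (!identical(r$meta$type, "complex_field"))
    stop("not a complex_field TIFF: ", path, call. = FALSE)
  complex_field(r$pages[[1L]] + 1i * r$pages[[2L]], r$meta$pitch,
                r$meta$wavelength, r$meta$z_position)
}

#' Write a single intensity image as float TIFF with sidecar metadata
#' @param image Numeric matrix.
#' @param path Output path.
#' @param pitch Grid pitch in um recorded in the sidecar.
#' @return The path, invisibly.
#' @export
write_intensity_tiff <- function(image, path, pitch) {
  m <- as.matrix(image); attributes(m) <- list(dim = dim(m))
  .write_pages(list(m), path,
               list(type = "intensity", pitch = pitch))
}

#' Read an intensity image written by \code{write_intensity_tiff}
#' @param path TIFF path.
#' @return Matrix with attribute \code{pitch}.
#' @export
read_intensity_tiff <- function(path) {
  r <- .read_pages(path)
  out <- r$pages[[1L]]
  attr(out, "pitch") <- r$meta$pitch
  out
}

#' Write a 3D volume as a multi-page float TIFF z-stack
#'
#' Amplitude volumes store one page per plane; complex volumes store
#' real/imaginary page pairs. z values, pitch and mode go to the sidecar.
#'
#' @param vol A \code{volume3d}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  nz <- dim(vol$data)[3L]
  pages <- if (vol$mode == "amplitude") {
    lapply(seq_len(nz), function(i) vol$data[, , i])
  } else {
    unlist(lapply(seq_len(nz), function(i)
      list(Re(vol$data[, , i]), Im(vol$data[, , i]))), recursive = FALSE)
  }
  .write_pages(pages, path,
               list(type = "volume3d", mode = vol$mode,
                    pitch_xy = vol$pitch_xy, z_values = vol$z_values))
}

#' Read a volume written by \code{write_volume_tiff}
#' @param path TIFF path.
#' @return A \code{volume3d}.
#' @export
read_volume_tiff <- function(path) {
  r <- .read_pages(path)
  if (!identical(r$meta$type, "volume3d"))
    stop("not a volume3d TIFF: ", path, call. = FALSE)
  nz <- length(r$meta$z_values)
  d <- dim(r$pages[[1L]])
  if (identical(r$meta$mode, "amplitude")) {
    data <- array(0, c(d, nz))
    for (i in seq_len(nz)) data[, , i] <- pmax(r$pages[[i]], 0)
  } else {
    data <- array(0i, c(d, nz))
    for (i in seq_len(nz))
      data[, , i] <- r$pages[[2L * i - 1L]] + 1i * r$pages[[2L * i]]
  }
  volume3d(data, r$meta$pitch_xy, r$meta$z_values, r$meta$mode)
}

#' Write a sub-pixel shift table as CSV
#'
#' Columns \code{frame}, \code{dx_um}, \code{dy_um} — the layout expected
#' by the command-line PSR stage.
#'
#' @param shifts Two-column matrix of (dx, dy) in um, or a
#'   \code{lowres_stack}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_shifts_csv <- function(shifts, path) {
  if (inherits(shifts, "lowres_stack")) shifts <- shifts$shifts
  df <- data.frame(frame = seq_len(nrow(shifts)),
                   dx_um = shifts[, 1L], dy_um = shifts[, 2L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a shift table written by \code{write_shifts_csv}
#' @param path CSV path.
#' @return Matrix with columns \code{dx}, \code{dy} (um), ordered by frame.
#' @export
read_shifts_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "dx_um", "dy_um")
  if (!all(need %in% names(df)))
    stop("shifts CSV must have columns frame, dx_um, dy_um", call. = FALSE)
  df <- df[order(df$frame), ]
  m <- cbind(dx = df$dx_um, dy = df$dy_um)
  m
}
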
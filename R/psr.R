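# Pixel super-resolution: synthesize one fine-pitch intensity image from a
# grid of sub-pixel-shifted coarse frames acquired with a motorized stage.
# The stage shifts are known, so no shift estimation is performed:
# deterministic shift-and-add onto the upsampled grid, normalized by
# per-pixel coverage, with an optional Wiener deblur of the detector
# pixel-aperture (box) kernel.

#' Stack of sub-pixel-shifted low-resolution frames
#'
#' @param frames List of nonnegative intensity matrices, all the same shape.
#' @param shifts Two-column matrix (or list of pairs) of per-frame
#'   \code{(dx, dy)} shifts in um, in sample-plane coordinates.
#' @param pitch Detector pixel pitch in um.
#' @param height_id Integer tag identifying the acquisition height.
#' @return An object of class \code{lowres_stack}.
#' @export
lowres_stack <- function(frames, shifts, pitch, height_id = 1L) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  if (is.list(shifts)) shifts <- do.call(rbind, lapply(shifts, as.numeric))
  shifts <- as.matrix(shifts)
  if (nrow(shifts) != length(frames) || ncol(shifts) != 2L)
    stop("`shifts` must supply one (dx, dy) pair per frame", call. = FALSE)
  dims <- dim(frames[[1L]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims))
      stop("all frames must be matrices of one shape", call. = FALSE)
    if (any(!is.finite(f)) || any(f < 0))
      stop("frames must be finite and nonnegative", call. = FALSE)
  }
  if (pitch <= 0) stop("`pitch` must be positive", call. = FALSE)
  structure(
    list(frames = frames, shifts = shifts, pitch = pitch,
         height_id = as.integer(height_id)),
    class = "lowres_stack"
  )
}

#' Sub-pixel acquisition shift grid
#'
#' The k^2 stage shift vectors \code{(i*s, j*s)}, \code{0 <= i, j < k}, with
#' spacing \code{s = pitch / k} (0.278 um for a factor of 6 at 1.67 um
#' pixels), in row-major order (dy varies slowest).
#'
#' @param upsample_factor Integer k >= 1.
#' @param pitch Detector pixel pitch in um.
#' @return A k^2 x 2 matrix with columns \code{dx}, \code{dy} (um).
#' @examples
#' nrow(grid_shifts(6, 1.67)) # 36 frames per height
#' @export
grid_shifts <- function(upsample_factor, pitch) {
  k <- as.integer(upsample_factor)
  if (is.na(k) || k < 1L)
    stop("`upsample_factor` must be an integer >= 1", call. = FALSE)
  if (pitch <= 0) stop("`pitch` must be positive", call. = FALSE)
  s <- pitch / k
  g <- expand.grid(dx = (seq_len(k) - 1L) * s, dy = (seq_len(k) - 1L) * s,
                   KEEP.OUT.ATTRS = FALSE)
  # row-major: iterate dx fastest within each dy row
  m <- as.matrix(g[order(g$dy, g$dx), c("dx", "dy")])
  dimnames(m) <- list(NULL, c("dx", "dy"))
  m
}

#' Synthesize a high-resolution intensity image from a shifted stack
#'
#' Shift-and-add super-resolution using the known stage shifts: each coarse
#' frame is splatted onto the k-times-finer grid at its shift offset
#' (bilinear splatting of any sub-node residual), accumulated, and normalized
#' by per-pixel coverage. With \code{deblur = TRUE} the detector
#' pixel-aperture blur (a k x k box kernel on the fine grid) is removed by a
#' regularized Wiener inverse filter.
#'
#' @param stack A \code{lowres_stack}.
#' @param upsample_factor Integer k; the output grid is k times finer.
#' @param deblur Remove the pixel-aperture box blur (default FALSE).
#' @param reg Wiener regularizer for the aperture deblur (default 1e-3).
#' @return Nonnegative intensity matrix of shape \code{(k*ny, k*nx)} with
#'   attribute \code{pitch} set to \code{stack$pitch / k}.
#' @export
synthesize_highres <- function(stack, upsample_factor, deblur = FALSE,
                               reg = 1e-3) {
  stopifnot(inherits(stack, "lowres_stack"))
  k <- as.integer(upsample_factor)
  if (is.na(k) || k < 1L)
    stop("`upsample_factor` must be an integer >= 1", call. = FALSE)
  ny <- nrow(stack$frames[[1L]]); nx <- ncol(stack$frames[[1L]])
  NY <- ny * k; NX <- nx * k
  hp <- stack$pitch / k

  shifts <- stack$shifts
  if (any(shifts < 0) || any(shifts >= stack$pitch)) {
    warning("shifts outside [0, pitch) normalized modulo the pixel pitch")
    shifts <- shifts %% stack$pitch
  }

  acc <- matrix(0, NY, NX)
  cov <- matrix(0, NY, NX)
  base_row <- (seq_len(ny) - 1L) * k   # 0-based fine-grid rows of pixel 1..ny
  base_col <- (seq_len(nx) - 1L) * k
  splat <- function(frame, off_row, off_col, w) {
    if (w <= 0) return(invisible(NULL))
    rows <- (base_row + off_row) %% NY + 1L
    cols <- (base_col + off_col) %% NX + 1L
    acc[rows, cols] <<- acc[rows, cols] + w * frame
    cov[rows, cols] <<- cov[rows, cols] + w
  }
  for (m in seq_along(stack$frames)) {
    ox <- shifts[m, 1L] / hp          # fine-grid nodes along x (columns)
    oy <- shifts[m, 2L] / hp
    i0 <- floor(ox); ry <- oy - floor(oy); rx <- ox - i0; j0 <- floor(oy)
    f <- stack$frames[[m]]
    # bilinear splat of the sub-node residual over the 4 neighbouring nodes
    splat(f, j0,      i0,      (1 - rx) * (1 - ry))
    splat(f, j0,      i0 + 1,  rx       * (1 - ry))
    splat(f, j0 + 1,  i0,      (1 - rx) * ry)
    splat(f, j0 + 1,  i0 + 1,  rx       * ry)
  }
  if (any(cov == 0)) {
    warning("some high-res pixels received no frame coverage; ",
            "filled with the stack mean")
    acc[cov == 0] <- mean(acc[cov > 0] / cov[cov > 0])
    cov[cov == 0] <- 1
  }
  out <- acc / cov

  if (isTRUE(deblur) && k > 1L) {
    # aperture kernel: k x k box at offsets 0..k-1 (the block each detector
    # pixel integrates); shift-and-add output is the cross-correlation of the
    # truth with this kernel, so divide by conj in the Fourier domain
    ker <- matrix(0, NY, NX)
    ker[seq_len(k), seq_len(k)] <- 1 / k^2
    Kf <- stats::fft(ker)
    Of <- stats::fft(out)
    est <- stats::fft(Of * Kf / (Mod(Kf)^2 + reg), inverse = TRUE) / (NY * NX)
    out <- pmax(Re(est), 0)
  }
  attr(out, "pitch") <- hp
  out
}
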
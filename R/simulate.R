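# Forward model and fixture generator.
#
# Emulates the acquisition chain of a lens-free in-line holographic
# microscope: thin transmissive objects on one or more axial planes,
# unit plane-wave illumination, multi-slice angular-spectrum propagation to
# the detector, box-integrating detector pixels, a k x k sub-pixel shift
# grid, multiple detector heights, and optional additive Gaussian intensity
# noise. Every generator is deterministic under its seed so the whole
# pipeline is testable without experimental data.

#' Scene specification for the forward simulator
#'
#' A list of thin transmissive planes, each a complex transmission grid
#' \code{t(x, y)} with \code{|t| <= 1} at an axial distance z (um, to the
#' detector at its base position), on a common high-resolution grid.
#'
#' @param planes List of \code{list(z = , t = )} entries; \code{t} complex or
#'   numeric matrices of one shape with \code{|t| <= 1}.
#' @param pitch High-resolution grid pitch in um.
#' @param noise_sigma Additive Gaussian intensity noise level as a fraction
#'   of the mean intensity (default 0).
#' @param seed Integer seed controlling every random draw tied to the scene.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(planes, pitch, noise_sigma = 0, seed = 1L) {
  if (!is.list(planes) || length(planes) < 1L)
    stop("`planes` must be a non-empty list", call. = FALSE)
  dims <- dim(planes[[1L]]$t)
  for (p in planes) {
    if (is.null(p$z) || is.null(p$t))
      stop("each plane needs `z` and `t`", call. = FALSE)
    if (!identical(dim(p$t), dims))
      stop("all planes must share one grid shape", call. = FALSE)
    if (any(Mod(p$t) > 1 + 1e-12))
      stop("transmission magnitude must not exceed 1", call. = FALSE)
  }
  if (pitch <= 0) stop("`pitch` must be positive", call. = FALSE)
  structure(
    list(planes = planes, pitch = pitch, shape = dims,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Sparse micro-bead scene
#'
#' Disks of a given diameter at uniformly sampled lateral positions with a
#' minimum center separation of 5 diameters, assigned round-robin to the
#' requested z planes (emulating beads settled on both faces of a slide).
#' Bead centers snap to the pixel-corner lattice, so a 1 um bead covers 4
#' high-res pixels across at the default 0.278 um pitch. Deterministic per
#' seed.
#'
#' @param n Number of beads (>= 0).
#' @param diameter Bead diameter in um.
#' @param z_planes Axial distances (um) the beads are distributed over.
#' @param shape Grid dims \code{c(ny, nx)}.
#' @param pitch High-res pitch in um.
#' @param seed Integer seed.
#' @param opaque If TRUE (default) beads absorb fully (t = 0); otherwise
#'   they phase-shift by pi/2 at unit magnitude.
#' @param noise_sigma Passed to the scene (default 0).
#' @return A \code{scene_spec} with attribute \code{"centers"}: a matrix of
#'   bead x, y (um) and plane index.
#' @export
make_beads <- function(n, diameter, z_planes, shape = c(256L, 256L),
                       pitch = 1.67 / 6, seed = 1L, opaque = TRUE,
                       noise_sigma = 0) {
  n <- as.integer(n)
  if (n < 0L) stop("`n` must be >= 0", call. = FALSE)
  if (diameter <= 0) stop("`diameter` must be positive", call. = FALSE)
  shape <- as.integer(shape)
  ny <- shape[1L]; nx <- shape[2L]
  r <- diameter / 2
  sep <- 5 * diameter
  margin <- sep / 2 + r
  wx <- nx * pitch; wy <- ny * pitch
  if (n > 0L && (wx <= 2 * margin || wy <= 2 * margin))
    stop("grid too small to place any bead at this separation", call. = FALSE)

  centers <- matrix(numeric(0), 0L, 2L)
  if (n > 0L) {
    centers <- with_seed(seed, {
      acc <- matrix(NA_real_, n, 2L)
      got <- 0L; tries <- 0L; max_tries <- 2000L * n
      while (got < n && tries < max_tries) {
        tries <- tries + 1L
        # snap to the pixel-corner lattice so disk coverage is symmetric
        cx <- round(stats::runif(1L, margin, wx - margin) / pitch) * pitch
        cy <- round(stats::runif(1L, margin, wy - margin) / pitch) * pitch
        if (got == 0L ||
            all(sqrt((acc[seq_len(got), 1L] - cx)^2 +
                     (acc[seq_len(got), 2L] - cy)^2) >= sep)) {
          got <- got + 1L
          acc[got, ] <- c(cx, cy)
        }
      }
      if (got < n)
        stop(sprintf(
          "could only place %d of %d beads at separation %.3g um; ",
          got, n, sep), "reduce n or enlarge the grid", call. = FALSE)
      acc
    })
  }

  tval <- if (opaque) 0 + 0i else exp(1i * pi / 2)
  xs <- (seq_len(nx) - 0.5) * pitch   # pixel-center coordinates
  ys <- (seq_len(ny) - 0.5) * pitch
  plane_of <- if (n > 0L) ((seq_len(n) - 1L) %% length(z_planes)) + 1L else
    integer(0)                         # round-robin assignment
  planes <- lapply(seq_along(z_planes), function(ip) {
    t <- matrix(1 + 0i, ny, nx)
    for (b in which(plane_of == ip)) {
      dx2 <- (xs - centers[b, 1L])^2
      dy2 <- (ys - centers[b, 2L])^2
      inside <- outer(dy2, dx2, `+`) <= r^2
      t[inside] <- tval
    }
    list(z = z_planes[ip], t = t)
  })
  sc <- scene_spec(planes, pitch, noise_sigma = noise_sigma, seed = seed)
  attr(sc, "centers") <- cbind(x = centers[, 1L], y = centers[, 2L],
                               plane = plane_of)
  sc
}

#' Three-bar resolution target scene
#'
#' Binary-amplitude three-bar groups (1:1 bar/gap duty cycle, like the
#' elements of a resolution test chart) at the requested bar widths, laid
#' out left to right on a single plane. Bar positions are recorded for FWHM
#' measurement.
#'
#' @param bar_widths Bar widths in um; each must be at least 2x the pitch.
#' @param z Axial distance of the target plane (um).
#' @param shape Grid dims \code{c(ny, nx)}.
#' @param pitch High-res pitch in um.
#' @param noise_sigma Passed to the scene.
#' @param seed Scene seed.
#' @return A \code{scene_spec} with attribute \code{"bars"}: a data frame of
#'   group, bar index and x span (um) per bar.
#' @export
make_bar_target <- function(bar_widths, z, shape = c(256L, 256L),
                            pitch = 1.67 / 6, noise_sigma = 0, seed = 1L) {
  if (any(bar_widths < 2 * pitch))
    stop("bar widths below 2x the grid pitch are not sampleable",
         call. = FALSE)
  shape <- as.integer(shape)
  ny <- shape[1L]; nx <- shape[2L]
  t <- matrix(1 + 0i, ny, nx)
  xs <- (seq_len(nx) - 0.5) * pitch
  bar_h <- 0.6 * ny * pitch
  y0 <- (ny * pitch - bar_h) / 2
  rows <- xs_y <- (seq_len(ny) - 0.5) * pitch
  row_in <- rows >= y0 & rows <= y0 + bar_h
  bars <- list()
  x <- 2 * max(bar_widths)
  for (g in seq_along(bar_widths)) {
    w <- bar_widths[g]
    for (b in 1:3) {
      x0 <- x; x1 <- x + w
      if (x1 > nx * pitch - w)
        stop("bar groups exceed the grid; enlarge the grid or drop widths",
             call. = FALSE)
      col_in <- xs >= x0 & xs < x1
      t[row_in, col_in] <- 0 + 0i
      bars[[length(bars) + 1L]] <- data.frame(group = g, bar = b,
                                              x0 = x0, x1 = x1, width = w)
      x <- x1 + w                       # 1:1 gap
    }
    x <- x + 2 * w                      # inter-group spacing
  }
  sc <- scene_spec(list(list(z = z, t = t)), pitch,
                   noise_sigma = noise_sigma, seed = seed)
  attr(sc, "bars") <- do.call(rbind, bars)
  sc
}

#' Render the detector hologram of a scene
#'
#' Multi-slice forward model: a unit plane wave traverses the scene planes
#' in z order (farthest from the detector first), is multiplied by each
#' plane's transmission with angular-spectrum propagation between planes,
#' and propagates the final distance to the detector. Returns the intensity
#' \code{|U|^2} with optional seeded Gaussian noise; the noiseless complex
#' detector field is attached as attribute \code{"field"}.
#'
#' @param scene A \code{scene_spec}.
#' @param config An \code{optical_config} (supplies the wavelength).
#' @param z_shift Extra detector offset in um (> 0 moves the detector away
#'   from the sample; used for multi-height acquisition).
#' @param noise_sigma Noise level override (default: the scene's).
#' @param seed Seed override (default: the scene's).
#' @return Intensity matrix with attributes \code{pitch} and \code{field}.
#' @export
render_hologram <- function(scene, config, z_shift = 0,
                            noise_sigma = scene$noise_sigma,
                            seed = scene$seed) {
  stopifnot(inherits(scene, "scene_spec"), inherits(config, "optical_config"))
  d <- vapply(scene$planes, function(p) p$z + z_shift, numeric(1L))
  if (any(d <= 0))
    stop("scene plane lies beyond the detector (nonpositive distance)",
         call. = FALSE)
  ord <- order(d, decreasing = TRUE)
  u <- complex_field(matrix(1 + 0i, scene$shape[1L], scene$shape[2L]),
                     scene$pitch, config$wavelength)
  for (i in seq_along(ord)) {
    u$data <- u$data * scene$planes[[ord[i]]]$t
    step <- if (i < length(ord)) d[ord[i]] - d[ord[i + 1L]] else d[ord[i]]
    u <- propagate(u, step)
  }
  intensity <- Mod(u$data)^2
  if (noise_sigma > 0) {
    intensity <- with_seed(seed, {
      intensity + noise_sigma * mean(intensity) *
        matrix(stats::rnorm(length(intensity)), nrow(intensity))
    })
    intensity <- pmax(intensity, 0)
  }
  attr(intensity, "pitch") <- scene$pitch
  attr(intensity, "field") <- u
  intensity
}

# circular sub-pixel shift of an image by (sx, sy) in pixels, implemented in
# the Fourier domain (exact for band-limited images; exact integer shift
# otherwise): S[m] = G[m + s].
fourier_shift <- function(img, sx, sy) {
  ny <- nrow(img); nx <- ncol(img)
  fy <- fft_freq(ny, 1); fx <- fft_freq(nx, 1)
  ph <- exp(2i * pi * (outer(fy * sy, rep(1, nx)) +
                       outer(rep(1, ny), fx * sx)))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE) / (ny * nx))
}

# box-average an image into k x k blocks (detector pixel integration)
box_bin <- function(img, k) {
  ny <- nrow(img); nx <- ncol(img)
  a <- array(img, c(k, ny %/% k, nx))
  s1 <- colSums(a)                               # (ny/k) x nx
  b <- array(t(s1), c(k, nx %/% k, ny %/% k))
  t(colSums(b)) / k^2
}

#' Acquire a sub-pixel-shifted low-resolution stack
#'
#' Emulates the motorized-stage acquisition: for each shift of the k x k
#' grid, the high-resolution intensity is laterally shifted by that
#' sub-pixel amount (Fourier-domain, circular) and box-averaged over k x k
#' blocks to the detector pitch. Shifts are recorded exactly; optional
#' per-frame Gaussian noise is seeded.
#'
#' @param highres Nonnegative high-resolution intensity matrix; its dims
#'   must be divisible by the upsampling factor.
#' @param config An \code{optical_config} (supplies k and the pitches).
#' @param seed Integer seed for the per-frame noise.
#' @param noise_sigma Per-frame noise as a fraction of the mean (default 0).
#' @param height_id Integer tag stored on the stack.
#' @return A \code{lowres_stack} of k^2 frames at the detector pitch.
#' @export
acquire_lowres_stack <- function(highres, config, seed = 1L,
                                 noise_sigma = 0, height_id = 1L) {
  stopifnot(inherits(config, "optical_config"))
  k <- config$upsample_factor
  ny <- nrow(highres); nx <- ncol(highres)
  if (ny %% k != 0L || nx %% k != 0L)
    stop(sprintf("grid dims (%d, %d) not divisible by factor %d; crop to (%d, %d)",
                 ny, nx, k, (ny %/% k) * k, (nx %/% k) * k), call. = FALSE)
  hp <- highres_pitch(config)
  sh <- grid_shifts(k, config$pixel_pitch)
  frames <- with_seed(seed, {
    lapply(seq_len(nrow(sh)), function(m) {
      s <- fourier_shift(highres, sh[m, 1L] / hp, sh[m, 2L] / hp)
      f <- box_bin(pmax(s, 0), k)
      if (noise_sigma > 0)
        f <- pmax(f + noise_sigma * mean(f) *
                    matrix(stats::rnorm(length(f)), nrow(f)), 0)
      f
    })
  })
  lowres_stack(frames, sh, config$pixel_pitch, height_id = height_id)
}

#' Acquire a full multi-height, sub-pixel-shifted data set
#'
#' Renders the scene at each detector height (the first entry of
#' \code{z_list} is the base position; later entries move the detector
#' away), produces one \code{lowres_stack} per height, and returns the
#' noiseless complex detector fields as ground truth for testing.
#'
#' @param scene A \code{scene_spec}.
#' @param config An \code{optical_config}.
#' @param z_list Strictly increasing detector heights in um (>= 2 entries);
#'   scene plane z values are distances to the detector at \code{z_list[1]}.
#' @param seed Master seed; each height draws its noise from an offset
#'   substream.
#' @return A list: \code{stacks} (list of \code{lowres_stack}),
#'   \code{z_list}, \code{gt_fields} (list of noiseless
#'   \code{complex_field}s at the detector), and \code{pitch}.
#' @export
acquire_multiheight <- function(scene, config, z_list, seed = 1L) {
  if (length(z_list) < 2L || any(diff(z_list) <= 0))
    stop("`z_list` must be >= 2 strictly increasing heights", call. = FALSE)
  offsets <- z_list - z_list[1L]
  out <- lapply(seq_along(z_list), function(j) {
    holo <- render_hologram(scene, config, z_shift = offsets[j],
                            noise_sigma = 0)
    stack <- acquire_lowres_stack(holo, config, seed = seed + 101L * j,
                                  noise_sigma = scene$noise_sigma,
                                  height_id = j)
    list(stack = stack, field = attr(holo, "field"))
  })
  list(stacks = lapply(out, `[[`, "stack"),
       z_list = z_list,
       gt_fields = lapply(out, `[[`, "field"),
       pitch = scene$pitch)
}

#' Pixel-super-resolve every height of a multi-height acquisition
#'
#' Convenience wrapper: runs \code{\link{synthesize_highres}} on each
#' height's stack and assembles the result into a \code{multiheight_set}
#' ready for \code{\link{recover_phase}}.
#'
#' @param acq Result of \code{\link{acquire_multiheight}}.
#' @param config An \code{optical_config}.
#' @param deblur,reg Passed to \code{\link{synthesize_highres}}.
#' @return A \code{multiheight_set}.
#' @export
psr_multiheight <- function(acq, config, deblur = FALSE, reg = 1e-3) {
  holos <- lapply(acq$stacks, synthesize_highres,
                  upsample_factor = config$upsample_factor,
                  deblur = deblur, reg = reg)
  holos <- lapply(holos, function(h) { attributes(h) <- list(dim = dim(h)); h })
  multiheight_set(holos, acq$z_list, pitch = highres_pitch(config),
                  wavelength = config$wavelength)
}
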
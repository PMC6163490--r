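# Shared fixtures, built in code and memoised so expensive simulations run
# once per test session.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# band-limited random complex field (restricted to the propagating band)
bl_field <- function(n = 64, pitch = 0.278, wavelength = 0.532, seed = 1) {
  set.seed(seed)
  raw <- matrix(stats::rnorm(n * n), n) + 1i * matrix(stats::rnorm(n * n), n)
  f <- complex_field(raw, pitch, wavelength)
  holovol:::band_limit(f)
}

# low-pass an image to spatial frequencies below fc (cycles/um)
lowpass_img <- function(img, pitch, fc) {
  n1 <- nrow(img); n2 <- ncol(img)
  fy <- holovol:::fft_freq(n1, pitch)
  fx <- holovol:::fft_freq(n2, pitch)
  mask <- outer(fy^2, fx^2, `+`) <= fc^2
  Re(stats::fft(stats::fft(img) * mask, inverse = TRUE) / (n1 * n2))
}

# dilated disk support mask for a bead scene (radius multiplier `dilate`)
bead_support <- function(scene, dilate = 5) {
  centers <- attr(scene, "centers")
  hp <- scene$pitch
  ny <- scene$shape[1L]; nx <- scene$shape[2L]
  xs <- (seq_len(nx) - 0.5) * hp
  ys <- (seq_len(ny) - 0.5) * hp
  support <- matrix(FALSE, ny, nx)
  r <- dilate * 0.5  # beads in fixtures are 1 um diameter
  for (b in seq_len(nrow(centers))) {
    support <- support |
      (outer((ys - centers[b, 2L])^2, (xs - centers[b, 1L])^2, `+`) <= r^2)
  }
  support
}

# six-height noiseless acquisition of an off-center bead scene (single
# plane at the nominal focus), PSR'd and phase-recovered at the defaults
recovery_fixture <- function() memo_fixture("recovery", {
  cfg <- optical_config()
  hp <- highres_pitch(cfg)
  scene <- make_beads(3, 1.0, 721, shape = c(252L, 252L), pitch = hp,
                      seed = 7)
  acq <- acquire_multiheight(scene, cfg, z_list = 721 + 20 * (0:5), seed = 7)
  mh <- psr_multiheight(acq, cfg)
  rec <- suppressWarnings(recover_phase(mh))
  rec1 <- suppressWarnings(recover_phase(mh, max_iter = 1L))
  list(cfg = cfg, hp = hp, scene = scene, acq = acq, mh = mh,
       rec = rec, rec1 = rec1)
})

# two beads on different planes (700 and 760 um), recovered hologram,
# background-subtracted measured volume, simulated PSF and Gold result
twobead_fixture <- function() memo_fixture("twobead", {
  cfg <- optical_config()
  hp <- highres_pitch(cfg)
  scene <- make_beads(2, 1.0, c(700, 760), shape = c(252L, 252L),
                      pitch = hp, seed = 11)
  acq <- acquire_multiheight(scene, cfg, z_list = 721 + 20 * (0:5),
                             seed = 11)
  mh <- psr_multiheight(acq, cfg)
  rec <- suppressWarnings(recover_phase(mh))
  z_values <- seq(640, 820, by = 7.5)   # 25 planes spanning both beads
  measured <- build_measured_volume(rec$field, z_values,
                                    background = "mean")
  psf <- simulate_psf(cfg, c(252L, 252L), z_values, pitch = hp)
  gold <- gold_deconvolve(measured, psf, beta = 0.001, n_iter = 20L)
  centers <- attr(scene, "centers")
  voxels <- cbind(row = round(centers[, "y"] / hp + 0.5),
                  col = round(centers[, "x"] / hp + 0.5),
                  z = centers[, "plane"])
  list(cfg = cfg, hp = hp, scene = scene, rec = rec,
       z_values = z_values, measured = measured, psf = psf, gold = gold,
       bead_z = c(700, 760), voxels = voxels)
})

# fraction of axial-profile energy outside +/- `halo` planes of the peak
offfocus_fraction <- function(profile, halo = 2L) {
  ipk <- which.max(profile)
  idx <- max(1L, ipk - halo):min(length(profile), ipk + halo)
  1 - sum(profile[idx]) / sum(profile)
}
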
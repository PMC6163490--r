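test_that("volume construction enforces the grid invariants", {
  d <- array(1, c(4, 4, 3))
  expect_error(volume3d(d, 1, c(1, 2, 4)), "uniform")
  expect_error(volume3d(d, 1, c(3, 2, 1)), "increasing")
  expect_error(volume3d(-d, 1, 1:3), "nonnegative")
  expect_error(volume3d(d, 1, 1:2), "match")
  v <- volume3d(d, 0.278, 1:3)
  expect_s3_class(v, "volume3d")
})

test_that("a single-z measured volume equals one back-propagation", {
  f <- bl_field(32, seed = 5)
  v <- build_measured_volume(f, 150, mode = "complex")
  expect_equal(v$data[, , 1], propagate(f, -150)$data, tolerance = 1e-12)
})

test_that("the bead focus plane holds the global maximum of the scattered stack", {
  fx <- twobead_fixture()
  M <- fx$measured
  imax <- arrayInd(which.max(M$data), dim(M$data))
  # global max belongs to one of the two bead columns at its focal plane
  hit <- FALSE
  for (b in 1:2) {
    zi <- which.min(abs(fx$z_values - fx$bead_z[b]))
    if (abs(imax[1] - fx$voxels[b, "row"]) <= 4 &&
        abs(imax[2] - fx$voxels[b, "col"]) <= 4 &&
        abs(imax[3] - zi) <= 1) hit <- TRUE
  }
  expect_true(hit)
})

test_that("simulated PSF is centered, normalized, and axially peaked", {
  cfg <- optical_config()
  zv <- seq(680, 760, by = 10)
  psf <- simulate_psf(cfg, c(64L, 64L), zv)
  d <- dim(psf$data)
  ctr <- c(33L, 33L, 5L)   # floor(n/2)+1 on every axis
  expect_equal(sum(Mod(psf$data)), 1, tolerance = 1e-12)
  pk <- arrayInd(which.max(Mod(psf$data)), d)
  expect_equal(as.integer(pk), ctr)
  ax <- Mod(psf$data[ctr[1], ctr[2], ])
  expect_gt(ax[ctr[3]], ax[1])
  expect_gt(ax[ctr[3]], ax[d[3]])
  # center plane lateral max at the center voxel
  plane <- Mod(psf$data[, , ctr[3]])
  expect_equal(as.integer(arrayInd(which.max(plane), dim(plane))), ctr[1:2])
})

test_that("FFT convolution matches the direct triple-sum oracle", {
  set.seed(4)
  d <- c(8L, 8L, 4L)
  O <- array(stats::runif(prod(d)), d)
  P <- array(stats::runif(prod(d)), d)
  P <- P / sum(P)
  out <- convolve3d(volume3d(O, 1, 1:4), volume3d(P, 1, 1:4))

  # direct sum with the kernel origin at the grid center, circular indexing
  ctr <- c(5L, 5L, 3L)
  ref <- array(0, d)
  for (i in 1:8) for (j in 1:8) for (k in 1:4) {
    s <- 0
    for (a in 1:8) for (b in 1:8) for (cc in 1:4) {
      ii <- ((i - a + ctr[1] - 1) %% 8) + 1
      jj <- ((j - b + ctr[2] - 1) %% 8) + 1
      kk <- ((k - cc + ctr[3] - 1) %% 4) + 1
      s <- s + O[a, b, cc] * P[ii, jj, kk]
    }
    ref[i, j, k] <- s
  }
  expect_lt(holovol:::rel_l2(out$data, ref), 1e-10)
})

test_that("convolution identities: delta kernel, constant preservation, guards", {
  set.seed(6)
  d <- c(8L, 8L, 4L)
  O <- array(stats::runif(prod(d)), d)
  vo <- volume3d(O, 1, 1:4)
  delta <- array(0, d); delta[5, 5, 3] <- 1
  vd <- volume3d(delta, 1, 1:4)
  expect_lt(holovol:::rel_l2(convolve3d(vo, vd)$data, O), 1e-12)

  P <- array(stats::runif(prod(d)), d); P <- P / sum(P)
  ones <- volume3d(array(1, d), 1, 1:4)
  expect_lt(max(abs(convolve3d(ones, volume3d(P, 1, 1:4))$data - 1)), 1e-10)

  expect_error(convolve3d(vo, volume3d(array(1, c(4, 4, 4)), 1, 1:4)),
               "shapes")
})

test_that("Wiener deconvolution inverts a noiseless forward convolution", {
  set.seed(8)
  d <- c(16L, 16L, 8L)
  O <- array(stats::runif(prod(d)), d)
  # well-conditioned kernel: dominant central delta plus a weak smooth part
  P <- array(stats::runif(prod(d)) / prod(d), d)
  P[9, 9, 5] <- P[9, 9, 5] + 10
  P <- P / sum(P)
  vo <- volume3d(O, 1, 1:8); vp <- volume3d(P, 1, 1:8)
  M <- convolve3d(vo, vp)
  R <- wiener_deconvolve(M, vp, beta = 1e-12)
  expect_lt(holovol:::rel_l2(R$data, O), 1e-6)

  # delta kernel: exact 1/(1+beta) scaling
  delta <- array(0, d); delta[9, 9, 5] <- 1
  vd <- volume3d(delta, 1, 1:8)
  R2 <- wiener_deconvolve(M, vd, beta = 0.25)
  expect_lt(holovol:::rel_l2(R2$data, M$data / 1.25), 1e-10)

  # beta = 0 with spectral nulls must refuse
  box <- array(1 / prod(d), d)
  expect_error(wiener_deconvolve(M, volume3d(box, 1, 1:8), beta = 0),
               "beta")
})

test_that("min/max matching is affine, idempotent and phase-preserving", {
  set.seed(10)
  d <- c(6L, 6L, 3L)
  ref <- volume3d(array(stats::runif(prod(d), 0.2, 2), d), 1, 1:3)
  vol <- volume3d(array(stats::runif(prod(d), 5, 9), d), 1, 1:3)
  m1 <- match_minmax(vol, ref)
  expect_equal(min(m1$data), min(ref$data), tolerance = 1e-12)
  expect_equal(max(m1$data), max(ref$data), tolerance = 1e-12)
  m2 <- match_minmax(m1, ref)
  expect_lt(max(abs(m2$data - m1$data)), 1e-12)

  z <- array(stats::runif(prod(d)) * exp(2i * pi *
                                         stats::runif(prod(d))), d)
  vz <- volume3d(z, 1, 1:3, mode = "complex")
  mz <- match_minmax(vz, ref)
  expect_equal(Arg(mz$data)[Mod(z) > 0], Arg(z)[Mod(z) > 0],
               tolerance = 1e-10)
})

test_that("Gold iteration: delta-kernel fixed point and nonnegativity", {
  set.seed(12)
  d <- c(8L, 8L, 4L)
  M <- volume3d(array(stats::runif(prod(d), 0.5, 1.5), d), 1, 1:4)
  delta <- array(0, d); delta[5, 5, 3] <- 1
  vd <- volume3d(delta, 1, 1:4)
  beta <- 1e-3
  g <- gold_deconvolve(M, vd, beta = beta, n_iter = 1L)
  # with a delta kernel the reblurred volume equals M, so the update
  # multiplier is |M|^2 / (|M|^2 + beta)
  tol <- beta / min(M$data)^2
  expect_lt(max(abs(g$volume$data - M$data) / M$data), tol)
  expect_lt(g$residuals[1], 1e-12)

  P <- array(stats::runif(prod(d)), d); P <- P / sum(P)
  g2 <- gold_deconvolve(M, volume3d(P, 1, 1:4), beta = 1e-3, n_iter = 5L)
  expect_true(all(g2$volume$data >= 0))
  expect_length(g2$residuals, 5L)
  expect_true(all(is.finite(g2$residuals)))
  expect_warning(gold_deconvolve(M, vd, n_iter = 201L), "over-fit")
})

test_that("Gold deconvolution confines beads axially and cuts background", {
  fx <- twobead_fixture()
  for (b in 1:2) {
    pm <- axial_profile(fx$measured, fx$voxels[b, "row"], fx$voxels[b, "col"])
    pg <- axial_profile(fx$gold$volume, fx$voxels[b, "row"],
                        fx$voxels[b, "col"])
    expect_lt(fwhm(pg, fx$z_values), fwhm(pm, fx$z_values))
    expect_lt(offfocus_fraction(pg), offfocus_fraction(pm))
  }
})
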
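test_that("bead scenes are deterministic, sparse and correctly sampled", {
  hp <- 1.67 / 6
  s1 <- make_beads(4, 1.0, c(700, 760), shape = c(128L, 128L), pitch = hp,
                   seed = 21)
  s2 <- make_beads(4, 1.0, c(700, 760), shape = c(128L, 128L), pitch = hp,
                   seed = 21)
  s3 <- make_beads(4, 1.0, c(700, 760), shape = c(128L, 128L), pitch = hp,
                   seed = 22)
  expect_identical(attr(s1, "centers"), attr(s2, "centers"))
  expect_false(identical(attr(s1, "centers"), attr(s3, "centers")))

  # minimum separation 5 diameters
  ctr <- attr(s1, "centers")
  dmat <- as.matrix(stats::dist(ctr[, c("x", "y")]))
  expect_true(all(dmat[upper.tri(dmat)] >= 5))

  # round-robin plane assignment
  expect_equal(unname(ctr[, "plane"]), c(1, 2, 1, 2))

  # empty scene: unit transmission
  s0 <- make_beads(0, 1.0, 700, shape = c(32L, 32L), pitch = hp)
  expect_true(all(s0$planes[[1]]$t == 1))

  # a 1 um bead spans 4 high-res pixels across
  sb <- make_beads(1, 1.0, 700, shape = c(64L, 64L), pitch = hp, seed = 5)
  t <- sb$planes[[1]]$t
  covered <- Mod(t) < 1
  expect_equal(max(rowSums(covered)), 4)
  expect_equal(max(colSums(covered)), 4)

  # over-packed demand errors with the achievable count
  expect_error(make_beads(500, 1.0, 700, shape = c(64L, 64L), pitch = hp,
                          seed = 1), "beads")
})

test_that("bar targets have the stated geometry", {
  hp <- 1.67 / 6
  sc <- make_bar_target(3, z = 800, shape = c(256L, 256L), pitch = hp)
  bars <- attr(sc, "bars")
  expect_equal(nrow(bars), 3L)
  expect_equal(unique(bars$x1 - bars$x0), 3)
  # gaps equal widths
  expect_equal(bars$x0[-1] - bars$x1[-3], c(3, 3))

  # FWHM of a ground-truth bar dip equals the width within one pixel
  amp <- 1 - Mod(sc$planes[[1]]$t)   # bars bright in this view
  mid <- round(nrow(amp) / 2)
  prof <- amp[mid, ]
  xs <- (seq_len(ncol(amp)) - 0.5) * hp
  in_bar <- xs >= bars$x0[1] - 3 & xs <= bars$x1[1] + 3
  expect_lt(abs(fwhm(prof[in_bar], xs[in_bar]) - 3), hp + 1e-9)

  expect_error(make_bar_target(0.3, z = 800, pitch = hp), "sampleable")
})

test_that("hologram rendering obeys passivity and refocuses beads", {
  cfg <- optical_config()
  hp <- highres_pitch(cfg)

  empty <- make_beads(0, 1.0, 700, shape = c(48L, 48L), pitch = hp)
  h0 <- render_hologram(empty, cfg)
  expect_lt(max(abs(h0 - 1)), 1e-12)

  sc <- make_beads(1, 1.0, 500, shape = c(96L, 96L), pitch = hp, seed = 3)
  holo <- render_hologram(sc, cfg)
  expect_lte(mean(holo), 1 + 1e-9)
  # back-propagation restores a dark disk at the bead
  f <- complex_field(sqrt(holo), hp, cfg$wavelength)
  bp <- Mod(propagate(f, -500)$data)^2
  ctr <- attr(sc, "centers")
  i <- round(ctr[1, "y"] / hp + 0.5); j <- round(ctr[1, "x"] / hp + 0.5)
  expect_lt(bp[i, j], 0.5 * stats::median(bp))

  expect_error(render_hologram(sc, cfg, z_shift = -600), "detector")
})

test_that("seeded noise is reproducible and scales with the requested sigma", {
  cfg <- optical_config()
  hp <- highres_pitch(cfg)
  sc <- make_beads(1, 1.0, 500, shape = c(48L, 48L), pitch = hp, seed = 3,
                   noise_sigma = 0.02)
  a <- render_hologram(sc, cfg)
  b <- render_hologram(sc, cfg)
  expect_identical(a, b)
  clean <- render_hologram(sc, cfg, noise_sigma = 0)
  resid <- a - clean
  expect_gt(stats::sd(resid), 0.01)
  expect_lt(stats::sd(resid), 0.04)
})

test_that("low-resolution acquisition bins to detector pitch with exact shifts", {
  cfg <- optical_config()
  set.seed(2)
  G <- matrix(stats::runif(48 * 48), 48)
  st <- acquire_lowres_stack(G, cfg, seed = 1)
  expect_length(st$frames, 36L)
  expect_equal(dim(st$frames[[1]]), c(8L, 8L))
  expect_equal(st$pitch, 1.67)
  expect_equal(st$shifts, grid_shifts(6, 1.67))

  cfg1 <- optical_config(upsample_factor = 1)
  st1 <- acquire_lowres_stack(G, cfg1, seed = 1)
  expect_length(st1$frames, 1L)
  expect_equal(st1$frames[[1]], G, tolerance = 1e-12)

  expect_error(acquire_lowres_stack(matrix(1, 50, 48), cfg, seed = 1),
               "crop to \\(48, 48\\)")
})

test_that("multi-height acquisition is consistent free-space propagation", {
  cfg <- optical_config()
  hp <- highres_pitch(cfg)
  sc <- make_beads(2, 1.0, c(700, 760), shape = c(96L, 96L), pitch = hp,
                   seed = 9)
  z_list <- 761 + 20 * (0:2)
  acq <- acquire_multiheight(sc, cfg, z_list, seed = 4)
  expect_length(acq$stacks, 3L)
  expect_equal(sum(lengths(lapply(acq$stacks, `[[`, "frames"))), 108L)

  # ground-truth fields chain by free-space propagation between heights
  for (i in 1:2) {
    stepped <- propagate(acq$gt_fields[[i]], z_list[i + 1] - z_list[i])
    expect_lt(holovol:::rel_l2(stepped$data, acq$gt_fields[[i + 1]]$data),
              1e-10)
  }

  acq2 <- acquire_multiheight(sc, cfg, z_list, seed = 4)
  expect_identical(acq$stacks[[1]]$frames, acq2$stacks[[1]]$frames)

  expect_error(acquire_multiheight(sc, cfg, 700, seed = 1), "increasing")
})

test_that("pixel super-resolution resolves finer bars than the raw pitch", {
  cfg <- optical_config()
  hp <- highres_pitch(cfg)
  # 1.2 um bars: beyond the 1.67 um detector sampling, within the 6x grid
  sc <- make_bar_target(1.2, z = 400, shape = c(144L, 144L), pitch = hp)
  bars <- attr(sc, "bars")
  acq <- acquire_multiheight(sc, cfg, z_list = c(400, 420), seed = 2)
  mh <- psr_multiheight(acq, cfg)

  hr <- propagate(complex_field(sqrt(mh$holograms[[1]]), hp,
                                cfg$wavelength), -400)
  lr_int <- acq$stacks[[1]]$frames[[1]]
  lr <- propagate(complex_field(sqrt(lr_int), 1.67, cfg$wavelength), -400)

  # modulation strength at the bar fundamental frequency over the group
  f0 <- 1 / (2 * 1.2)
  modulation <- function(field, pitch) {
    amp <- Mod(field$data)
    ys <- (seq_len(nrow(amp)) - 0.5) * pitch
    rows <- ys > 0.25 * max(ys) & ys < 0.75 * max(ys)
    prof <- colMeans(amp[rows, , drop = FALSE])
    xs <- (seq_len(ncol(amp)) - 0.5) * pitch
    span <- xs >= bars$x0[1] - 1.2 & xs <= bars$x1[3] + 1.2
    x <- xs[span]; y <- prof[span] - mean(prof[span])
    Mod(sum(y * exp(-2i * pi * f0 * x))) / length(y)
  }
  expect_gt(modulation(hr, hp), modulation(lr, 1.67))
})
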
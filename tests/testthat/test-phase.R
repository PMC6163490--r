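test_that("sharpness is zero for constants and linear in edge height", {
  expect_equal(sharpness(matrix(3.7, 16, 16)), 0)

  step <- function(h) {
    img <- matrix(0, 32, 32)
    img[, 17:32] <- h
    img
  }
  s1 <- sharpness(step(1))
  s2 <- sharpness(step(2))
  expect_gt(s1, 0)
  expect_lt(abs(s2 - 2 * s1), 1e-12)
  # additive-constant invariance
  expect_equal(sharpness(step(1) + 5), s1, tolerance = 1e-12)
  expect_error(sharpness(matrix(1, 2, 2)), "3 x 3")
})

test_that("sharpness of bar-target back-propagations peaks at the focus plane", {
  cfg <- optical_config()
  hp <- highres_pitch(cfg)
  scene <- make_bar_target(3, z = 800, shape = c(128L, 128L), pitch = hp)
  holo <- render_hologram(scene, cfg)
  f <- complex_field(sqrt(holo), hp, cfg$wavelength)
  dz <- 20
  score <- function(z) sharpness(Mod(propagate(f, -z)$data))
  at_focus <- score(800)
  expect_gt(at_focus, score(800 - 3 * dz))
  expect_gt(at_focus, score(800 + 3 * dz))
})

test_that("golden-section autofocus agrees with a fine brute-force scan", {
  cfg <- optical_config()
  hp <- highres_pitch(cfg)
  scene <- make_bar_target(3, z = 800, shape = c(192L, 192L), pitch = hp)
  holo <- render_hologram(scene, cfg)
  f <- complex_field(sqrt(holo), hp, cfg$wavelength)

  z_gold <- suppressWarnings(autofocus(f, 500, 1100, tol = 1))

  # independent oracle: 0.5 um brute-force scan around the nominal focus
  z_scan <- seq(790, 810, by = 0.5)
  s_scan <- vapply(z_scan,
                   function(z) sharpness(Mod(propagate(f, -z)$data)),
                   numeric(1))
  z_brute <- z_scan[which.max(s_scan)]

  expect_lt(abs(z_gold - 800), 5)
  expect_lt(abs(z_gold - z_brute), 5)

  expect_equal(autofocus(f, 700, 700), 700)
  expect_error(autofocus(holo, 500, 1100), "pitch")
  expect_error(autofocus(f, 900, 500), "z_lo")
})

test_that("multi-height set construction enforces the z geometry", {
  h <- list(matrix(1, 8, 8), matrix(1, 8, 8))
  expect_error(multiheight_set(h[1], 700, 0.278, 0.532), "at least 2")
  expect_error(multiheight_set(h, c(740, 720), 0.278, 0.532), "increasing")
  expect_error(multiheight_set(h, c(720, 720.5), 0.278, 0.532),
               "unreliable")
  set <- multiheight_set(h, c(720, 740), 0.278, 0.532)
  expect_s3_class(set, "multiheight_set")
})

test_that("phase recovery improves data fidelity and reports convergence", {
  fx <- recovery_fixture()
  rep <- fx$rec$report
  expect_length(rep$residual_history, rep$iterations_run)
  expect_true(all(is.finite(rep$residual_history)))
  expect_equal(rep$converged,
               utils::tail(rep$residual_history, 1) < 1e-4)
  expect_lte(utils::tail(rep$residual_history, 1),
             rep$residual_history[1])

  fid_final <- amplitude_residual(fx$rec$field, fx$mh)
  fid_iter1 <- amplitude_residual(fx$rec1$field, fx$mh)
  expect_lte(fid_final, fid_iter1)
})

test_that("phase recovery is deterministic and falls back to nominal heights", {
  fx <- recovery_fixture()
  again <- suppressWarnings(recover_phase(fx$mh))
  expect_identical(again$field$data, fx$rec$field$data)
  expect_identical(again$report$residual_history,
                   fx$rec$report$residual_history)
  expect_warning(recover_phase(fx$mh, max_iter = 1L), "nominal")
})

test_that("multi-height recovery suppresses the twin image vs a single height", {
  fx <- recovery_fixture()
  z0 <- 721
  refoc_multi <- propagate(fx$rec$field, -z0)
  single <- complex_field(sqrt(fx$mh$holograms[[1]]), fx$hp,
                          fx$cfg$wavelength)
  refoc_single <- propagate(single, -z0)

  bg <- !bead_support(fx$scene, dilate = 5)
  artifact <- function(f) sum((Mod(f$data)[bg] - 1)^2)
  expect_lte(artifact(refoc_multi), 0.5 * artifact(refoc_single))
})

test_that("autofocus refinement recovers the true height offsets", {
  cfg <- optical_config()
  hp <- highres_pitch(cfg)
  scene <- make_bar_target(3, z = 700, shape = c(126L, 126L), pitch = hp)
  acq <- acquire_multiheight(scene, cfg, z_list = c(700, 720, 740), seed = 2)
  mh <- psr_multiheight(acq, cfg)
  mh <- suppressWarnings(refine_heights(mh, window = 15, tol = 1))
  expect_length(mh$z_refined, 3L)
  expect_true(all(abs(mh$z_refined - c(700, 720, 740)) < 5))
})
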
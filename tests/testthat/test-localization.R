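test_that("frame averaging is a sliding mean with the stated length", {
  set.seed(1)
  mv <- array(stats::rnorm(8 * 8 * 100, 50, 5), c(8, 8, 100))
  avg <- averageFrames(mv, 3L)
  expect_identical(dim(avg)[3], 98L)
  expect_equal(avg[, , 10], (mv[, , 10] + mv[, , 11] + mv[, , 12]) / 3)
  cst <- array(7, c(4, 4, 10))
  expect_equal(averageFrames(cst, 3L)[, , 1], matrix(7, 4, 4))
  expect_error(averageFrames(cst, 11L), "exceeds")
  # white-noise variance reduced by the window factor
  big <- array(stats::rnorm(6 * 6 * 3000), c(6, 6, 3000))
  v <- stats::var(averageFrames(big, 3L)[3, 3, seq(1, 2998, by = 3)])
  expect_lt(abs(v - 1 / 3), 0.05)
})

test_that("candidate detection finds emitters and nothing else", {
  set.seed(2)
  blank <- matrix(stats::rnorm(900, 10, 1), 30, 30)
  expect_identical(nrow(detectCandidates(blank)), 0L)
  mv <- renderMovie(staticTrack(1), defaultCam(), fov = c(30L, 30L),
                    seed = 3)$movie
  seeds <- detectCandidates(mv[, , 1])
  expect_identical(nrow(seeds), 1L)
  expect_lt(sqrt((seeds$col - 16)^2 + (seeds$row - 15)^2), 2.1)
  # two emitters 20 px apart
  fr <- mv[, , 1]
  fr2 <- matrix(stats::rnorm(900, 10, 1), 30, 30)
  fr2[, 1:10] <- fr[, 11:20]; fr2[, 21:30] <- fr[, 11:20]
  expect_identical(nrow(detectCandidates(fr2)), 2L)
})

test_that("noise-free asymmetric Gaussian fits recover generating parameters", {
  cases <- list(c(x = 12.30, y = 9.60, sMaj = 3.0, sMin = 1.2,
                  th = 30 * pi / 180),
                c(x = 13.75, y = 12.20, sMaj = 2.2, sMin = 1.8,
                  th = 140 * pi / 180),
                c(x = 11.10, y = 14.40, sMaj = 4.0, sMin = 1.0,
                  th = 95 * pi / 180))
  for (cs in cases) {
    fr <- ecsnano:::.asymGauss(1:25, 1:25, cs["x"], cs["y"], cs["sMaj"],
                               cs["sMin"], cs["th"], 100, 5)
    f <- fitAsymmetricGaussian(fr, round(cs["y"]), round(cs["x"]),
                               fitWindow = 15, pixelSizeNm = 1)
    expect_true(f$accepted)
    expect_lt(abs(f$x_px - cs["x"]), 1e-3)
    expect_lt(abs(f$y_px - cs["y"]), 1e-3)
    expect_lt(abs(f$smaj_nm - cs["sMaj"]), 1e-3)
    expect_lt(abs(f$smin_nm - cs["sMin"]), 1e-3)
    expect_lt(abs(f$theta_rad - cs["th"]), 0.1 * pi / 180)
  }
})

test_that("circular spots give equal sigmas and any orientation", {
  fr <- ecsnano:::.asymGauss(1:21, 1:21, 10.5, 10.5, 2.0, 2.0, 0.7, 50, 2)
  f <- fitAsymmetricGaussian(fr, 10, 10, fitWindow = 15, pixelSizeNm = 1)
  expect_true(f$accepted)
  expect_lt(abs(f$smaj_nm - f$smin_nm), 1e-3)
  expect_gte(f$theta_rad, 0); expect_lt(f$theta_rad, pi)
})

test_that("fit is equivariant under integer-pixel translation", {
  fr <- ecsnano:::.asymGauss(1:40, 1:40, 15.3, 14.6, 3, 1.5, 1.0, 80, 5)
  f1 <- fitAsymmetricGaussian(fr, 15, 15, fitWindow = 15, pixelSizeNm = 1)
  shifted <- matrix(5, 40, 40)
  shifted[1:36 + 4, 1:34 + 6] <- fr[1:36, 1:34]
  f2 <- fitAsymmetricGaussian(shifted, 19, 21, fitWindow = 15,
                              pixelSizeNm = 1)
  expect_equal(f2$x_px, f1$x_px + 6, tolerance = 1e-6)
  expect_equal(f2$y_px, f1$y_px + 4, tolerance = 1e-6)
})

test_that("degenerate fit windows are rejected with reasons", {
  flat <- matrix(5, 30, 30)
  f <- fitAsymmetricGaussian(flat, 15, 15, fitWindow = 15, pixelSizeNm = 1)
  expect_false(f$accepted)
  expect_identical(f$reason, "flat_window")
  f2 <- fitAsymmetricGaussian(flat, 2, 2, fitWindow = 15, pixelSizeNm = 1)
  expect_identical(f2$reason, "window_outside_frame")
})

test_that("a full movie of a static emitter localizes tightly", {
  mv <- renderMovie(staticTrack(62), defaultCam(), fov = c(30L, 30L),
                    seed = 7)$movie
  locs <- localizeMovie(mv, pixelSizeNm = 100)
  acc <- locs[locs$accepted, ]
  expect_gte(nrow(acc), 57)                # >= 95% of 60 averaged frames
  # averaged frames carry ~3x the photons; orientation 0 puts the major
  # axis along x
  sMaj <- ecsnano:::.fwhmToSigma(sqrt(600^2 + 450^2))
  sMin <- ecsnano:::.fwhmToSigma(450)
  bx <- localizationBound(3e4, sMaj, 100, 10 / 3 + 1 / 3)
  by <- localizationBound(3e4, sMin, 100, 10 / 3 + 1 / 3)
  expect_lt(stats::sd(acc$x_nm), 2 * bx)
  expect_lt(stats::sd(acc$y_nm), 2 * by)
  # type invariants hold on everything accepted
  expect_true(all(acc$smaj_nm >= acc$smin_nm))
  expect_true(all(acc$smin_nm > 0))
  expect_true(all(acc$theta_rad >= 0 & acc$theta_rad < pi))
})

test_that("blank movies localize to an empty table without error", {
  set.seed(4)
  blank <- array(stats::rnorm(20 * 20 * 10, 10, 1), c(20, 20, 10))
  locs <- localizeMovie(blank, pixelSizeNm = 100)
  expect_identical(sum(locs$accepted), 0L)
})

test_that("localization is deterministic on identical input", {
  mv <- renderMovie(staticTrack(8), defaultCam(), fov = c(24L, 24L),
                    seed = 5)$movie
  expect_identical(localizeMovie(mv, 100), localizeMovie(mv, 100))
})

test_that("moving-emitter localization error stays below the in-water precision scale", {
  g <- generateGeometry(2, poolRadiusRange = c(200, 300),
                        domain = c(3000, 3000), gapRange = c(150, 250),
                        seed = 31)
  trk <- simulateWalker(g, 5e4, nSteps = 40, dt = 0.03, seed = 32)
  mv <- renderMovie(trk, defaultCam(), fov = c(30L, 30L), seed = 33)
  locs <- localizeMovie(mv$movie, pixelSizeNm = 100)
  acc <- locs[locs$accepted, ]
  truth <- mv$truth[acc$t_index, ]
  err <- sqrt((acc$x_nm - truth$x_nm)^2 + (acc$y_nm - truth$y_nm)^2)
  expect_lt(stats::median(err), 50)        # sub-50 nm median error
})
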
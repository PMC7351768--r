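test_that("geometry generation is deterministic and respects invariants", {
  g1 <- generateGeometry(4, seed = 11)
  g2 <- generateGeometry(4, seed = 11)
  expect_identical(g1@pools, g2@pools)
  expect_identical(g1@channels, g2@channels)
  g3 <- generateGeometry(4, seed = 12)
  expect_false(identical(g1@pools, g3@pools))
  # every channel endpoint inside a pool (also enforced by validity)
  expect_true(validObject(g1))
  # single pool: inside() is true exactly on the disc
  g <- generateGeometry(1, poolRadiusRange = c(100, 100), seed = 1)
  cx <- g@pools[1, "cx"]; cy <- g@pools[1, "cy"]
  expect_true(all(insideGeometry(g, cx + c(0, 99, -99), cy)))
  expect_false(any(insideGeometry(g, cx + c(101, 150), cy)))
})

test_that("generated geometry is connected on its raster", {
  g <- generateGeometry(5, seed = 3)
  res <- 10
  xs <- seq(0, g@domain[1], by = res)
  ys <- seq(0, g@domain[2], by = res)
  inside <- outer(ys, xs, function(y, x) insideGeometry(g, x, y)) * 1
  lab <- ecsnano:::.labelComponents(inside, 8L)
  expect_identical(max(lab), 1L)
})

test_that("walker reproduces free Brownian statistics", {
  trk <- simulateWalker(NULL, D = 1e6, nSteps = 1e5, dt = 0.030, seed = 42)
  p <- trackPositions(trk)
  dEst <- mean(rowSums(diff(p)^2)) / (4 * 0.030)
  expect_lt(abs(dEst / 1e6 - 1), 0.03)
})

test_that("degenerate walkers behave as contracted", {
  trk <- simulateWalker(NULL, D = 0, nSteps = 50, seed = 1,
                        start = c(10, 20))
  p <- trackPositions(trk)
  expect_true(all(p[, 1] == 10) && all(p[, 2] == 20))
  expect_error(simulateWalker(generateGeometry(1, seed = 1), 1e5, 10,
                              start = c(-1e5, -1e5)),
               "outside")
})

test_that("confined walker stays inside; channel confinement bounds variance", {
  g <- channelGeometry(50)
  trk <- simulateWalker(g, 3e5, nSteps = 2000, dt = 0.030, seed = 5,
                        start = c(4000, 0))
  p <- trackPositions(trk)
  expect_true(all(insideGeometry(g, p[, 1], p[, 2]) |
                  abs(signedDistance(g, p[, 1], p[, 2])) < 1e-6))
  expect_true(all(abs(p[, 2]) <= 25 + 1e-6))      # hard reflection bound
  expect_lt(stats::var(p[, 2]), 50^2 / 4)
})

test_that("walker occupancy of two pools is proportional to pool areas", {
  pools <- matrix(c(1000, 1000, 300, 2400, 1000, 150), 2, 3, byrow = TRUE,
                  dimnames = list(NULL, c("cx", "cy", "r")))
  ch <- matrix(c(1000, 1000, 2400, 1000, 80), 1, 5,
               dimnames = list(NULL, c("x1", "y1", "x2", "y2", "width")))
  g <- new("SceneGeometry", pools = pools, channels = ch,
           domain = c(3400, 2000), resolution = 5)
  trk <- simulateWalker(g, 1e6, nSteps = 6e4, dt = 0.030, seed = 8,
                        start = c(1000, 1000))
  p <- trackPositions(trk)
  d1 <- sqrt((p[, 1] - 1000)^2 + (p[, 2] - 1000)^2)
  d2 <- sqrt((p[, 1] - 2400)^2 + (p[, 2] - 1000)^2)
  in1 <- d1 <= 300 & d2 > 150
  in2 <- d2 <= 150 & d1 > 300
  # steps are serially correlated, so we compare proportions with a
  # tolerance rather than a nominal iid chi-square
  expect_lt(abs(sum(in2) / sum(in1) - (150 / 300)^2), 0.08)
})

test_that("movie rendering matches its forward model", {
  trk <- staticTrack(5)
  cam <- defaultCam()
  mv <- renderMovie(trk, cam, noise = FALSE, fov = c(30L, 30L))
  # zero noise, zero drift, static emitter: all frames identical
  for (f in 2:5) expect_identical(mv$movie[, , f], mv$movie[, , 1])
  # conservation: total = background * pixels + photon budget (FOV truncation
  # only; emitter is centred 15 px from every edge, > 4 sigma)
  tot <- sum(mv$movie[, , 1])
  expect_lt(abs(tot - (10 * 900 + 1e4)) / 1e4, 0.02)
  # injected drift is reported verbatim in the truth table
  dr <- cbind(seq_len(5) * 0.05, rep(0, 5)); dr <- sweep(dr, 2, dr[1, ])
  mv2 <- renderMovie(trk, cam, drift = dr, noise = FALSE, fov = c(30L, 30L))
  expect_identical(mv2$truth$drift_x_px, dr[, 1])
  # out-of-view emitter: frame is pure background, flagged
  far <- staticTrack(2, x = 1e6, y = 1e6)
  mv3 <- renderMovie(far, cam, noise = FALSE, fov = c(20L, 20L))
  expect_false(any(mv3$truth$visible))
  expect_true(all(mv3$movie == 10))
})

test_that("rendering with a seed is reproducible", {
  trk <- staticTrack(4)
  m1 <- renderMovie(trk, defaultCam(), seed = 9)$movie
  m2 <- renderMovie(trk, defaultCam(), seed = 9)$movie
  expect_identical(m1, m2)
})

test_that("EM-like masks hit the target fraction with exact truth", {
  res <- generateEcsMask(0.17, mode = "packing", dim = c(128L, 128L),
                         seed = 21)
  frac <- volumeFraction(res$mask)
  expect_gte(frac, 0.165); expect_lte(frac, 0.175)
  expect_identical(res$truth@volumeFraction, frac)
  res2 <- generateEcsMask(0.17, mode = "packing", dim = c(128L, 128L),
                          seed = 21)
  expect_identical(maskPixels(res$mask), maskPixels(res2$mask))
  # stripes mode: recovered thickness equals the recorded truth width
  st <- generateEcsMask(0.2, mode = "stripes", widthsNm = c(40, 80),
                        dim = c(120L, 120L), pixelSizeNm = 4, seed = 2)
  lt <- localThickness(st$mask)
  wf <- st$truth@widthField
  interior <- wf > 0 & col(wf) %in% 10:110
  expect_lt(stats::median(abs(lt$map[interior] - wf[interior]) /
                          wf[interior]), 0.15)
})

test_that("packing-mode masks have the nominal width along straight boundaries", {
  # straight cell-cell boundaries carry the nominal gap; Voronoi junctions
  # are genuinely wider (the pools of the channels-and-pools morphology),
  # so the lower quartile of the thickness distribution tracks the gap
  for (sd in c(4, 9, 14)) {
    res <- generateEcsMask(0.25, mode = "packing", dim = c(128L, 128L),
                           pixelSizeNm = 1, nCells = 12L, seed = sd)
    lt <- localThickness(res$mask, pixelSizeNm = 1)
    nominal <- res$truth@widthField[res$truth@widthField > 0][1]
    q25 <- stats::quantile(lt$widths_nm, 0.25, names = FALSE)
    expect_lt(abs(q25 - nominal) / nominal, 0.40)
    expect_gt(stats::median(lt$widths_nm), nominal)  # junction pools wider
  }
})

test_that("reference fractals are the advertised deterministic rasters", {
  ln <- generateReferenceFractal("line", 6)
  expect_identical(sum(ln), 64)
  sq <- generateReferenceFractal("filled_square", 5)
  expect_true(all(sq == 1))
  si <- generateReferenceFractal("sierpinski", 6)
  expect_identical(sum(si), 3^6)            # 3^levels pixels by construction
  expect_error(generateReferenceFractal("sierpinski", 2), "levels")
  expect_error(generateReferenceFractal("blob"))
})

test_that("movie TIFF round-trips through 16-bit storage", {
  trk <- staticTrack(3)
  mv <- renderMovie(trk, defaultCam(), seed = 2)$movie
  f <- withr::local_tempfile(fileext = ".tif")
  writeMovieTIFF(mv, f)
  back <- readMovieTIFF(f)
  expect_identical(dim(back), dim(mv))
  expect_lt(max(abs(back - pmin(pmax(round(mv), 0), 65535))), 1e-6)
})
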
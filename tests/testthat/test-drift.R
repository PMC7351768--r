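makeDriftEquations <- function(true, noiseSd = 0.02, seed = 1) {
  T <- nrow(true)
  eqs <- expand.grid(t = seq_len(T), u = seq_len(T))
  eqs <- eqs[eqs$t < eqs$u, ]
  set.seed(seed)
  eqs$dx <- true[eqs$u, 1] - true[eqs$t, 1] + stats::rnorm(nrow(eqs), 0, noiseSd)
  eqs$dy <- true[eqs$u, 2] - true[eqs$t, 2] + stats::rnorm(nrow(eqs), 0, noiseSd)
  eqs$outlier <- FALSE
  rownames(eqs) <- NULL
  eqs
}

# linear ramp + low-pass-filtered random walk, amplitude `amp` px
smoothDrift <- function(T, amp = 5, seed = 1) {
  set.seed(seed)
  rw <- apply(matrix(stats::rnorm(T * 2), T, 2), 2, cumsum)
  k <- stats::dnorm(seq(-3, 3, length.out = 21))
  sm <- apply(rw, 2, function(v)
    stats::filter(c(rep(v[1], 10), v, rep(v[T], 10)), k / sum(k))[11:(T + 10)])
  sm <- sweep(sm, 2, sm[1, ])
  sm <- sm / max(abs(sm)) * amp / 2
  lin <- cbind(seq(0, amp / 2, length.out = T),
               seq(0, -amp / 4, length.out = T))
  sweep(sm + lin, 2, (sm + lin)[1, ])
}

test_that("cross-correlation recovers integer and fractional shifts", {
  set.seed(3)
  base <- ecsnano:::.conv2same(matrix(stats::rnorm(64 * 64), 64, 64),
                               ecsnano:::.gaussKernel(2))
  rolled <- base[c(62:64, 1:61), c(4:64, 1:3)]   # shift by (+3 rows... )
  sh <- crossCorrelationShift(base, rolled)
  expect_equal(unname(sh), c(-3, 3), tolerance = 1e-9)
  frac <- fourierShift(base, 0.4, -0.3)
  sh2 <- crossCorrelationShift(base, frac)
  expect_lt(abs(sh2["dx"] - 0.4), 0.1)
  expect_lt(abs(sh2["dy"] + 0.3), 0.1)
  expect_error(crossCorrelationShift(matrix(1, 8, 8), matrix(1, 8, 8)),
               "flat")
})

test_that("pairwise shifts produce exactly T(T-1)/2 equations", {
  set.seed(5)
  reg <- array(0, c(16, 16, 10))
  base <- ecsnano:::.conv2same(matrix(stats::rnorm(256), 16, 16),
                               ecsnano:::.gaussKernel(1.5))
  for (f in 1:10) reg[, , f] <- base + stats::rnorm(256, 0, 0.01)
  eqs <- pairwiseShifts(reg)
  expect_identical(nrow(eqs), 45L)
  expect_true(all(eqs$t < eqs$u))
  expect_lt(max(abs(c(eqs$dx, eqs$dy))), 0.2)   # static scene
})

test_that("consistent equation systems are recovered exactly up to gauge", {
  true <- smoothDrift(20, amp = 4, seed = 2)
  eqs <- makeDriftEquations(true, noiseSd = 0)
  ds <- solveDrift(eqs, nFrames = 20, smoothWindow = 1L)
  expect_equal(driftEstimate(ds), unname(true), tolerance = 1e-9)
  expect_identical(driftEstimate(ds)[1, ], c(0, 0))
})

test_that("zero-drift equations give zero drift", {
  true <- matrix(0, 15, 2)
  eqs <- makeDriftEquations(true, noiseSd = 0)
  ds <- solveDrift(eqs, nFrames = 15)
  expect_lt(max(abs(driftEstimate(ds))), 1e-9)
})

test_that("corrupted equations are flagged and drift still recovered", {
  true <- smoothDrift(50, amp = 5, seed = 7)
  eqs <- makeDriftEquations(true, noiseSd = 0.02, seed = 8)
  expect_identical(nrow(eqs), 1225L)
  set.seed(9)
  bad <- sample(nrow(eqs), 122)
  eqs$dx[bad] <- eqs$dx[bad] + 5
  ds <- solveDrift(eqs, nFrames = 50, thresholdPx = 1.0)
  fin <- attr(ds, "equations")
  expect_true(all(fin$outlier[bad]))
  rmse <- sqrt(mean((driftEstimate(ds) - true)^2))
  expect_lt(rmse, 0.1)
})

test_that("a disconnected equation graph is reported with the frames", {
  eqs <- data.frame(t = c(1L, 1L, 4L), u = c(2L, 3L, 5L),
                    dx = 0, dy = 0, outlier = FALSE)
  expect_error(solveDrift(eqs, nFrames = 5), "disconnected.*4, 5")
})

test_that("outlier iteration terminates with a non-increasing active set", {
  true <- smoothDrift(30, amp = 5, seed = 3)
  eqs <- makeDriftEquations(true, noiseSd = 0.3, seed = 4)
  ds <- solveDrift(eqs, nFrames = 30, thresholdPx = 0.5)
  expect_s4_class(ds, "DriftSeries")
  expect_true(all(ds@nEquations >= 1L))
})

test_that("applying drift shifts positions as position - r_t * pixel", {
  locs <- data.frame(t_index = c(1L, 2L, 3L), x_nm = c(0, 100, 200),
                     y_nm = c(0, 0, 0))
  zero <- new("DriftSeries", drift = matrix(0, 3, 2),
              nEquations = rep(1L, 3), smoothingWindow = 1L)
  out <- applyDrift(locs, zero, 100)
  expect_identical(out$x_nm, locs$x_nm)
  cst <- new("DriftSeries",
             drift = rbind(c(0, 0), c(1, 1), c(1, 1)),
             nEquations = rep(1L, 3), smoothingWindow = 1L)
  out2 <- applyDrift(locs, cst, 100)
  expect_equal(out2$x_nm, locs$x_nm - c(0, 100, 100))
  expect_equal(out2$y_nm, locs$y_nm - c(0, 100, 100))
  expect_error(applyDrift(data.frame(t_index = 9L, x_nm = 0, y_nm = 0),
                          zero, 100), "outside")
})

test_that("end-to-end drift correction restores static-emitter precision", {
  trk <- staticTrack(42)
  cam <- defaultCam()
  drift <- cbind(seq_len(42) * 0.05, seq_len(42) * 0.02)
  drift <- sweep(drift, 2, drift[1, ])
  noDrift <- renderMovie(trk, cam, fov = c(30L, 30L), seed = 11)
  withDrift <- renderMovie(trk, cam, drift = drift, fov = c(30L, 30L),
                           seed = 11)
  locsA <- localizeMovie(noDrift$movie, 100)
  locsB <- localizeMovie(withDrift$movie, 100)
  # the static emitter itself is the background feature here
  eqs <- pairwiseShifts(withDrift$movie)
  ds <- solveDrift(eqs, nFrames = 42)
  corr <- applyDrift(locsB[locsB$accepted, ], ds, 100)
  sdA <- stats::sd(locsA$x_nm[locsA$accepted])
  sdRaw <- stats::sd(locsB$x_nm[locsB$accepted])
  sdCorr <- stats::sd(corr$x_nm)
  expect_gt(sdRaw, 3 * sdA)                # drift dominates uncorrected
  expect_lt(sdCorr, 2.2 * sdA)             # correction restores precision
})
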
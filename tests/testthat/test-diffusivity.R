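test_that("instantaneous MSD windows obey closed forms", {
  # stationary points: MSD identically zero
  still <- data.frame(t_s = (0:29) * 0.03, x_nm = 5, y_nm = -3)
  curves <- msdInstantaneous(still)
  expect_true(all(vapply(curves, function(w) all(w$msd_nm2 == 0),
                         logical(1))))
  # straight-line motion at speed v: MSD(tau) = v^2 tau^2 exactly
  v <- 1000                                  # nm/s
  lin <- data.frame(t_s = (0:29) * 0.03, x_nm = v * (0:29) * 0.03,
                    y_nm = 0)
  w <- msdInstantaneous(lin)[[1]]
  expect_equal(w$msd_nm2, v^2 * w$lag_s^2, tolerance = 1e-9)
  # too-short trajectory: empty result
  expect_identical(msdInstantaneous(still[1:10, ]), list())
})

test_that("windowed Brownian MSD matches 4 D tau on average", {
  msds <- c(); lags <- c()
  for (s in 1:10) {
    tr <- trackToDf(simulateWalker(NULL, 1e6, nSteps = 40, seed = s))
    for (w in msdInstantaneous(tr)) { msds <- c(msds, w$msd_nm2)
                                      lags <- c(lags, w$lag_s) }
  }
  pooled <- tapply(msds, lags, mean)
  tau <- as.numeric(names(pooled))[1:3]
  expect_equal(as.vector(pooled[1:3]), 4 * 1e6 * tau, tolerance = 0.1)
})

test_that("D_inst fitting is exact on linear curves and robust to offsets", {
  msd <- data.frame(lag_s = (1:5) * 0.03, msd_nm2 = 4 * (1:5) * 0.03)
  expect_equal(as.numeric(fitDInst(msd)), 1, tolerance = 1e-12)
  withOffset <- msd; withOffset$msd_nm2 <- withOffset$msd_nm2 + 900
  expect_equal(as.numeric(fitDInst(withOffset)), 1, tolerance = 1e-12)
  neg <- data.frame(lag_s = (1:4) * 0.03, msd_nm2 = c(4, 3, 2, 1))
  d <- fitDInst(neg)
  expect_identical(as.numeric(d), 0)
  expect_true(attr(d, "floored"))
  expect_true(is.na(fitDInst(msd[1, , drop = FALSE])))
})

test_that("rod reference diffusivity follows the formula exactly", {
  med <- new("ReferenceMedium")
  # independent log-space evaluation, 10 significant digits
  logD <- log(3) + log(med@kB) + log(med@temperature) +
    log(log(2 * 500 / med@diameter)) -
    log(8 * pi) - log(med@viscosity) - log(500e-9)
  expect_equal(dReference(500), exp(logD) * 1e18, tolerance = 1e-10)
  # the worked value: ~1.01e-11 m^2/s for a 500 nm nanotube at 37 C
  expect_equal(dReference(500) * 1e-18, 1.0088e-11, tolerance = 1e-3)
  # doubling the viscosity halves D exactly
  thick <- new("ReferenceMedium", viscosity = 1.4e-3)
  expect_equal(dReference(500, thick) * 2, dReference(500), tolerance = 1e-12)
  # strictly decreasing in L beyond diameter*e/2
  L <- seq(2, 2000, by = 7)
  expect_true(all(diff(dReference(L)) < 0))
  expect_error(dReference(-5), "> 0")
})

test_that("relative diffusivity recovers an imposed hindrance", {
  dref <- dReference(500)
  rs <- c()
  for (s in 1:30) {
    tr <- trackToDf(simulateWalker(NULL, 0.03 * dref, nSteps = 100,
                                   seed = 300 + s))
    est <- relativeDiffusivity(list(tr))
    rs <- c(rs, est$ratio)
  }
  expect_gt(stats::median(rs), 0.024)
  expect_lt(stats::median(rs), 0.036)
  # all-immobile input gives an empty table
  set.seed(1)
  frozen <- data.frame(t_s = (0:99) * 0.03,
                       x_nm = stats::rnorm(100, 0, 5),
                       y_nm = stats::rnorm(100, 0, 5),
                       traj_id = 1L, smaj_nm = NA_real_)
  expect_identical(nrow(relativeDiffusivity(list(frozen))), 0L)
})

test_that("density maps render unit-amplitude Gaussians", {
  m <- makeMap(1000, 1000, mode = "density")
  vals <- mapValues(m)
  expect_equal(max(vals), 1.0, tolerance = 1e-6)
  expect_equal(explorationArea(m),
               sum(vals >= 0.5) * 25^2 / 1e6, tolerance = 1e-12)
  # brute-force rasterized disc of the rendering Gaussian on the 25 nm
  # grid (thresholds off 0.5: the half maximum of a 50 nm FWHM Gaussian
  # falls exactly on the neighbouring pixel centre, a knife edge)
  sig <- 50 / (2 * sqrt(2 * log(2)))
  ctr <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  dd <- outer((seq_len(nrow(vals)) - ctr[1])^2,
              (seq_len(ncol(vals)) - ctr[2])^2, "+") * 25^2
  for (thr in c(0.4, 0.6)) {
    oracle <- sum(exp(-dd / (2 * sig^2)) >= thr) * 25^2 / 1e6
    expect_equal(explorationArea(m, threshold = thr), oracle,
                 tolerance = 1e-12)
  }
})

test_that("mean-value maps are convex combinations of their inputs", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    x <- stats::runif(n, 0, 2000); y <- stats::runif(n, 0, 2000)
    v <- stats::runif(n, -3, 9)
    m <- makeMap(x, y, v, mode = "mean_value")
    vals <- mapValues(m)
    expect_gte(min(vals, na.rm = TRUE), min(v) - 1e-9)
    expect_lte(max(vals, na.rm = TRUE), max(v) + 1e-9)
  }
  cst <- makeMap(c(0, 100, 200), c(0, 50, 100), rep(4.2, 3),
                 mode = "mean_value")
  covered <- !is.na(mapValues(cst))
  expect_true(all(abs(mapValues(cst)[covered] - 4.2) < 1e-6))
})

test_that("two distant value clusters keep their own map medians", {
  set.seed(8)
  x <- c(stats::rnorm(60, 0, 40), stats::rnorm(60, 5000, 40))
  y <- c(stats::rnorm(60, 0, 40), stats::rnorm(60, 5000, 40))
  v <- rep(c(0.02, 0.2), each = 60)
  m <- makeMap(x, y, v, mode = "mean_value")
  vals <- mapValues(m)
  nx <- ncol(vals); ny <- nrow(vals)
  lower <- vals[seq_len(ny %/% 3), seq_len(nx %/% 3)]
  upper <- vals[(ny - ny %/% 3):ny, (nx - nx %/% 3):nx]
  expect_equal(stats::median(lower, na.rm = TRUE), 0.02, tolerance = 0.01)
  expect_equal(stats::median(upper, na.rm = TRUE), 0.2, tolerance = 0.01)
})

test_that("exploration area grows monotonically with coverage", {
  set.seed(9)
  x <- stats::runif(50, 0, 1000); y <- stats::runif(50, 0, 1000)
  bounds <- c(-200, 1200, -200, 1200)
  a1 <- explorationArea(makeMap(x[1:20], y[1:20], mode = "density",
                                bounds = bounds))
  a2 <- explorationArea(makeMap(x, y, mode = "density", bounds = bounds))
  expect_gte(a2, a1)
})
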
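# Redundant cross-correlation (RCC) drift estimation.
#
# Slow sample drift is estimated from background features: the image
# region is cross-correlated between every frame pair (t, u), giving the
# overdetermined system Delta_{t,u} = r_u - r_t of T(T-1)/2 equations in
# the T per-frame drifts, solved in a least-squares sense with iterative
# outlier rejection and weighted smoothing.

#' Sub-pixel shift between two images
#'
#' FFT cross-correlation; the integer peak is refined per axis by a
#' 3-point quadratic (parabolic) interpolation. Returns the displacement
#' of \code{b} relative to \code{a} in px.
#'
#' @param a,b numeric matrices of identical size.
#' @return numeric length-2: (dx, dy) in px (columns, rows).
#' @export
crossCorrelationShift <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must share dimensions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("flat region: cross-correlation undefined (zero variance)")
  A <- a - mean(a); B <- b - mean(b)
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  pk <- which.max(cc)
  pr <- ((pk - 1L) %% nr) + 1L
  pc <- ((pk - 1L) %/% nr) + 1L
  interp <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  dr <- interp(cc[wrap(pr - 1L, nr), pc], cc[pr, pc], cc[wrap(pr + 1L, nr), pc])
  dc <- interp(cc[pr, wrap(pc - 1L, nc)], cc[pr, pc], cc[pr, wrap(pc + 1L, nc)])
  shiftRow <- (pr - 1L); shiftCol <- (pc - 1L)
  if (shiftRow > nr / 2) shiftRow <- shiftRow - nr
  if (shiftCol > nc / 2) shiftCol <- shiftCol - nc
  c(dx = shiftCol + dc, dy = shiftRow + dr)
}

#' All pairwise frame shifts of a region series
#'
#' Computes the shift between every ordered frame pair (t < u) of the
#' selected region, yielding exactly T(T-1)/2 drift equations.
#'
#' @param region array rows x cols x T of the background-feature region.
#' @return data.frame with columns \code{t}, \code{u}, \code{dx},
#'   \code{dy} (px) and \code{outlier} (all FALSE initially).
#' @export
pairwiseShifts <- function(region) {
  T <- dim(region)[3]
  if (T < 2L) stop("need at least two frames")
  ffts <- lapply(seq_len(T), function(t) {
    fr <- region[, , t]
    if (stats::sd(fr) == 0)
      stop("flat region in frame ", t, ": cross-correlation undefined")
    stats::fft(fr - mean(fr))
  })
  nr <- dim(region)[1]; nc <- dim(region)[2]
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  interp <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  n <- T * (T - 1L) %/% 2L
  tt <- integer(n); uu <- integer(n); dx <- numeric(n); dy <- numeric(n)
  k <- 0L
  for (t in 1:(T - 1L)) for (u in (t + 1L):T) {
    k <- k + 1L
    cc <- Re(stats::fft(Conj(ffts[[t]]) * ffts[[u]], inverse = TRUE))
    pk <- which.max(cc)
    pr <- ((pk - 1L) %% nr) + 1L
    pc <- ((pk - 1L) %/% nr) + 1L
    dr <- interp(cc[wrap(pr - 1L, nr), pc], cc[pr, pc],
                 cc[wrap(pr + 1L, nr), pc])
    dc <- interp(cc[pr, wrap(pc - 1L, nc)], cc[pr, pc],
                 cc[pr, wrap(pc + 1L, nc)])
    sr <- pr - 1L; sc <- pc - 1L
    if (sr > nr / 2) sr <- sr - nr
    if (sc > nc / 2) sc <- sc - nc
    tt[k] <- t; uu[k] <- u; dx[k] <- sc + dc; dy[k] <- sr + dr
  }
  data.frame(t = tt, u = uu, dx = dx, dy = dy, outlier = FALSE)
}

# Least-squares solve of Delta_{t,u} = r_u - r_t with gauge r_1 = 0,
# given the subset of equation rows to use.
#' @noRd
.solveGauge <- function(eqs, T, use) {
  e <- eqs[use, , drop = FALSE]
  m <- nrow(e)
  A <- matrix(0, m, T - 1L)
  sel <- e$u > 1L; A[cbind(which(sel), e$u[sel] - 1L)] <- 1
  sel <- e$t > 1L; A[cbind(which(sel), e$t[sel] - 1L)] <- -1
  qrA <- qr(A)
  rx <- c(0, qr.coef(qrA, e$dx))
  ry <- c(0, qr.coef(qrA, e$dy))
  rx[is.na(rx)] <- 0; ry[is.na(ry)] <- 0
  cbind(rx, ry)
}

#' Solve the RCC equation system for a drift series
#'
#' Least-squares solution of the T(T-1)/2 pairwise-shift equations with
#' the gauge fixed at r_1 = (0, 0). Equations whose residual exceeds the
#' threshold (default 1 px) are flagged as outliers and the system is
#' re-solved iteratively until the outlier set stabilises (the non-outlier
#' set is non-increasing; a hard cap bounds the iterations). The result is
#' smoothed by a moving average in which each frame is weighted by its
#' non-outlier equation count.
#'
#' @param equations data.frame from \code{\link{pairwiseShifts}}.
#' @param nFrames total frame count T; defaults to \code{max(equations$u)}.
#' @param thresholdPx residual threshold for outlier flagging (px).
#' @param smoothWindow moving-average window (frames); 1 disables
#'   smoothing.
#' @param maxIter outlier-iteration cap.
#' @return a \linkS4class{DriftSeries}; the input equations with final
#'   outlier flags are attached as attribute \code{"equations"}.
#' @export
solveDrift <- function(equations, nFrames = max(equations$u),
                       thresholdPx = 1.0, smoothWindow = 5L,
                       maxIter = 100L) {
  T <- as.integer(nFrames)
  if (T < 2L) stop("need equations over at least two frames")
  if (any(equations$t >= equations$u))
    stop("equations must have t < u")
  use <- !equations$outlier
  prevUse <- rep(NA, length(use))
  iter <- 0L
  r <- NULL
  repeat {
    iter <- iter + 1L
    .checkConnected(equations[use, , drop = FALSE], T)
    r <- .solveGauge(equations, T, use)
    resx <- equations$dx - (r[equations$u, 1] - r[equations$t, 1])
    resy <- equations$dy - (r[equations$u, 2] - r[equations$t, 2])
    resid <- sqrt(resx^2 + resy^2)
    newUse <- use & resid <= thresholdPx   # non-outlier set never grows
    if (identical(newUse, use) || identical(newUse, prevUse) ||
        iter >= maxIter) { use <- newUse; break }
    prevUse <- use
    use <- newUse
  }
  .checkConnected(equations[use, , drop = FALSE], T)
  r <- .solveGauge(equations, T, use)
  counts <- integer(T)
  tab <- table(c(equations$t[use], equations$u[use]))
  counts[as.integer(names(tab))] <- as.integer(tab)
  sm <- .weightedSmooth(r, counts, smoothWindow)
  sm <- sweep(sm, 2, sm[1, ])              # re-pin gauge after smoothing
  equations$outlier <- !use
  out <- new("DriftSeries", drift = unname(sm),
             nEquations = counts, smoothingWindow = as.integer(smoothWindow))
  attr(out, "equations") <- equations
  out
}

#' @noRd
.checkConnected <- function(eqs, T) {
  g <- igraph::graph_from_edgelist(cbind(eqs$t, eqs$u), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, T - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    main <- which.max(comp$csize)
    bad <- which(comp$membership != main)
    stop("drift equation graph is disconnected; frames {",
         paste(bad, collapse = ", "), "} are not linked to frame 1")
  }
  invisible(TRUE)
}

# Moving-average smoothing with per-frame weights.
#' @noRd
.weightedSmooth <- function(r, weights, window) {
  if (window <= 1L) return(r)
  T <- nrow(r)
  half <- (window - 1L) %/% 2L
  out <- r
  w <- pmax(weights, 1e-9)
  for (t in seq_len(T)) {
    lo <- max(1L, t - half); hi <- min(T, t + half)
    ww <- w[lo:hi]
    out[t, 1] <- sum(r[lo:hi, 1] * ww) / sum(ww)
    out[t, 2] <- sum(r[lo:hi, 2] * ww) / sum(ww)
  }
  out
}

#' Apply a drift correction to localizations
#'
#' Subtracts the per-frame drift (converted to nm) from each localization:
#' corrected position = position - r_t * pixelSize.
#'
#' @param localizations data.frame with \code{t_index}, \code{x_nm},
#'   \code{y_nm} (as produced by \code{\link{localizeMovie}}).
#' @param drift a \linkS4class{DriftSeries}.
#' @param pixelSizeNm camera pixel size (nm).
#' @return the localizations with corrected \code{x_nm}, \code{y_nm};
#'   the uncorrected positions are kept as \code{x_raw_nm}, \code{y_raw_nm}.
#' @export
applyDrift <- function(localizations, drift, pixelSizeNm = 100) {
  r <- driftEstimate(drift)
  ti <- round(localizations$t_index)
  if (any(ti < 1L | ti > nrow(r)))
    stop("localization time index outside the drift range")
  localizations$x_raw_nm <- localizations$x_nm
  localizations$y_raw_nm <- localizations$y_nm
  localizations$x_nm <- localizations$x_nm - r[ti, 1] * pixelSizeNm
  localizations$y_nm <- localizations$y_nm - r[ti, 2] * pixelSizeNm
  localizations
}
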
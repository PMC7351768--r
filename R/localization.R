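# Sub-pixel emitter localization by asymmetric 2D Gaussian fitting.

#' Sliding average of consecutive frames
#'
#' Averages \code{window} consecutive frames (default 3) ahead of each
#' fit to improve the localization precision. The average is sliding, not
#' block: output frame t is the mean of input frames t .. t+window-1 and
#' is timestamped at the central input frame, so the 30 ms sampling
#' required by the 90 ms MSD fits is preserved. Consecutive averaged
#' frames share input frames and are therefore serially correlated; the
#' MSD machinery works on lags of at least one sample.
#'
#' @param movie array rows x cols x frames.
#' @param window number of frames per average (>= 1).
#' @return array rows x cols x (frames - window + 1), with attribute
#'   \code{frameOffset} giving the index offset of the central frame
#'   (= (window - 1) / 2).
#' @export
averageFrames <- function(movie, window = 3L) {
  nF <- dim(movie)[3]
  if (window < 1L) stop("window must be >= 1")
  if (window > nF) stop("window (", window, ") exceeds movie length (", nF, ")")
  nOut <- nF - window + 1L
  out <- array(0, c(dim(movie)[1:2], nOut))
  acc <- array(0, dim(movie)[1:2])
  for (k in seq_len(window)) acc <- acc + movie[, , k]
  out[, , 1] <- acc / window
  if (nOut > 1L) for (t in 2:nOut) {
    acc <- acc - movie[, , t - 1L] + movie[, , t + window - 1L]
    out[, , t] <- acc / window
  }
  attr(out, "frameOffset") <- (window - 1) / 2
  out
}

#' Detect candidate emitters in one frame
#'
#' Local maxima exceeding background + threshold x (robust) background sd,
#' with a minimum pairwise separation enforced in order of decreasing
#' intensity. Background and its sd are estimated by the frame median and
#' MAD.
#'
#' @param frame numeric matrix.
#' @param threshold detection threshold in background-sd units.
#' @param minSeparation minimum seed separation (px).
#' @return data.frame with columns \code{row}, \code{col},
#'   \code{intensity}; zero rows if nothing is detected.
#' @export
detectCandidates <- function(frame, threshold = 5, minSeparation = 5) {
  if (threshold <= 0) stop("threshold must be > 0")
  bkg <- stats::median(frame)
  s <- stats::mad(frame)
  if (s == 0) s <- stats::sd(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- frame
  isMax <- frame >= bkg + threshold * s
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    isMax <- isMax & frame >= pad[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(row = integer(0), col = integer(0),
                      intensity = numeric(0)))
  inten <- frame[idx]
  ord <- order(inten, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; inten <- inten[ord]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    sel <- which(keep)
    d <- sqrt((idx[sel, 1] - idx[i, 1])^2 + (idx[sel, 2] - idx[i, 2])^2)
    if (all(d >= minSeparation)) keep[i] <- TRUE
  }
  data.frame(row = idx[keep, 1], col = idx[keep, 2], intensity = inten[keep])
}

# Moment-based initial parameters from a fit window.
#' @noRd
.momentInit <- function(win) {
  bkg <- stats::median(win)
  w <- pmax(win - bkg, 0)
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  rows <- seq_len(nrow(win)); cols <- seq_len(ncol(win))
  cy <- sum(rows * rowSums(w)) / tot
  cx <- sum(cols * colSums(w)) / tot
  dy <- matrix(rows - cy, nrow(win), ncol(win))
  dx <- matrix(rep(cols - cx, each = nrow(win)), nrow(win), ncol(win))
  mxx <- sum(w * dx^2) / tot; myy <- sum(w * dy^2) / tot
  mxy <- sum(w * dx * dy) / tot
  tr <- mxx + myy; det <- mxx * myy - mxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0.25)
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  list(x = cx, y = cy, sMaj = sqrt(max(l1, 0.3)), sMin = sqrt(max(l2, 0.3)),
       theta = theta %% pi, amp = max(win) - bkg, bkg = bkg)
}

#' Fit one asymmetric 2D Gaussian
#'
#' Nonlinear least squares (Levenberg-Marquardt) of an elliptical Gaussian
#' with arbitrary orientation over (x, y, sigma_major, sigma_minor, theta,
#' amplitude, background), initialised from window moments. Orientation is
#' reported in [0, pi); sigma_major >= sigma_minor is enforced by swapping
#' axes after the fit. Fits are rejected (with a reason code) on
#' non-convergence, a degenerate flat window, amplitude below 2x the
#' residual background sd, or a major sigma exceeding half the fit window.
#'
#' @param frame numeric matrix (one averaged frame).
#' @param seedRow,seedCol integer seed position (px).
#' @param fitWindow odd window edge (px); must fit inside the frame.
#' @param pixelSizeNm pixel size used to convert to nm.
#' @param tIndex time index recorded in the output.
#' @param residCap rejection cap on the residual norm relative to the
#'   fitted amplitude.
#' @return one-row data.frame: t_index, x_nm, y_nm, x_px, y_px, smaj_nm,
#'   smin_nm, theta_rad, amp, bkg, resid, accepted, reason.
#' @export
fitAsymmetricGaussian <- function(frame, seedRow, seedCol, fitWindow = 15L,
                                  pixelSizeNm = 100, tIndex = 1L,
                                  residCap = 2.0) {
  half <- (fitWindow - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  rej <- function(reason)
    data.frame(t_index = tIndex, x_nm = NA_real_, y_nm = NA_real_,
               x_px = NA_real_, y_px = NA_real_, smaj_nm = NA_real_,
               smin_nm = NA_real_, theta_rad = NA_real_, amp = NA_real_,
               bkg = NA_real_, resid = NA_real_, accepted = FALSE,
               reason = reason)
  if (seedRow - half < 1L || seedRow + half > nr ||
      seedCol - half < 1L || seedCol + half > nc)
    return(rej("window_outside_frame"))
  rows <- (seedRow - half):(seedRow + half)
  cols <- (seedCol - half):(seedCol + half)
  win <- frame[rows, cols]
  if (max(win) - min(win) < .Machine$double.eps * 100)
    return(rej("flat_window"))
  init <- .momentInit(win)
  if (is.null(init)) return(rej("flat_window"))
  xs <- seq_along(cols); ys <- seq_along(rows)
  residFun <- function(p)
    as.vector(win - .asymGauss(xs, ys, p[1], p[2], p[3], p[4], p[5],
                               p[6], p[7]))
  p0 <- c(init$x, init$y, init$sMaj, init$sMin, init$theta,
          init$amp, init$bkg)
  fit <- try(minpack.lm::nls.lm(
    par = p0, fn = residFun,
    lower = c(0.5, 0.5, 0.2, 0.2, -2 * pi, 0, -Inf),
    upper = c(length(xs) + 0.5, length(ys) + 0.5, fitWindow, fitWindow,
              2 * pi, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(rej("fit_error"))
  if (!fit$info %in% 1:4) return(rej("no_convergence"))
  p <- fit$par
  sMaj <- p[3]; sMin <- p[4]; theta <- p[5]
  if (sMin > sMaj) { tmp <- sMaj; sMaj <- sMin; sMin <- tmp
                     theta <- theta + pi / 2 }
  theta <- theta %% pi
  res <- residFun(c(p[1], p[2], sMaj, sMin, theta, p[6], p[7]))
  residNorm <- sqrt(mean(res^2))
  bkgSd <- stats::mad(res)
  reason <- "ok"; accepted <- TRUE
  if (p[6] < 2 * bkgSd) { accepted <- FALSE; reason <- "low_amplitude" }
  if (sMaj > fitWindow / 2) { accepted <- FALSE; reason <- "sigma_too_wide" }
  if (residNorm > residCap * max(p[6], .Machine$double.eps))
    { accepted <- FALSE; reason <- "high_residual" }
  colPx <- p[1] + cols[1] - 1
  rowPx <- p[2] + rows[1] - 1
  data.frame(t_index = tIndex,
             x_nm = .pxToNm(colPx, pixelSizeNm),
             y_nm = .pxToNm(rowPx, pixelSizeNm),
             x_px = colPx, y_px = rowPx,
             smaj_nm = sMaj * pixelSizeNm, smin_nm = sMin * pixelSizeNm,
             theta_rad = theta, amp = p[6], bkg = p[7],
             resid = residNorm, accepted = accepted, reason = reason)
}

#' Localize all emitters in a movie
#'
#' Full localization chain: sliding frame averaging, candidate detection,
#' and one asymmetric Gaussian fit per candidate. Rejected fits are kept
#' in the output flagged \code{accepted = FALSE}; a failing frame never
#' aborts the movie. The result is deterministic for a given movie.
#'
#' @param movie array rows x cols x frames.
#' @param pixelSizeNm camera pixel size (nm).
#' @param window frame-averaging window (default 3).
#' @param exposure frame interval (s) used for the t_s column.
#' @param threshold detection threshold (background-sd units).
#' @param fitWindow fit window edge (px).
#' @param minSeparation candidate separation (px).
#' @return data.frame of localizations; \code{t_index} is the central
#'   input-frame index, \code{t_s} its time.
#' @export
localizeMovie <- function(movie, pixelSizeNm = 100, window = 3L,
                          exposure = 0.030, threshold = 5,
                          fitWindow = 15L, minSeparation = 5) {
  avg <- averageFrames(movie, window)
  off <- attr(avg, "frameOffset")
  out <- vector("list", dim(avg)[3])
  for (t in seq_len(dim(avg)[3])) {
    fr <- avg[, , t]
    seeds <- detectCandidates(fr, threshold, minSeparation)
    if (!nrow(seeds)) next
    fits <- lapply(seq_len(nrow(seeds)), function(i)
      fitAsymmetricGaussian(fr, seeds$row[i], seeds$col[i], fitWindow,
                            pixelSizeNm, tIndex = t + off))
    out[[t]] <- do.call(rbind, fits)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- fitAsymmetricGaussian(matrix(0, 3, 3), 2, 2, 3, pixelSizeNm)[0, ]
  res$t_s <- (res$t_index - 1) * exposure
  rownames(res) <- NULL
  res
}

#' Lateral localization precision bound for a Gaussian spot
#'
#' Least-squares localization variance for a pixelated Gaussian PSF with
#' uniform background (Mortensen-style bound): with sigma_a^2 = sigma^2 +
#' a^2/12, var = sigma_a^2/N (16/9 + 8 pi sigma_a^2 b^2 / (N a^2)), where
#' N is the collected photon count, a the pixel size and b^2 the
#' background photons per pixel. Used to benchmark fitted positions.
#'
#' @param photons expected photons in the spot.
#' @param sigmaNm PSF Gaussian sigma (nm).
#' @param pixelSizeNm pixel size (nm).
#' @param backgroundPhotons background photons per pixel.
#' @return standard deviation bound per axis (nm).
#' @export
localizationBound <- function(photons, sigmaNm, pixelSizeNm,
                              backgroundPhotons = 0) {
  sa2 <- sigmaNm^2 + pixelSizeNm^2 / 12
  v <- sa2 / photons *
    (16 / 9 + 8 * pi * sa2 * backgroundPhotons / (photons * pixelSizeNm^2))
  sqrt(v)
}
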
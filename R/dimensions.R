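# Local ECS width from trajectory confinement windows.

# One-time calibration of the width estimator, determined on simulated
# channels (50-200 nm, tissue-like walker diffusivity, 30 nm localization
# noise, 6-point windows at quartile 0.25) and frozen; see the methods
# vignette. .widthCalibration maps the noise-corrected minor-axis
# peak-to-peak extent of selected windows to a channel width;
# .widthNoiseCoef is the effective noise inflation of that extent in
# sigma units (well below the iid range coefficient 2.53 of 6 normal
# draws, because maximum-confinement selection favours low-noise windows).
.widthCalibration <- 2.2215
.widthNoiseCoef <- 1.45

#' Sliding 6-point confinement windows
#'
#' For every run of \code{k} consecutive localizations (default 6), fits
#' the second-moment ellipse of the window: principal axes from the
#' eigenvectors of the 2x2 covariance, extents as peak-to-peak
#' projections of the points on each axis, and the eccentricity ratio
#' minor extent / major extent (0 = line, 1 = isotropic).
#'
#' @param traj data.frame of one trajectory with \code{x_nm}, \code{y_nm}.
#' @param k window length (localizations).
#' @return data.frame: cx, cy (centroid nm), major_nm, minor_nm
#'   (peak-to-peak extents), ratio, axis_theta (major-axis angle, rad).
#' @export
confinementWindows <- function(traj, k = 6L) {
  n <- nrow(traj)
  if (n < k) return(data.frame(cx = numeric(0), cy = numeric(0),
                               major_nm = numeric(0), minor_nm = numeric(0),
                               ratio = numeric(0), axis_theta = numeric(0)))
  out <- vector("list", n - k + 1L)
  for (s in seq_len(n - k + 1L)) {
    idx <- s:(s + k - 1L)
    x <- traj$x_nm[idx]; y <- traj$y_nm[idx]
    cx <- mean(x); cy <- mean(y)
    cm <- cbind(x - cx, y - cy)
    cov <- crossprod(cm) / k
    eig <- eigen(cov, symmetric = TRUE)
    vMaj <- eig$vectors[, 1]; vMin <- eig$vectors[, 2]
    pMaj <- cm %*% vMaj; pMin <- cm %*% vMin
    major <- diff(range(pMaj)); minor <- diff(range(pMin))
    ratio <- if (major <= 0) 1 else min(minor / major, 1)
    out[[s]] <- data.frame(cx = cx, cy = cy, major_nm = major,
                           minor_nm = minor, ratio = ratio,
                           axis_theta = atan2(vMaj[2], vMaj[1]) %% pi)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Local width estimates from maximally confined windows
#'
#' Operationalises "maximum confinement" as the windows in the lowest
#' quartile of the eccentricity ratio within each trajectory: there the
#' minor axis is set by the local ECS boundary rather than by the random
#' walk. The width is the minor-axis peak-to-peak extent, corrected for
#' localization noise by quadrature subtraction of the selection-adjusted
#' noise term (1.45 sigma), and scaled by a calibration factor; both
#' constants were fixed once on synthetic channels and are frozen.
#'
#' @param windows data.frame from \code{\link{confinementWindows}} (one
#'   trajectory), or a list of such data.frames.
#' @param quartile selection quantile on the eccentricity ratio.
#' @param locNoiseNm per-axis localization error sd (nm) to subtract.
#' @param k window length the windows were built with.
#' @param calibration multiplicative calibration constant.
#' @return data.frame: x_nm, y_nm, width_nm, ratio; zero rows when all
#'   windows are isotropic (flagged via attribute \code{"allIsotropic"}).
#' @export
estimateLocalWidth <- function(windows, quartile = 0.25, locNoiseNm = 0,
                               k = 6L, calibration = .widthCalibration) {
  if (is.data.frame(windows)) windows <- list(windows)
  rows <- lapply(windows, function(w) {
    if (!nrow(w)) return(NULL)
    cut <- stats::quantile(w$ratio, quartile, names = FALSE)
    sel <- w[w$ratio <= cut, , drop = FALSE]
    if (!nrow(sel)) return(NULL)
    noiseRange <- .widthNoiseCoef * locNoiseNm
    corrected <- sqrt(pmax(sel$minor_nm^2 - noiseRange^2, 0))
    data.frame(x_nm = sel$cx, y_nm = sel$cy,
               width_nm = calibration * corrected, ratio = sel$ratio)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      width_nm = numeric(0), ratio = numeric(0))
    attr(out, "allIsotropic") <- TRUE
  } else {
    rownames(out) <- NULL
    attr(out, "allIsotropic") <- FALSE
  }
  out
}

#' Super-resolved local-dimension map
#'
#' Mean-value map (25 nm pixels, 50 nm FWHM rendering) of local width
#' estimates; see \code{\link{makeMap}}.
#'
#' @param widths data.frame from \code{\link{estimateLocalWidth}}.
#' @param ... forwarded to \code{\link{makeMap}}.
#' @return a \linkS4class{SuperResolvedMap} carrying widths in nm.
#' @export
dimensionMap <- function(widths, ...) {
  makeMap(widths$x_nm, widths$y_nm, widths$width_nm,
          mode = "mean_value", ...)
}
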
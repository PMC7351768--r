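# Instantaneous MSD, D_inst, the rod free-diffusion reference, relative
# diffusivity, and super-resolved map rendering.

#' Instantaneous MSD over a sliding window
#'
#' For every position of a sliding window (450 ms by default, i.e. 15
#' samples at 30 ms) along a trajectory, computes the time-averaged MSD at
#' every lag representable inside the window. Each curve carries the
#' window's centroid position and central time, which later anchor the
#' diffusivity estimate on the map.
#'
#' @param traj data.frame of one trajectory with \code{t_s}, \code{x_nm},
#'   \code{y_nm}, sampled at a constant interval.
#' @param windowSpanS sliding-window span (s), default 0.450.
#' @param dt sampling interval (s); inferred from \code{t_s} if NULL.
#' @return list of data.frames, one per window, each with columns
#'   \code{lag_s}, \code{msd_nm2}, \code{n_pairs} and attributes
#'   \code{centerTime}, \code{cx}, \code{cy}; empty list if the
#'   trajectory is shorter than the window.
#' @export
msdInstantaneous <- function(traj, windowSpanS = 0.450, dt = NULL) {
  n <- nrow(traj)
  if (is.null(dt)) {
    if (n < 2L) return(list())
    dt <- stats::median(diff(traj$t_s))
  }
  k <- round(windowSpanS / dt)
  if (k < 4L) stop("window span must cover at least 4 samples")
  if (n < k + 1L) return(list())
  out <- vector("list", n - k)
  for (s in seq_len(n - k)) {
    idx <- s:(s + k)                      # k+1 samples spanning k*dt
    x <- traj$x_nm[idx]; y <- traj$y_nm[idx]
    lags <- seq_len(k)
    msd <- vapply(lags, function(l) {
      m <- length(idx) - l
      mean((x[(1 + l):(m + l)] - x[1:m])^2 +
           (y[(1 + l):(m + l)] - y[1:m])^2)
    }, numeric(1))
    w <- data.frame(lag_s = lags * dt, msd_nm2 = msd,
                    n_pairs = length(idx) - lags)
    attr(w, "centerTime") <- mean(traj$t_s[idx])
    attr(w, "cx") <- mean(x); attr(w, "cy") <- mean(y)
    out[[s]] <- w
  }
  out
}

#' Instantaneous diffusion coefficient from one MSD curve
#'
#' Ordinary least-squares line over the lags within the fit span (first
#' 90 ms by default, i.e. 3 lag points at 30 ms), with a free intercept
#' that absorbs the static localization-error offset. For 2D tracking,
#' D_inst = slope / 4; negative slopes are floored at zero and flagged.
#'
#' @param msd data.frame with \code{lag_s}, \code{msd_nm2}.
#' @param fitSpanS largest lag included in the fit (s), default 0.090.
#' @param intercept logical, fit a free intercept (default TRUE).
#' @return numeric D_inst (nm^2/s) with attribute \code{floored}.
#' @export
fitDInst <- function(msd, fitSpanS = 0.090, intercept = TRUE) {
  sel <- msd$lag_s <= fitSpanS + 1e-12
  if (sum(sel) < 2L) return(structure(NA_real_, floored = FALSE))
  x <- msd$lag_s[sel]; y <- msd$msd_nm2[sel]
  slope <- if (intercept) stats::cov(x, y) / stats::var(x)
           else sum(x * y) / sum(x * x)
  d <- slope / 4
  structure(max(d, 0), floored = d < 0)
}

#' Free-diffusion coefficient of a rod probe
#'
#' Translational diffusion coefficient of a rigid rod of length L and
#' aspect ratio phi in a fluid of reference viscosity:
#' D_ref = 3 kB T ln(2 phi) / (8 pi eta L). Defaults describe a nanotube
#' at 37 C in a cerebrospinal-fluid-like medium (eta = 0.70 mPa s).
#'
#' @param lengthNm rod length L (nm), > 0.
#' @param medium a \linkS4class{ReferenceMedium}.
#' @return D_ref in nm^2/s.
#' @examples
#' dReference(500)  # ~1.0e7 nm^2/s, i.e. ~1.0e-11 m^2/s
#' @export
dReference <- function(lengthNm, medium = new("ReferenceMedium")) {
  if (any(lengthNm <= 0)) stop("rod length must be > 0")
  phi <- lengthNm / medium@diameter
  if (any(phi <= 1)) stop("aspect ratio phi = L/diameter must be > 1")
  L <- lengthNm * 1e-9
  dSI <- 3 * medium@kB * medium@temperature * log(2 * phi) /
    (8 * pi * medium@viscosity * L)
  dSI * 1e18                               # m^2/s -> nm^2/s
}

#' Relative diffusivity estimates along trajectories
#'
#' For each mobile trajectory: estimates the probe length (falling back,
#' flagged, to the cohort median when undefined), computes D_ref, slides
#' the instantaneous-MSD window, fits D_inst per window and reports the
#' ratio D_inst / D_ref at the window centroid.
#'
#' @param trajs list of per-trajectory data.frames (see
#'   \code{\link{splitTrajectories}}); immobile trajectories should
#'   already be excluded, and are dropped here if
#'   \code{excludeImmobile = TRUE}.
#' @param medium a \linkS4class{ReferenceMedium}.
#' @param windowSpanS,fitSpanS MSD window and fit spans (s).
#' @param psfFwhmNm optical FWHM forwarded to the length estimator.
#' @param excludeImmobile drop trajectories classified immobile.
#' @return data.frame: traj_id, t_s, x_nm, y_nm, D_inst, D_ref, ratio,
#'   length_nm, length_imputed.
#' @export
relativeDiffusivity <- function(trajs, medium = new("ReferenceMedium"),
                                windowSpanS = 0.450, fitSpanS = 0.090,
                                psfFwhmNm = 450, excludeImmobile = TRUE) {
  if (excludeImmobile) {
    mob <- vapply(trajs, function(tr) {
      im <- classifyImmobile(tr)
      is.na(im) || !im
    }, logical(1))
    trajs <- trajs[mob]
  }
  if (!length(trajs))
    return(data.frame(traj_id = integer(0), t_s = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      D_inst = numeric(0), D_ref = numeric(0),
                      ratio = numeric(0), length_nm = numeric(0),
                      length_imputed = logical(0)))
  lens <- vapply(trajs, function(tr)
    if ("smaj_nm" %in% names(tr)) estimateLength(tr, psfFwhmNm = psfFwhmNm)
    else NA_real_, numeric(1))
  cohort <- stats::median(lens, na.rm = TRUE)
  if (!is.finite(cohort)) cohort <- 500    # nominal nanotube length
  rows <- list()
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    L <- lens[i]; imputed <- FALSE
    if (!is.finite(L) || L <= 0) { L <- cohort; imputed <- TRUE }
    dRef <- dReference(max(L, 2), medium)
    curves <- msdInstantaneous(tr, windowSpanS)
    if (!length(curves)) next
    id <- if ("traj_id" %in% names(tr)) tr$traj_id[1] else i
    rows[[length(rows) + 1L]] <- do.call(rbind, lapply(curves, function(w) {
      d <- fitDInst(w, fitSpanS)
      data.frame(traj_id = id, t_s = attr(w, "centerTime"),
                 x_nm = attr(w, "cx"), y_nm = attr(w, "cy"),
                 D_inst = as.numeric(d), D_ref = dRef,
                 ratio = as.numeric(d) / dRef, length_nm = L,
                 length_imputed = imputed)
    }))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(traj_id = integer(0), t_s = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      D_inst = numeric(0), D_ref = numeric(0),
                      ratio = numeric(0), length_nm = numeric(0),
                      length_imputed = logical(0))
  rownames(out) <- NULL
  out
}

#' Render a super-resolved map from point values
#'
#' Density mode: localizations are accumulated on the map grid (25 nm
#' pixels by default) and convolved with a unit-amplitude 2D Gaussian of
#' 50 nm FWHM, so one isolated localization at a pixel centre peaks at
#' exactly 1. Mean-value mode: values falling in the same pixel are first
#' averaged, then spread by normalized convolution (value-weighted sum
#' divided by weight sum), which keeps every map value inside the range of
#' the inputs; pixels with no support are NA.
#'
#' @param x,y point coordinates (nm).
#' @param values per-point values (mean_value mode); ignored for density.
#' @param pixelNm map pixel size (nm), default 25.
#' @param fwhmNm rendering Gaussian FWHM (nm), default 50.
#' @param mode \code{"density"} or \code{"mean_value"}.
#' @param bounds optional numeric length-4 (xmin, xmax, ymin, ymax) nm;
#'   default covers the data padded by 3 rendering sigmas.
#' @return a \linkS4class{SuperResolvedMap}.
#' @export
makeMap <- function(x, y, values = NULL, pixelNm = 25, fwhmNm = 50,
                    mode = c("density", "mean_value"), bounds = NULL) {
  mode <- match.arg(mode)
  if (!length(x)) stop("need at least one point")
  if (mode == "mean_value" && (is.null(values) || length(values) != length(x)))
    stop("mean_value mode needs one value per point")
  sigma <- .fwhmToSigma(fwhmNm)
  pad <- 3 * sigma
  if (is.null(bounds))
    bounds <- c(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
  x0 <- bounds[1]; y0 <- bounds[3]
  nc <- max(1L, ceiling((bounds[2] - x0) / pixelNm) + 1L)
  nr <- max(1L, ceiling((bounds[4] - y0) / pixelNm) + 1L)
  ci <- pmin(pmax(round((x - x0) / pixelNm) + 1L, 1L), nc)
  ri <- pmin(pmax(round((y - y0) / pixelNm) + 1L, 1L), nr)
  kern <- .gaussKernel(sigma / pixelNm)
  lin <- (ci - 1L) * nr + ri
  if (mode == "density") {
    counts <- matrix(0, nr, nc)
    tab <- table(lin)
    counts[as.integer(names(tab))] <- as.integer(tab)
    vals <- .conv2same(counts, kern)
    weights <- vals
  } else {
    occ <- matrix(0, nr, nc); acc <- matrix(0, nr, nc)
    tab <- tapply(values, lin, mean)
    occ[as.integer(names(tab))] <- 1
    acc[as.integer(names(tab))] <- as.numeric(tab)
    weights <- .conv2same(occ, kern)
    num <- .conv2same(acc, kern)
    vals <- ifelse(weights > 1e-4, num / pmax(weights, 1e-12), NA_real_)
  }
  new("SuperResolvedMap", values = vals, weights = weights,
      pixelSize = pixelNm, origin = c(x0, y0), mode = mode)
}

#' Explored area from a density map
#'
#' Binarises a density map at the given amplitude threshold (default 0.5,
#' the half maximum of a single rendered localization) and reports the
#' foreground area.
#'
#' @param map a \linkS4class{SuperResolvedMap} in density mode.
#' @param threshold amplitude threshold.
#' @return area in um^2.
#' @export
explorationArea <- function(map, threshold = 0.5) {
  if (map@mode != "density") stop("exploration area needs a density map")
  sum(map@values >= threshold, na.rm = TRUE) * pixelSize(map)^2 / 1e6
}
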
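# Synthetic ground-truth generators.
#
# These generators emulate every statistical structure the downstream
# analysis assumes -- channels-and-pools ECS geometry, confined Brownian
# rod probes, asymmetric-Gaussian emitter rendering with EM-CCD noise and
# global drift, EM-like binary masks with known volume fraction and
# widths, and reference fractals -- so that every estimator in the package
# can be validated against known truth without any external data.

#' Generate a channels-and-pools scene geometry
#'
#' Builds a connected planar ECS model: \code{nPools} circular pools
#' (voids) joined by straight channels whose endpoints are pool centres,
#' so connectivity holds by construction. Pool radii and channel widths
#' are drawn uniformly from the given ranges; defaults reflect the ECS
#' configuration seen in cryofixed tissue (pools 100-300 nm across,
#' channels below 100 nm).
#'
#' @param nPools number of pools (>= 1).
#' @param poolRadiusRange numeric length-2, pool radius range (nm).
#' @param channelWidthRange numeric length-2, channel width range (nm).
#' @param domain numeric length-2, field extent (nm).
#' @param gapRange numeric length-2, boundary-to-boundary pool spacing
#'   range (nm) used when placing successive pools.
#' @param seed integer seed; identical seeds give identical geometries.
#' @param maxAttempts rejection-sampling cap per pool placement.
#' @return a \linkS4class{SceneGeometry}.
#' @examples
#' g <- generateGeometry(3, seed = 1)
#' insideGeometry(g, g@pools[1, "cx"], g@pools[1, "cy"])
#' @export
generateGeometry <- function(nPools,
                             poolRadiusRange = c(50, 150),
                             channelWidthRange = c(40, 100),
                             domain = c(5000, 5000),
                             gapRange = c(200, 600),
                             seed = 1L,
                             maxAttempts = 1000L) {
  if (nPools < 1L) stop("nPools must be >= 1")
  if (any(poolRadiusRange <= 0) || any(channelWidthRange <= 0))
    stop("radius and width ranges must be positive")
  set.seed(seed)
  pools <- matrix(NA_real_, nPools, 3,
                  dimnames = list(NULL, c("cx", "cy", "r")))
  channels <- matrix(numeric(0), 0, 5,
                     dimnames = list(NULL, c("x1", "y1", "x2", "y2", "width")))
  pools[1, ] <- c(domain / 2,
                  stats::runif(1, poolRadiusRange[1], poolRadiusRange[2]))
  if (nPools > 1L) {
    for (i in 2:nPools) {
      r <- stats::runif(1, poolRadiusRange[1], poolRadiusRange[2])
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        j <- sample.int(i - 1L, 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        gap <- stats::runif(1, gapRange[1], gapRange[2])
        d <- pools[j, "r"] + gap + r
        cx <- pools[j, "cx"] + d * cos(ang)
        cy <- pools[j, "cy"] + d * sin(ang)
        margin <- r + 10
        if (cx < margin || cy < margin ||
            cx > domain[1] - margin || cy > domain[2] - margin) next
        prev <- pools[seq_len(i - 1L), , drop = FALSE]
        if (any(sqrt((prev[, "cx"] - cx)^2 + (prev[, "cy"] - cy)^2) <
                prev[, "r"] + r + 20)) next
        pools[i, ] <- c(cx, cy, r)
        w <- stats::runif(1, channelWidthRange[1], channelWidthRange[2])
        channels <- rbind(channels,
                          c(pools[j, "cx"], pools[j, "cy"], cx, cy, w))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("geometry placement failed after ", maxAttempts,
             " attempts; enlarge the domain or reduce nPools")
    }
  }
  colnames(channels) <- c("x1", "y1", "x2", "y2", "width")
  new("SceneGeometry", pools = pools, channels = channels,
      domain = as.numeric(domain), resolution = 5)
}

#' Signed distance to the geometry boundary
#'
#' Negative inside the union of pools and channels, positive outside;
#' magnitude is the Euclidean distance to the nearest boundary. Vectorised
#' over points.
#'
#' @param geom a \linkS4class{SceneGeometry}, or NULL for free space
#'   (always -Inf, i.e. inside).
#' @param x,y numeric vectors of coordinates (nm).
#' @return numeric vector of signed distances (nm).
#' @export
signedDistance <- function(geom, x, y) {
  if (is.null(geom)) return(rep(-Inf, length(x)))
  p <- geom@pools
  d <- Reduce(pmin, lapply(seq_len(nrow(p)), function(i)
    sqrt((x - p[i, "cx"])^2 + (y - p[i, "cy"])^2) - p[i, "r"]))
  ch <- geom@channels
  if (nrow(ch)) {
    for (i in seq_len(nrow(ch))) {
      ax <- ch[i, "x1"]; ay <- ch[i, "y1"]
      bx <- ch[i, "x2"]; by <- ch[i, "y2"]
      vx <- bx - ax; vy <- by - ay
      len2 <- vx^2 + vy^2
      t <- pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
      dseg <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
      d <- pmin(d, dseg - ch[i, "width"] / 2)
    }
  }
  d
}

#' Inside-geometry predicate
#'
#' @inheritParams signedDistance
#' @return logical vector, TRUE where (x, y) lies inside the union of
#'   pools and channels.
#' @export
insideGeometry <- function(geom, x, y) signedDistance(geom, x, y) <= 0

# Outward boundary normal by central differences of the signed distance.
#' @noRd
.sdfNormal <- function(geom, x, y, h = 0.05) {
  gx <- (signedDistance(geom, x + h, y) - signedDistance(geom, x - h, y)) / (2 * h)
  gy <- (signedDistance(geom, x, y + h) - signedDistance(geom, x, y - h)) / (2 * h)
  n <- sqrt(gx^2 + gy^2)
  if (n < 1e-12) c(1, 0) else c(gx, gy) / n
}

#' Simulate a confined Brownian walker
#'
#' Reflected Brownian motion of a rod probe inside a scene geometry, with
#' locally varying diffusivity. Per-axis increments are drawn as
#' Normal(0, 2 D(x) dt) using the diffusivity at the step's start, then
#' reflected specularly against the geometry boundary (re-applied until
#' the point is inside), which preserves a uniform equilibrium density.
#' Probe orientation follows the channel axis inside channels and slow
#' rotational diffusion in pools.
#'
#' @param geom a \linkS4class{SceneGeometry}, or NULL for unconfined
#'   motion.
#' @param D diffusivity (nm^2/s): a scalar or a function of (x, y)
#'   returning the local diffusivity.
#' @param nSteps number of steps; the track has nSteps + 1 positions.
#' @param dt step interval (s), default 0.030.
#' @param seed integer seed.
#' @param start numeric length-2 start position (nm); defaults to the
#'   first pool centre (or the origin if unconfined). Must be inside.
#' @param probeLength rod length (nm), default 500.
#' @param rotDiff rotational diffusivity in pools (rad^2/s).
#' @return a \linkS4class{TruthTrack}.
#' @examples
#' trk <- simulateWalker(NULL, D = 1e6, nSteps = 100, seed = 2)
#' @export
simulateWalker <- function(geom, D, nSteps, dt = 0.030, seed = 1L,
                           start = NULL, probeLength = 500,
                           rotDiff = 5) {
  .chkScalar(dt, "dt")
  if (is.null(start))
    start <- if (is.null(geom)) c(0, 0) else
      unname(geom@pools[1, c("cx", "cy")])
  if (!is.null(geom) && !insideGeometry(geom, start[1], start[2]))
    stop("start point lies outside the geometry")
  Dfun <- if (is.function(D)) D else function(x, y) D
  if (Dfun(start[1], start[2]) <= 0 && !is.function(D))
    stopifnot(D >= 0)
  set.seed(seed)
  n <- nSteps + 1L
  pos <- matrix(NA_real_, n, 2)
  dTrue <- numeric(n)
  orient <- numeric(n)
  pos[1, ] <- start
  orient[1] <- stats::runif(1, 0, pi)
  dTrue[1] <- Dfun(start[1], start[2])
  for (k in seq_len(nSteps)) {
    cur <- pos[k, ]
    Dl <- Dfun(cur[1], cur[2])
    dTrue[k] <- Dl
    sd <- sqrt(2 * max(Dl, 0) * dt)
    prop <- cur + stats::rnorm(2, 0, sd)
    if (!is.null(geom)) {
      iter <- 0L
      while (signedDistance(geom, prop[1], prop[2]) > 0 && iter < 20L) {
        s <- signedDistance(geom, prop[1], prop[2])
        nv <- .sdfNormal(geom, prop[1], prop[2])
        prop <- prop - 2 * s * nv          # specular fold across boundary
        iter <- iter + 1L
      }
      if (signedDistance(geom, prop[1], prop[2]) > 0) prop <- cur
    }
    pos[k + 1L, ] <- prop
    orient[k + 1L] <- .probeOrientation(geom, prop, orient[k], rotDiff, dt)
  }
  dTrue[n] <- Dfun(pos[n, 1], pos[n, 2])
  new("TruthTrack", positions = pos, dt = dt, dTrue = dTrue,
      probeLength = probeLength, orientation = orient %% pi)
}

# Orientation model: channel axis when the nearest primitive is a channel,
# rotational diffusion otherwise. A stand-in (tissue rod rotation is not
# characterised); see the methods vignette.
#' @noRd
.probeOrientation <- function(geom, p, prev, rotDiff, dt) {
  if (!is.null(geom) && nrow(geom@channels)) {
    ch <- geom@channels
    pools <- geom@pools
    dPool <- min(sqrt((p[1] - pools[, "cx"])^2 + (p[2] - pools[, "cy"])^2) -
                   pools[, "r"])
    for (i in seq_len(nrow(ch))) {
      ax <- ch[i, "x1"]; ay <- ch[i, "y1"]
      bx <- ch[i, "x2"]; by <- ch[i, "y2"]
      vx <- bx - ax; vy <- by - ay
      len2 <- vx^2 + vy^2
      t <- min(1, max(0, ((p[1] - ax) * vx + (p[2] - ay) * vy) / len2))
      dseg <- sqrt((p[1] - (ax + t * vx))^2 + (p[2] - (ay + t * vy))^2) -
        ch[i, "width"] / 2
      if (dseg <= 0 && dseg < dPool)
        return(atan2(vy, vx) %% pi)
    }
  }
  (prev + stats::rnorm(1, 0, sqrt(2 * rotDiff * dt))) %% pi
}

#' Render a synthetic single-emitter movie
#'
#' Forward model of the near-infrared recordings: per frame, the emitter
#' is drawn as an asymmetric 2D Gaussian whose major-axis footprint is the
#' probe length elongated by the exciton diffusion length (~100 nm) and
#' blurred by the optical PSF, placed at the true position plus the
#' injected drift. The expected image (background + emitter) receives
#' Poisson shot noise, then Gaussian read noise, then gain. A ground-truth
#' table accompanies the movie.
#'
#' @param track a \linkS4class{TruthTrack}.
#' @param cam a \linkS4class{CameraModel}.
#' @param drift numeric matrix (frames x 2) of global drift in px, or NULL
#'   for none.
#' @param fov integer length-2, field of view in px (rows, cols).
#' @param psfFwhm optical PSF full width at half maximum (nm).
#' @param excitonLength apparent emission elongation of the nanotube (nm).
#' @param noise logical; FALSE renders the noise-free expected movie.
#' @param seed integer seed for the noise.
#' @return list with \code{movie} (array rows x cols x frames, in camera
#'   counts), \code{truth} (data.frame: frame, x_nm, y_nm, D_true,
#'   length_nm, drift_x_px, drift_y_px, visible), and \code{cam}.
#' @export
renderMovie <- function(track, cam, drift = NULL, fov = c(32L, 32L),
                        psfFwhm = 450, excitonLength = 100,
                        noise = TRUE, seed = 1L) {
  stopifnot(is(track, "TruthTrack"), is(cam, "CameraModel"))
  nF <- nrow(track@positions)
  if (is.null(drift)) drift <- matrix(0, nF, 2)
  if (nrow(drift) != nF)
    stop("drift must have one row per frame (", nF, ")")
  px <- cam@pixelSize
  apparentMajFwhm <- sqrt((track@probeLength + excitonLength)^2 + psfFwhm^2)
  sMaj <- .fwhmToSigma(apparentMajFwhm)
  sMin <- .fwhmToSigma(psfFwhm)
  peak <- cam@photons / (2 * pi * sMaj * sMin / px^2)  # counts at the mode
  xs <- .pxToNm(seq_len(fov[2]), px)
  ys <- .pxToNm(seq_len(fov[1]), px)
  movie <- array(0, c(fov[1], fov[2], nF))
  visible <- logical(nF)
  set.seed(seed)
  for (f in seq_len(nF)) {
    ex <- track@positions[f, 1] + drift[f, 1] * px
    ey <- track@positions[f, 2] + drift[f, 2] * px
    visible[f] <- ex >= xs[1] && ex <= xs[length(xs)] &&
      ey >= ys[1] && ey <= ys[length(ys)]
    expected <- matrix(cam@background, fov[1], fov[2])
    if (visible[f])
      expected <- .asymGauss(xs, ys, ex, ey, sMaj, sMin,
                             track@orientation[f], peak, cam@background)
    frame <- if (noise) {
      shot <- matrix(stats::rpois(length(expected), expected),
                     fov[1], fov[2])
      (shot + matrix(stats::rnorm(length(expected), 0, cam@readNoise),
                     fov[1], fov[2])) * cam@gain
    } else expected * cam@gain
    movie[, , f] <- frame
  }
  truth <- data.frame(
    frame = seq_len(nF),
    x_nm = track@positions[, 1], y_nm = track@positions[, 2],
    D_true = track@dTrue, length_nm = track@probeLength,
    drift_x_px = drift[, 1], drift_y_px = drift[, 2],
    visible = visible)
  list(movie = movie, truth = truth, cam = cam)
}

#' Generate an EM-like binary ECS mask with known truth
#'
#' Two morphologies are available. \code{"packing"} emulates cell packing:
#' Voronoi-like cells whose boundaries are opened into ECS sheets of a
#' nominal gap width, found by bisection so the foreground fraction hits
#' the target within 0.5 percentage points; straight cell-cell boundaries
#' carry that nominal width while cell junctions are wider, reproducing
#' the channels-and-pools configuration. \code{"stripes"} draws
#' parallel straight compartments whose widths are drawn from
#' \code{widthsNm}, giving an exactly known width field for recovery
#' tests. The achieved volume fraction recorded in the truth equals the
#' measured foreground fraction exactly.
#'
#' @param targetFraction target ECS volume fraction in (0, 1); tissue
#'   values run about 0.15-0.24.
#' @param mode \code{"packing"} or \code{"stripes"}.
#' @param widthsNm candidate compartment widths (nm) for stripes mode.
#' @param dim integer length-2 mask size (px).
#' @param pixelSizeNm physical pixel size (nm), default 1.42 (EM scale).
#' @param nCells number of packing seeds (packing mode).
#' @param seed integer seed.
#' @return list with \code{mask} (an \linkS4class{EcsMask}) and
#'   \code{truth} (a \linkS4class{MaskTruth}).
#' @export
generateEcsMask <- function(targetFraction, mode = c("packing", "stripes"),
                            widthsNm = c(50, 80, 120, 180, 250),
                            dim = c(256L, 256L), pixelSizeNm = 1.42,
                            nCells = 25L, seed = 1L) {
  mode <- match.arg(mode)
  if (targetFraction <= 0 || targetFraction >= 1)
    stop("targetFraction must be in (0, 1)")
  set.seed(seed)
  nr <- dim[1]; nc <- dim[2]
  if (mode == "packing") {
    # build the cell packing on a padded canvas and crop the interior, so
    # no image border cuts a cell open (border pixels would otherwise be
    # spuriously far from their second-nearest seed)
    pad <- ceiling(min(nr, nc) / 3)
    nrP <- nr + 2L * pad; ncP <- nc + 2L * pad
    nSeeds <- max(4L, round(nCells * (nrP * ncP) / (nr * nc)))
    sx <- stats::runif(nSeeds, 1, ncP)
    sy <- stats::runif(nSeeds, 1, nrP)
    cols <- matrix(rep(seq_len(ncP), each = nrP), nrP, ncP)
    rows <- matrix(rep(seq_len(nrP), ncP), nrP, ncP)
    d1 <- matrix(Inf, nrP, ncP); d2 <- matrix(Inf, nrP, ncP)
    for (i in seq_len(nSeeds)) {
      di <- sqrt((cols - sx[i])^2 + (rows - sy[i])^2)
      smaller <- di < d1
      d2 <- ifelse(smaller, d1, pmin(d2, di))
      d1 <- ifelse(smaller, di, d1)
    }
    margin <- (d2 - d1)[pad + seq_len(nr), pad + seq_len(nc)]
    fracAt <- function(t) mean(margin < t)
    lo <- 0; hi <- max(margin)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (fracAt(mid) < targetFraction) lo <- mid else hi <- mid
    }
    gap <- hi
    if (abs(fracAt(gap) - targetFraction) > 0.005)
      stop("target volume fraction unachievable for this packing")
    mask <- (margin < gap) * 1
    widthField <- mask * gap * pixelSizeNm  # nominal uniform width
  } else {
    targetPx <- as.integer(round(targetFraction * nr * nc))
    wPx <- pmax(1L, as.integer(round(widthsNm / pixelSizeNm)))
    # plan the stripe heights first, then distribute the leftover rows as
    # uniform separations and trim the last stripe to the exact pixel count
    heights <- integer(0)
    while (sum(heights) * nc < targetPx)
      heights <- c(heights, wPx[sample.int(length(wPx), 1L)])
    n <- length(heights)
    sepTotal <- nr - sum(heights)
    if (sepTotal < 2L * (n + 1L))
      stop("target volume fraction unachievable for this stripe spec")
    sep <- sepTotal %/% (n + 1L)
    mask <- matrix(0, nr, nc)
    widthField <- matrix(0, nr, nc)
    row <- 1L + sep
    placed <- 0L
    for (i in seq_len(n)) {
      w <- heights[i]
      rows <- row:(row + w - 1L)
      need <- targetPx - placed
      len <- min(nc, ceiling(need / w))
      mask[rows, seq_len(len)] <- 1
      widthField[rows, seq_len(len)] <- w * pixelSizeNm
      excess <- w * len - need
      if (excess > 0L) {                   # trim the last partial column
        drop <- rows[seq_len(excess)]
        mask[drop, len] <- 0
        widthField[drop, len] <- 0
      }
      placed <- placed + w * len - max(excess, 0L)
      row <- row + w + sep
    }
    stopifnot(sum(mask) == targetPx)
  }
  truth <- new("MaskTruth", volumeFraction = mean(mask > 0),
               widthField = widthField, pixelSize = pixelSizeNm)
  list(mask = new("EcsMask", mask = mask, pixelSize = pixelSizeNm),
       truth = truth)
}

#' Deterministic reference rasters for fractal-dimension checks
#'
#' Known-dimension binary images: a straight line (dimension 1), a filled
#' square (dimension 2), and the Sierpinski triangle
#' (log 3 / log 2 = 1.585). The Sierpinski raster uses the bitwise-AND
#' construction, which makes box counts at power-of-two box sizes exact.
#'
#' @param kind one of \code{"line"}, \code{"filled_square"},
#'   \code{"sierpinski"}.
#' @param levels dyadic levels; the image is 2^levels on a side.
#'   Sierpinski requires levels >= 3.
#' @return binary matrix.
#' @export
generateReferenceFractal <- function(kind = c("line", "filled_square",
                                              "sierpinski"),
                                     levels = 6L) {
  kind <- match.arg(kind)
  n <- 2L^levels
  switch(kind,
    line = { m <- matrix(0, n, n); m[n %/% 2L, ] <- 1; m },
    filled_square = matrix(1, n, n),
    sierpinski = {
      if (levels < 3L) stop("sierpinski requires levels >= 3")
      idx <- 0:(n - 1L)
      outer(idx, idx, function(i, j) as.numeric(bitwAnd(i, j) == 0L))
    })
}

#' Write a movie as a multi-page 16-bit TIFF
#'
#' Counts are clamped to [0, 65535] and stored as 16-bit integers.
#' @param movie array rows x cols x frames (camera counts).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMovieTIFF <- function(movie, path) {
  frames <- lapply(seq_len(dim(movie)[3]), function(f) {
    m <- movie[, , f]
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file.
#' @param scale value a full-scale pixel maps to (default 65535, the
#'   inverse of \code{writeMovieTIFF}).
#' @return array rows x cols x frames.
#' @export
readMovieTIFF <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  array(unlist(pages), c(dim(pages[[1]]), length(pages))) * scale
}
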
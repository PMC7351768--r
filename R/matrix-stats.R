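# Matrix-network morphometry, stereology arithmetic, and the study's
# statistical comparisons.

#' Stained-area fraction of a grayscale image
#'
#' Percentage of (ROI) pixels whose intensity exceeds an automatic
#' threshold, optionally after subtracting a background reference value
#' (e.g. the mean gray value of an unstained contralateral field, clipped
#' at zero). The default thresholding criterion is Otsu's method.
#'
#' @param image numeric matrix (grayscale).
#' @param method thresholding method; \code{"otsu"} (default) or a
#'   numeric threshold value.
#' @param roi optional binary matrix restricting the measurement.
#' @param backgroundReference optional scalar subtracted from the image
#'   (negatives clipped at 0) before thresholding.
#' @return percentage in [0, 100].
#' @export
areaFraction <- function(image, method = "otsu", roi = NULL,
                         backgroundReference = NULL) {
  img <- image
  if (!is.null(backgroundReference))
    img <- pmax(img - backgroundReference, 0)
  sel <- if (is.null(roi)) rep(TRUE, length(img)) else as.vector(roi > 0)
  if (!any(sel)) stop("empty ROI")
  v <- as.vector(img)[sel]
  if (max(v) == min(v)) return(if (max(v) > 0) 100 else 0)
  thr <- if (is.numeric(method)) method else {
    rng <- range(v)
    norm <- matrix((v - rng[1]) / (rng[2] - rng[1]), ncol = 1)
    EBImage::otsu(norm, range = c(0, 1)) * (rng[2] - rng[1]) + rng[1]
  }
  100 * mean(v > thr)
}

#' Box-counting fractal dimension
#'
#' Least-squares slope of log N(s) versus log(1/s) over a dyadic series of
#' box sizes (2 px up to a quarter of the image side), using a single grid
#' origin at the image corner. For planar binary images the estimate lies
#' in [0, 2]: about 1 for curves, 2 for filled areas, log 3 / log 2 for
#' the Sierpinski triangle.
#'
#' @param image binary matrix (nonzero = foreground).
#' @param boxSizes box edge lengths (px); default powers of 2 from 2 to
#'   min(nrow, ncol)/4. At least 4 sizes are required.
#' @return list: \code{dimension}, \code{table} (data.frame of box size
#'   and count), \code{fit} (the lm object).
#' @export
boxCountingDimension <- function(image, boxSizes = NULL) {
  m <- (image > 0) * 1
  if (!any(m > 0)) stop("empty foreground")
  if (is.null(boxSizes)) {
    maxS <- min(dim(m)) / 4
    boxSizes <- 2^(1:floor(log2(maxS)))
  }
  if (length(boxSizes) < 4L)
    stop("need at least 4 box sizes (image too small)")
  fgIdx <- which(m > 0, arr.ind = TRUE)
  counts <- vapply(boxSizes, function(s) {
    br <- (fgIdx[, 1] - 1L) %/% s
    bc <- (fgIdx[, 2] - 1L) %/% s
    length(unique(br * (max(bc) + 1L + 1L) + bc))
  }, numeric(1))
  if (all(counts == 1))
    stop("foreground fits in a single box at every size")
  tab <- data.frame(box_px = boxSizes, n_boxes = counts)
  fit <- stats::lm(log(n_boxes) ~ I(log(1 / box_px)), data = tab)
  list(dimension = unname(stats::coef(fit)[2]), table = tab, fit = fit)
}

#' Skeleton length distribution of a stained network
#'
#' Lengths of the cables of a binarised network image: the image
#' (optionally restricted to an ROI mask) is skeletonized per connected
#' component and each component's longest shortest path is reported, via
#' the same machinery as the EM compartment lengths.
#'
#' @param image binary matrix (nonzero = foreground).
#' @param pixelSizeNm pixel size (nm).
#' @param roi optional binary matrix; pixels outside are dropped.
#' @return data.frame as from \code{\link{compartmentLengths}}.
#' @export
skeletonLengthDistribution <- function(image, pixelSizeNm = 100,
                                       roi = NULL) {
  m <- (image > 0) * 1
  if (!is.null(roi)) m <- m * (roi > 0)
  compartmentLengths(m, pixelSizeNm = pixelSizeNm)
}

#' Optical fractionator estimate
#'
#' Unbiased stereological cell count: N = sum(Q-) x 1/ssf x 1/asf x t/h,
#' with sum(Q-) the objects counted, ssf the section sampling fraction,
#' asf the area sampling fraction, t the actual section thickness and h
#' the dissector height.
#'
#' @param sumQ number of objects counted (> 0).
#' @param ssf section sampling fraction, in (0, 1].
#' @param asf area sampling fraction, in (0, 1].
#' @param t section thickness (um).
#' @param h dissector height (um); must not exceed t.
#' @return list: \code{N} (exact), \code{N_rounded} (nearest integer).
#' @examples
#' fractionatorEstimate(100, 1/4, 1/2, 40, 10)$N  # 3200
#' @export
fractionatorEstimate <- function(sumQ, ssf, asf, t, h) {
  for (v in list(sumQ = sumQ, ssf = ssf, asf = asf, t = t, h = h))
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("all fractionator parameters must be positive scalars")
  if (ssf > 1 || asf > 1) stop("ssf and asf must be in (0, 1]")
  if (h > t) stop("dissector height h exceeds section thickness t")
  N <- sumQ * (1 / ssf) * (1 / asf) * (t / h)
  list(N = N, N_rounded = as.integer(round(N)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_a - ECDF_b| with an exact p-value for small samples and
#' the asymptotic approximation for large ones (the usual practice for
#' large continuous datasets).
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param exact logical or NULL (NULL = automatic, exact when n*m is
#'   small and there are no ties).
#' @return list: \code{statistic} (D), \code{p.value}, \code{exact}.
#' @export
ksTwoSample <- function(a, b, exact = NULL) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample must have >= 2 values")
  ht <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       exact = grepl("^Exact", ht$method))
}

#' Summarize a continuous distribution
#'
#' Relative frequency or cumulative distribution table plus median and
#' interquartile range (linear-interpolation quartile convention,
#' \code{stats::quantile} type 7).
#'
#' @param values numeric vector (>= 1 value).
#' @param kind \code{"frequency"} (normalized histogram) or
#'   \code{"cumulative"} (ECDF at the sorted values).
#' @param bins number of histogram bins (frequency mode).
#' @return list: \code{table} (data.frame), \code{median}, \code{iqr}
#'   (length-2: 25% and 75% quantiles), \code{n}.
#' @export
summarizeDistribution <- function(values, kind = c("frequency", "cumulative"),
                                  bins = 30L) {
  kind <- match.arg(kind)
  if (!length(values)) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tab <- if (kind == "frequency") {
    h <- graphics::hist(values, breaks = bins, plot = FALSE)
    data.frame(mid = h$mids, rel_freq = h$counts / sum(h$counts),
               density = h$density)
  } else {
    s <- sort(values)
    data.frame(value = s, ecdf = seq_along(s) / length(s))
  }
  list(table = tab, median = q[2], iqr = q[c(1, 3)], n = length(values))
}
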
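#' @import methods
NULL

#' Scene geometry: channels-and-pools ECS model
#'
#' Planar geometry describing the extracellular space as an arrangement of
#' circular pools (100-300 nm voids) connected by narrow channels
#' (< 100 nm), the configuration observed in cryofixed brain tissue.
#' Pools are discs; channels are capsules (segments with a width). The
#' union is connected by construction: every channel endpoint is a pool
#' centre.
#'
#' @slot pools numeric matrix with columns \code{cx}, \code{cy}, \code{r}
#'   (nm); one row per pool.
#' @slot channels numeric matrix with columns \code{x1}, \code{y1},
#'   \code{x2}, \code{y2}, \code{width} (nm); zero rows allowed.
#' @slot domain numeric length-2, extent of the field (nm).
#' @slot resolution numeric, raster pitch (nm) used when the geometry is
#'   rasterised for inside tests and occupancy checks.
#' @exportClass SceneGeometry
setClass("SceneGeometry",
  representation(pools = "matrix", channels = "matrix",
                 domain = "numeric", resolution = "numeric"),
  validity = function(object) {
    p <- object@pools; ch <- object@channels
    if (nrow(p) < 1L) return("at least one pool is required")
    if (any(p[, "r"] <= 0)) return("pool radii must be > 0")
    if (nrow(ch)) {
      if (any(ch[, "width"] <= 0)) return("channel widths must be > 0")
      insidePool <- function(x, y)
        any(sqrt((p[, "cx"] - x)^2 + (p[, "cy"] - y)^2) <= p[, "r"] + 1e-9)
      for (i in seq_len(nrow(ch))) {
        if (!insidePool(ch[i, "x1"], ch[i, "y1"]) ||
            !insidePool(ch[i, "x2"], ch[i, "y2"]))
          return("every channel endpoint must lie inside a pool")
      }
    }
    if (length(object@domain) != 2L || any(object@domain <= 0))
      return("domain must be two positive extents (nm)")
    if (object@resolution <= 0) return("resolution must be > 0")
    TRUE
  })

#' Ground-truth walker track
#'
#' Time-ordered true positions of one simulated probe, with the local true
#' diffusivity at each step, the probe length and its orientation. Serves
#' as the oracle for parameter-recovery tests of the tracking, diffusivity
#' and dimension estimators.
#'
#' @slot positions numeric matrix (n x 2), true positions (nm).
#' @slot dt numeric, constant step interval (s).
#' @slot dTrue numeric length n, local true diffusivity at each position
#'   (nm^2/s).
#' @slot probeLength numeric, rod length (nm).
#' @slot orientation numeric length n, probe major-axis angle (rad).
#' @exportClass TruthTrack
setClass("TruthTrack",
  representation(positions = "matrix", dt = "numeric", dTrue = "numeric",
                 probeLength = "numeric", orientation = "numeric"),
  validity = function(object) {
    n <- nrow(object@positions)
    if (ncol(object@positions) != 2L) return("positions must be n x 2")
    if (object@dt <= 0) return("dt must be > 0")
    if (length(object@dTrue) != n) return("dTrue must match positions")
    if (length(object@orientation) != n) return("orientation must match positions")
    if (object@probeLength < 0) return("probeLength must be >= 0")
    TRUE
  })

#' EM-CCD camera forward model
#'
#' Parameters of the camera model used to render synthetic movies: expected
#' photons are Poisson distributed, Gaussian read noise is added, then the
#' electron gain is applied.
#'
#' @slot pixelSize numeric, image pixel size (nm).
#' @slot exposure numeric, exposure time (s); default 0.030.
#' @slot photons numeric, expected total detected photons per frame from
#'   one emitter.
#' @slot background numeric, expected background photons per pixel.
#' @slot gain numeric, multiplicative gain applied after noise.
#' @slot readNoise numeric, read noise standard deviation (photons).
#' @exportClass CameraModel
setClass("CameraModel",
  representation(pixelSize = "numeric", exposure = "numeric",
                 photons = "numeric", background = "numeric",
                 gain = "numeric", readNoise = "numeric"),
  prototype(pixelSize = 100, exposure = 0.030, photons = 1e4,
            background = 10, gain = 1, readNoise = 1),
  validity = function(object) {
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    if (object@exposure <= 0) return("exposure must be > 0")
    if (object@photons < 0 || object@background < 0 ||
        object@gain <= 0 || object@readNoise < 0)
      return("photons/background >= 0, gain > 0, readNoise >= 0")
    TRUE
  })

#' Per-frame drift estimate
#'
#' Result of the redundant cross-correlation (RCC) solver: one 2D drift
#' vector per frame, gauge-fixed so the first frame has zero drift, with
#' the number of non-outlier pairwise equations that supported each frame.
#'
#' @slot drift numeric matrix (T x 2), drift in px, columns \code{rx},
#'   \code{ry}; first row is (0, 0).
#' @slot nEquations integer length T, non-outlier equation count per frame.
#' @slot smoothingWindow integer, moving-average window used (frames).
#' @exportClass DriftSeries
setClass("DriftSeries",
  representation(drift = "matrix", nEquations = "integer",
                 smoothingWindow = "integer"),
  validity = function(object) {
    if (ncol(object@drift) != 2L) return("drift must be T x 2")
    if (nrow(object@drift) < 1L) return("drift must have >= 1 frame")
    if (max(abs(object@drift[1L, ])) > 1e-9)
      return("gauge violated: drift at frame 1 must be (0, 0)")
    if (length(object@nEquations) != nrow(object@drift))
      return("nEquations must have one entry per frame")
    TRUE
  })

#' Super-resolved raster map
#'
#' A 25 nm-pitch (by default) raster built from localizations, carrying
#' either a localization density (sum of unit-amplitude Gaussians) or a
#' locally averaged value (relative diffusivity, local ECS width). Pixels
#' never reached by any localization are NA in \code{mean_value} mode.
#'
#' @slot values numeric matrix, map values (row = y, col = x).
#' @slot weights numeric matrix, accumulated Gaussian weight per pixel.
#' @slot pixelSize numeric, map pixel size (nm).
#' @slot origin numeric length-2, (x, y) nm of the centre of pixel [1, 1].
#' @slot mode character, \code{"density"} or \code{"mean_value"}.
#' @exportClass SuperResolvedMap
setClass("SuperResolvedMap",
  representation(values = "matrix", weights = "matrix",
                 pixelSize = "numeric", origin = "numeric",
                 mode = "character"),
  validity = function(object) {
    if (!object@mode %in% c("density", "mean_value"))
      return("mode must be 'density' or 'mean_value'")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    if (!all(dim(object@values) == dim(object@weights)))
      return("values and weights must share dimensions")
    TRUE
  })

#' Binary ECS mask
#'
#' Binarised segmentation of the extracellular space (foreground = ECS)
#' with its physical pixel size; EM-scale masks default to 1.42 nm/px.
#'
#' @slot mask numeric matrix of 0/1.
#' @slot pixelSize numeric, pixel size (nm).
#' @exportClass EcsMask
setClass("EcsMask",
  representation(mask = "matrix", pixelSize = "numeric"),
  prototype(pixelSize = 1.42),
  validity = function(object) {
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    v <- unique(as.vector(object@mask))
    if (!all(v %in% c(0, 1))) return("mask must be binary (0/1)")
    TRUE
  })

#' Ground truth for a generated ECS mask
#'
#' @slot volumeFraction numeric in [0, 1]; equals foreground count divided
#'   by total count of the generated mask, exactly.
#' @slot widthField numeric matrix, nominal true local width (nm) at each
#'   foreground pixel, 0 elsewhere.
#' @slot pixelSize numeric (nm).
#' @exportClass MaskTruth
setClass("MaskTruth",
  representation(volumeFraction = "numeric", widthField = "matrix",
                 pixelSize = "numeric"),
  validity = function(object) {
    if (object@volumeFraction < 0 || object@volumeFraction > 1)
      return("volumeFraction must be in [0, 1]")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    TRUE
  })

#' Reference medium for the rod free-diffusion coefficient
#'
#' Physical constants entering the rod translational diffusion formula
#' D_ref = 3 kB T ln(2 phi) / (8 pi eta L): recording temperature,
#' reference (cerebrospinal-fluid-like) viscosity, and the rod diameter
#' fixing the aspect ratio phi = L / diameter.
#'
#' @slot temperature numeric, K (default 310.15, i.e. 37 C).
#' @slot viscosity numeric, Pa s (default 0.70e-3).
#' @slot diameter numeric, rod diameter (nm), default 1.
#' @slot kB numeric, Boltzmann constant (J/K), CODATA exact value.
#' @exportClass ReferenceMedium
setClass("ReferenceMedium",
  representation(temperature = "numeric", viscosity = "numeric",
                 diameter = "numeric", kB = "numeric"),
  prototype(temperature = 310.15, viscosity = 0.70e-3, diameter = 1,
            kB = 1.380649e-23),
  validity = function(object) {
    if (any(c(object@temperature, object@viscosity, object@diameter,
              object@kB) <= 0))
      return("all medium parameters must be > 0")
    TRUE
  })
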
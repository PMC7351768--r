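# Generics and accessors for the package's S4 containers.

#' Pixel size accessor
#'
#' Physical pixel size in nm of a raster-carrying object.
#' @param object a \linkS4class{SuperResolvedMap}, \linkS4class{EcsMask},
#'   \linkS4class{CameraModel} or \linkS4class{MaskTruth}.
#' @return numeric scalar (nm).
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "SuperResolvedMap", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "EcsMask", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "CameraModel", function(object) object@pixelSize)
#' @rdname pixelSize
#' @export
setMethod("pixelSize", "MaskTruth", function(object) object@pixelSize)

#' Map values accessor
#'
#' The raster of a \linkS4class{SuperResolvedMap} (row = y, col = x;
#' NA where the map is undefined in \code{mean_value} mode).
#' @param object a \linkS4class{SuperResolvedMap}.
#' @return numeric matrix.
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname mapValues
#' @export
setMethod("mapValues", "SuperResolvedMap", function(object) object@values)

#' Binary mask accessor
#' @param object an \linkS4class{EcsMask}.
#' @return 0/1 numeric matrix.
#' @export
setGeneric("maskPixels", function(object) standardGeneric("maskPixels"))
#' @rdname maskPixels
#' @export
setMethod("maskPixels", "EcsMask", function(object) object@mask)

#' Drift estimate accessor
#' @param object a \linkS4class{DriftSeries}.
#' @return T x 2 numeric matrix of per-frame drift (px).
#' @export
setGeneric("driftEstimate", function(object) standardGeneric("driftEstimate"))
#' @rdname driftEstimate
#' @export
setMethod("driftEstimate", "DriftSeries", function(object) object@drift)

#' Track positions accessor
#' @param object a \linkS4class{TruthTrack}.
#' @return n x 2 numeric matrix of positions (nm).
#' @export
setGeneric("trackPositions", function(object) standardGeneric("trackPositions"))
#' @rdname trackPositions
#' @export
setMethod("trackPositions", "TruthTrack", function(object) object@positions)

setMethod("show", "SceneGeometry", function(object) {
  cat("SceneGeometry:", nrow(object@pools), "pool(s),",
      nrow(object@channels), "channel(s); domain",
      paste(round(object@domain), collapse = " x "), "nm\n")
})

setMethod("show", "TruthTrack", function(object) {
  cat("TruthTrack:", nrow(object@positions), "positions, dt =",
      object@dt, "s, probe length", round(object@probeLength), "nm\n")
})

setMethod("show", "DriftSeries", function(object) {
  d <- object@drift
  cat("DriftSeries:", nrow(d), "frames; max |drift| =",
      signif(max(sqrt(rowSums(d^2))), 3), "px; smoothing window",
      object@smoothingWindow, "frames\n")
})

setMethod("show", "SuperResolvedMap", function(object) {
  cat("SuperResolvedMap [", object@mode, "]: ",
      nrow(object@values), " x ", ncol(object@values), " px at ",
      object@pixelSize, " nm/px\n", sep = "")
})

setMethod("show", "EcsMask", function(object) {
  cat("EcsMask:", nrow(object@mask), "x", ncol(object@mask), "px at",
      object@pixelSize, "nm/px; foreground fraction",
      signif(mean(object@mask > 0), 3), "\n")
})

setMethod("show", "CameraModel", function(object) {
  cat("CameraModel:", object@pixelSize, "nm/px,",
      object@exposure * 1e3, "ms exposure,", object@photons,
      "photons/frame, background", object@background, "/px\n")
})

setMethod("show", "ReferenceMedium", function(object) {
  cat("ReferenceMedium: T =", object@temperature, "K, eta =",
      object@viscosity * 1e3, "mPa s, rod diameter",
      object@diameter, "nm\n")
})
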
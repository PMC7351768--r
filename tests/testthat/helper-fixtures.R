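# Programmatic fixtures shared across test files.

# Straight-channel geometry of width w: a capsule whose end pools have
# radius w/2, so the union is exactly the channel.
channelGeometry <- function(widthNm, lengthNm = 8000) {
  pools <- matrix(c(0, 0, widthNm / 2, lengthNm, 0, widthNm / 2), 2, 3,
                  byrow = TRUE, dimnames = list(NULL, c("cx", "cy", "r")))
  ch <- matrix(c(0, 0, lengthNm, 0, widthNm), 1, 5,
               dimnames = list(NULL, c("x1", "y1", "x2", "y2", "width")))
  new("SceneGeometry", pools = pools, channels = ch,
      domain = c(lengthNm, lengthNm), resolution = 5)
}

# TruthTrack positions as a trajectory data.frame.
trackToDf <- function(trk, trajId = 1L, locNoiseNm = 0, noiseSeed = NULL) {
  p <- trackPositions(trk)
  if (locNoiseNm > 0) {
    if (!is.null(noiseSeed)) set.seed(noiseSeed)
    p <- p + matrix(stats::rnorm(length(p), 0, locNoiseNm), nrow(p), 2)
  }
  data.frame(traj_id = trajId, t_index = seq_len(nrow(p)),
             t_s = (seq_len(nrow(p)) - 1) * trk@dt,
             x_nm = p[, 1], y_nm = p[, 2], smaj_nm = NA_real_)
}

# Static-emitter TruthTrack with fixed orientation.
staticTrack <- function(nFrames, x = 1500, y = 1400, lengthNm = 500,
                        theta = 0) {
  new("TruthTrack",
      positions = matrix(rep(c(x, y), each = nFrames), nFrames, 2),
      dt = 0.03, dTrue = rep(0, nFrames), probeLength = lengthNm,
      orientation = rep(theta, nFrames))
}

# Random blob mask: thresholded smoothed noise, moderate foreground.
randomBlobMask <- function(n = 64, seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rbinom(n * n, 1, 0.5), n, n)
  sm <- ecsnano:::.conv2same(base, matrix(1, 5, 5))
  (sm >= 13) * 1
}

defaultCam <- function(...) {
  args <- list(pixelSize = 100, exposure = 0.030, photons = 1e4,
               background = 10, gain = 1, readNoise = 1)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(new, c(list("CameraModel"), args))
}
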
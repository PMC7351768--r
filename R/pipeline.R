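# End-to-end orchestration: simulate -> localize -> drift -> track ->
# maps -> report, driven by a validated YAML configuration.

.configSchema <- list(
  pixel_size_nm = "numeric", exposure_s = "numeric", n_frames = "numeric",
  photons = "numeric", background = "numeric", read_noise = "numeric",
  drift_per_frame_px = "numeric", n_pools = "numeric",
  diffusivity_nm2_s = "numeric", map_pixel_nm = "numeric",
  map_fwhm_nm = "numeric", max_step_nm = "numeric",
  min_track_length = "numeric")

#' Default pipeline configuration
#'
#' All tunables of the demo pipeline with the recording conventions as
#' defaults: 30 ms exposure, 3-frame averaging, 1 px RCC outlier
#' threshold, 450 ms MSD windows with 90 ms fits, 25 nm map pixels with
#' 50 nm FWHM rendering.
#' @return named list.
#' @export
defaultRunConfig <- function() {
  list(pixel_size_nm = 100, exposure_s = 0.030, n_frames = 80,
       photons = 1e4, background = 10, read_noise = 1,
       drift_per_frame_px = 0.02, n_pools = 3,
       diffusivity_nm2_s = 3e5, map_pixel_nm = 25, map_fwhm_nm = 50,
       max_step_nm = 500, min_track_length = 20)
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML config, fills unset fields from
#' \code{\link{defaultRunConfig}}, and validates every field against the
#' schema before any stage runs; unknown or non-numeric fields raise an
#' error immediately.
#'
#' @param path YAML file, or NULL for the defaults.
#' @return validated named list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(.configSchema))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  for (f in names(.configSchema)) {
    if (is.null(cfg[[f]]))
      stop("config field missing: ", f)
    if (!is.numeric(cfg[[f]]) || !is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive number")
  }
  cfg
}

#' Run the full demo pipeline
#'
#' Executes the complete chain on a synthetic scene: geometry + walker
#' simulation, movie rendering with drift, localization, RCC drift
#' estimation and correction, trajectory linking, relative-diffusivity
#' and density maps, and a JSON report. Every intermediate is written to
#' \code{outDir} and checksummed (MD5) in the run manifest, so two runs
#' with the same config and seed are checksum-identical. A stage failure
#' halts with an error naming the stage; earlier outputs are retained.
#'
#' @param config list from \code{\link{readRunConfig}}.
#' @param seed integer master seed.
#' @param outDir output directory (created if needed).
#' @return the manifest (invisibly also written to manifest.json): stage
#'   list, parameters, seed, file checksums.
#' @export
runPipeline <- function(config = readRunConfig(), seed = 1L,
                        outDir = tempfile("ecsnano_run_")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  files <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr),
                    error = function(e) stop("stage '", name, "' failed: ",
                                             conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    res
  }
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  cam <- new("CameraModel", pixelSize = config$pixel_size_nm,
             exposure = config$exposure_s, photons = config$photons,
             background = config$background, gain = 1,
             readNoise = config$read_noise)

  sim <- stage("simulate", {
    geom <- generateGeometry(config$n_pools,
                             poolRadiusRange = c(150, 300),
                             domain = c(2600, 2600),
                             gapRange = c(150, 300),
                             seed = seed)
    trk <- simulateWalker(geom, config$diffusivity_nm2_s,
                          nSteps = config$n_frames - 1,
                          dt = config$exposure_s, seed = seed + 1L)
    nF <- config$n_frames
    drift <- cbind(seq_len(nF), seq_len(nF) / 2) * config$drift_per_frame_px
    drift <- sweep(drift, 2, drift[1, ])
    mv <- renderMovie(trk, cam, drift = drift, fov = c(28L, 40L),
                      seed = seed + 2L)
    # static background features in the right margin, clear of the scene;
    # the drift stage correlates only that region (as one would select an
    # ROI with visible background features on real data)
    bgSpots <- rbind(c(3100, 600), c(3600, 1300), c(3200, 2200))
    px <- cam@pixelSize
    xs <- .pxToNm(seq_len(dim(mv$movie)[2]), px)
    ys <- .pxToNm(seq_len(dim(mv$movie)[1]), px)
    set.seed(seed + 3L)
    for (f in seq_len(nF)) {
      bg <- 0
      for (s in seq_len(nrow(bgSpots)))
        bg <- bg + .asymGauss(xs, ys, bgSpots[s, 1] + drift[f, 1] * px,
                              bgSpots[s, 2] + drift[f, 2] * px,
                              220, 180, 0, 200, 0)
      mv$movie[, , f] <- mv$movie[, , f] +
        matrix(stats::rpois(length(bg), bg), nrow(bg), ncol(bg))
    }
    moviePath <- file.path(outDir, "movie.tif")
    writeMovieTIFF(mv$movie, moviePath)
    files <<- c(files, moviePath)
    emit(mv$truth, "truth.csv")
    list(movie = mv$movie, truth = mv$truth, drift = drift,
         driftRoiCols = 29:40)
  })

  locs <- stage("localize", {
    l <- localizeMovie(sim$movie, pixelSizeNm = cam@pixelSize,
                       exposure = cam@exposure)
    emit(l, "localizations.csv")
    l
  })

  driftEst <- stage("drift", {
    eqs <- pairwiseShifts(sim$movie[, sim$driftRoiCols, , drop = FALSE])
    ds <- solveDrift(eqs, nFrames = dim(sim$movie)[3])
    emit(data.frame(frame = seq_len(nrow(driftEstimate(ds))),
                    rx_px = driftEstimate(ds)[, 1],
                    ry_px = driftEstimate(ds)[, 2],
                    n_eqs = ds@nEquations), "drift.csv")
    ds
  })

  tracks <- stage("track", {
    corrected <- applyDrift(locs[locs$accepted, , drop = FALSE], driftEst,
                            pixelSizeNm = cam@pixelSize)
    linked <- linkTrajectories(corrected, maxStepNm = config$max_step_nm,
                               minLength = config$min_track_length)
    emit(linked, "trajectories.csv")
    linked
  })

  maps <- stage("map", {
    if (!nrow(tracks)) stop("no trajectories to map")
    est <- relativeDiffusivity(splitTrajectories(tracks),
                               excludeImmobile = FALSE)
    emit(est, "diffusivity.csv")
    dens <- makeMap(tracks$x_nm, tracks$y_nm, pixelNm = config$map_pixel_nm,
                    fwhmNm = config$map_fwhm_nm, mode = "density")
    densPath <- file.path(outDir, "density_map.tif")
    dv <- mapValues(dens) / max(1, max(mapValues(dens)))
    tiff::writeTIFF(pmin(pmax(dv, 0), 1), densPath, bits.per.sample = 32L)
    files <<- c(files, densPath)
    list(estimates = est, density = dens)
  })

  report <- stage("report", {
    est <- maps$estimates
    rep <- list(
      n_localizations = sum(locs$accepted),
      n_trajectories = length(unique(tracks$traj_id)),
      median_ratio = if (nrow(est)) stats::median(est$ratio) else NA,
      exploration_area_um2 = explorationArea(maps$density),
      max_drift_px = max(abs(driftEstimate(driftEst))))
    p <- file.path(outDir, "report.json")
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
    files <<- c(files, p)
    rep
  })

  files <- unique(c(files, list.files(outDir, full.names = TRUE)))
  files <- setdiff(files, file.path(outDir, "manifest.json"))
  sums <- tools::md5sum(sort(files))
  manifest <- list(
    package = "ecsnano",
    version = as.character(utils::packageVersion("ecsnano")),
    seed = seed, parameters = config, stages = stages,
    checksums = as.list(sums[!is.na(sums)]))
  names(manifest$checksums) <- basename(names(sums[!is.na(sums)]))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
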
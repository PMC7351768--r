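# Trajectory linking, probe-length estimation, immobile classification.

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking under a maximum step
#' length, with track memory over missed frames. Candidate links are taken
#' in order of increasing distance (ties broken by lowest track id); each
#' localization is used at most once. Tracks unmatched for more than
#' \code{memory} frames are closed; trajectories shorter than
#' \code{minLength} are dropped. Input row order is irrelevant (sorting is
#' internal).
#'
#' @param localizations data.frame with \code{t_index}, \code{t_s},
#'   \code{x_nm}, \code{y_nm} (extra columns are carried through);
#'   rejected localizations (an \code{accepted} column that is FALSE) are
#'   ignored.
#' @param maxStepNm maximum displacement per frame interval (nm). The
#'   default 500 nm is about 3 sigma of the largest per-30 ms step
#'   observed for nanotubes in tissue.
#' @param memory frames a track survives without a match.
#' @param minLength minimum number of localizations per trajectory.
#' @return data.frame of the input columns plus \code{traj_id}, sorted by
#'   (traj_id, t_index).
#' @export
linkTrajectories <- function(localizations, maxStepNm = 500, memory = 3L,
                             minLength = 20L) {
  locs <- localizations
  if ("accepted" %in% names(locs)) locs <- locs[locs$accepted, , drop = FALSE]
  if (!nrow(locs)) { locs$traj_id <- integer(0); return(locs) }
  locs <- locs[order(locs$t_index, locs$x_nm, locs$y_nm), , drop = FALSE]
  locs$traj_id <- NA_integer_
  frames <- sort(unique(locs$t_index))
  # active tracks: id, last x, y, last frame index (in `frames` ordering)
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    t = numeric(0))
  nextId <- 1L
  for (f in frames) {
    rows <- which(locs$t_index == f)
    act <- act[f - act$t <= memory + 1L, , drop = FALSE]
    assignedLoc <- rep(FALSE, length(rows))
    assignedTrk <- rep(FALSE, nrow(act))
    if (nrow(act) && length(rows)) {
      dmat <- outer(act$x, locs$x_nm[rows], "-")^2 +
              outer(act$y, locs$y_nm[rows], "-")^2
      gapCap <- outer(f - act$t, rep(1, length(rows))) * maxStepNm
      cand <- which(dmat <= gapCap^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], act$id[cand[, 1]])
        for (ci in ord) {
          i <- cand[ci, 1]; j <- cand[ci, 2]
          if (assignedTrk[i] || assignedLoc[j]) next
          assignedTrk[i] <- TRUE; assignedLoc[j] <- TRUE
          locs$traj_id[rows[j]] <- act$id[i]
          act$x[i] <- locs$x_nm[rows[j]]
          act$y[i] <- locs$y_nm[rows[j]]
          act$t[i] <- f
        }
      }
    }
    for (j in which(!assignedLoc)) {
      locs$traj_id[rows[j]] <- nextId
      act <- rbind(act, data.frame(id = nextId, x = locs$x_nm[rows[j]],
                                   y = locs$y_nm[rows[j]], t = f))
      nextId <- nextId + 1L
    }
  }
  keep <- names(which(table(locs$traj_id) >= minLength))
  locs <- locs[locs$traj_id %in% as.integer(keep), , drop = FALSE]
  locs <- locs[order(locs$traj_id, locs$t_index), , drop = FALSE]
  rownames(locs) <- NULL
  locs
}

#' Estimate the probe length from quasi-static frames
#'
#' When the probe barely moves (displacement to the next localization
#' below \code{dispCutoffNm}, default 40 nm), the major axis of the
#' asymmetric Gaussian fit reflects the rod footprint. The length is the
#' median over qualifying frames of the major-axis FWHM, deconvolved from
#' the optical FWHM by quadrature subtraction, minus the exciton diffusion
#' length (~100 nm apparent elongation of nanotube emission), floored at
#' zero. With fewer than \code{minFrames} qualifying frames the length is
#' undefined (NA) and callers fall back to the cohort median.
#'
#' @param traj data.frame of one trajectory, with \code{x_nm},
#'   \code{y_nm}, \code{smaj_nm}.
#' @param dispCutoffNm displacement cutoff for "undetectable movement".
#' @param excitonNm exciton diffusion length correction (nm).
#' @param psfFwhmNm optical FWHM (nm).
#' @param minFrames minimum qualifying frames (default 5).
#' @return length estimate (nm), or NA if undefined.
#' @export
estimateLength <- function(traj, dispCutoffNm = 40, excitonNm = 100,
                           psfFwhmNm = 450, minFrames = 5L) {
  n <- nrow(traj)
  if (n < 2L) return(NA_real_)
  disp <- sqrt(diff(traj$x_nm)^2 + diff(traj$y_nm)^2)
  quiet <- which(disp < dispCutoffNm)
  if (length(quiet) < minFrames) return(NA_real_)
  fwhm <- .sigmaToFwhm(traj$smaj_nm[quiet])
  rod <- sqrt(pmax(fwhm^2 - psfFwhmNm^2, 0))
  max(stats::median(rod) - excitonNm, 0)
}

#' Global MSD of one trajectory
#'
#' Time-averaged mean squared displacement over the whole trajectory.
#' @param traj data.frame with \code{x_nm}, \code{y_nm}, sampled at a
#'   constant interval.
#' @param maxLag largest lag (samples); default half the length.
#' @return data.frame with \code{lag} (samples) and \code{msd} (nm^2).
#' @export
globalMsd <- function(traj, maxLag = floor(nrow(traj) / 2)) {
  n <- nrow(traj)
  lags <- seq_len(max(1L, min(maxLag, n - 1L)))
  msd <- vapply(lags, function(k)
    mean((traj$x_nm[(1 + k):n] - traj$x_nm[1:(n - k)])^2 +
         (traj$y_nm[(1 + k):n] - traj$y_nm[1:(n - k)])^2), numeric(1))
  data.frame(lag = lags, msd = msd)
}

#' Classify a trajectory as immobile
#'
#' Immobile probes show a plateau-shaped global MSD. The rule: compute the
#' global MSD; the trajectory is immobile if the log-log slope over lags
#' in [4, span/4] samples is below \code{slopeMin} (default 0.2), or if
#' the plateau ratio MSD(span/2) / MSD(4) is below \code{plateauRatio}
#' (default 2).
#'
#' @param traj data.frame of one trajectory.
#' @param slopeMin minimum mobile log-log slope.
#' @param plateauRatio minimum mobile MSD growth ratio.
#' @return logical: TRUE if immobile.
#' @export
classifyImmobile <- function(traj, slopeMin = 0.2, plateauRatio = 2) {
  n <- nrow(traj)
  span <- floor(n / 2)
  if (span < 8L) return(NA)
  m <- globalMsd(traj, maxLag = span)
  loLag <- 4L; hiLag <- max(loLag + 2L, floor(span / 4))
  sel <- m$lag >= loLag & m$lag <= hiLag & m$msd > 0
  if (sum(sel) < 3L) return(TRUE)
  slope <- stats::coef(stats::lm(log(msd) ~ log(lag), data = m[sel, ]))[2]
  ratio <- m$msd[m$lag == max(loLag + 1L, floor(span / 2))] / m$msd[m$lag == loLag]
  if (!is.finite(ratio)) ratio <- Inf
  unname(slope < slopeMin || ratio < plateauRatio)
}

#' Split a linked table into per-trajectory data.frames
#' @param linked data.frame from \code{\link{linkTrajectories}}.
#' @return named list of data.frames, one per \code{traj_id}.
#' @export
splitTrajectories <- function(linked) {
  split(linked, linked$traj_id)
}
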
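#' @include detectors.R
NULL

applyEpisodes <- function(labels, eps) {
  for (i in seq_len(nrow(eps))) {
    a <- eps$start[i] + 1L
    b <- min(eps$end[i], length(labels))
    if (a <= b) labels[a:b] <- eps$state[i]
  }
  labels
}

absorbShortRuns <- function(labels, minFrames) {
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < minFrames)
    if (!length(short)) break
    i <- short[1]
    if (i == 1L) {
      r$values[i] <- r$values[i + 1L]
    } else if (i == length(r$lengths)) {
      r$values[i] <- r$values[i - 1L]
    } else {
      # absorb into the flanking run with greater duration; ties -> preceding
      if (r$lengths[i + 1L] > r$lengths[i - 1L])
        r$values[i] <- r$values[i + 1L]
      else
        r$values[i] <- r$values[i - 1L]
    }
    labels <- inverse.rle(r)
  }
  labels
}

#' Assemble the five-state ethogram
#'
#' Combines the per-snippet motion labels with the detector episode lists
#' into one mutually exclusive label per frame, using the precedence
#' stereotypy > grooming > rearing > locomotion > quiet-awake. Runs shorter
#' than \code{minDurationFrames} are then absorbed into the flanking run
#' with the greater duration (ties go to the preceding run), so every
#' registered behavior is sustained. Episodes are re-derived from the final
#' labels, keeping labels and episodes consistent by construction.
#'
#' @param stereotypy,rearing,grooming Episode data.frames (state, start,
#'   end) from the detectors; any may be empty.
#' @param motionLabels Per-snippet labels from \code{\link{classifyMotion}}.
#' @param nFrames Total frames in the session.
#' @param fps Frame rate.
#' @param snippetFrames Snippet length used for \code{motionLabels}.
#' @param minDurationFrames Minimum episode duration in frames, default 10
#'   (at 60 fps).
#' @param injectionFrame 0-based first post-injection frame.
#' @return An \linkS4class{Ethogram}.
#' @export
assembleEthogram <- function(stereotypy, rearing, grooming, motionLabels,
                             nFrames, fps = 60, snippetFrames = 600L,
                             minDurationFrames = 10L,
                             injectionFrame = 0L) {
  for (eps in list(stereotypy, rearing, grooming))
    if (nrow(eps) && max(eps$end) > nFrames)
      stop("alignment error: episode extends past frame ", nFrames)
  labels <- expandMotionLabels(motionLabels, nFrames, snippetFrames)
  labels <- applyEpisodes(labels, rearing)
  labels <- applyEpisodes(labels, grooming)
  labels <- applyEpisodes(labels, stereotypy)
  labels <- absorbShortRuns(labels, minDurationFrames)
  Ethogram(labels, fps = fps, injectionFrame = injectionFrame)
}

#' Compute the ethogram of one session end to end
#'
#' Runs the whole per-session analysis: paw cleaning and centroid speed,
#' speed-threshold calibration on a quiet segment, per-snippet motion
#' classification, the three episode detectors, and ethogram assembly.
#'
#' @param track A \linkS4class{KeypointTrack}.
#' @param injectionFrame 0-based first post-injection frame; defaults to
#'   \code{sessionMeta(track)$baseline_end_frame} or 0.
#' @param quietSegment Frame interval \code{c(start, end)} known to be
#'   quiet, used to calibrate the speed threshold and the weaving band;
#'   defaults to the pre-injection baseline.
#' @param config Parameter list, see \code{\link{pipelineConfig}}.
#' @return An \linkS4class{Ethogram}.
#' @export
computeEthogram <- function(track, injectionFrame = NULL,
                            quietSegment = NULL,
                            config = pipelineConfig()) {
  cfg <- config
  n <- nFrames(track)
  if (is.null(injectionFrame)) {
    injectionFrame <- sessionMeta(track)$baseline_end_frame
    if (is.null(injectionFrame)) injectionFrame <- 0L
  }
  injectionFrame <- as.integer(injectionFrame)
  if (is.null(quietSegment)) {
    if (injectionFrame < cfg$snippet_frames)
      stop("no quiet segment: provide quietSegment or a baseline of at ",
           "least one snippet")
    quietSegment <- c(0L, injectionFrame)
  }
  paws <- c("forepaw_left", "forepaw_right", "hindpaw_left", "hindpaw_right")
  clean <- cleanTrack(track, parts = paws,
                      likelihoodMin = cfg$likelihood_min,
                      maxGap = cfg$max_gap_frames)
  cen <- centroidSeries(clean, paws)
  disp <- displacementSeries(cen)
  thr <- calibrateSpeedThreshold(track, quietSegment,
                                 snippetFrames = cfg$snippet_frames,
                                 cmPerPx = cfg$cm_per_px,
                                 likelihoodMin = cfg$likelihood_min)
  motion <- classifyMotion(disp, fps = fps(track),
                           snippetFrames = cfg$snippet_frames,
                           threshold = thr, cmPerPx = cfg$cm_per_px)
  ang <- headAngleSeries(track, reference = cfg$weaving_reference)
  weaving <- detectHeadWeaving(
    ang, motion, fps = fps(track), snippetFrames = cfg$snippet_frames,
    referenceFrames = (quietSegment[1] + 1L):quietSegment[2],
    bandK = cfg$band_k, sdFloorDeg = cfg$sd_floor_deg,
    minCycles = cfg$min_cycles, cycleMaxGapS = cfg$cycle_max_gap_s,
    mergeGapS = cfg$merge_gap_s, locomotorMaxS = cfg$locomotor_max_s,
    rollWindowS = cfg$roll_window_s, smoothWindowS = cfg$smooth_window_s)
  rear <- detectRearing(track, occludedMax = cfg$rearing_occluded_max,
                        visibleMin = cfg$visible_min)
  groom <- detectGrooming(track, fps = fps(track),
                          forepawMax = cfg$grooming_forepaw_max,
                          visibleMin = cfg$visible_min,
                          minFrames = cfg$grooming_min_frames,
                          minOscillationHz = cfg$grooming_min_hz)
  assembleEthogram(weaving, rear, groom, motion, nFrames = n,
                   fps = fps(track), snippetFrames = cfg$snippet_frames,
                   minDurationFrames = cfg$min_duration_frames,
                   injectionFrame = injectionFrame)
}

#' Frame bookkeeping helpers
#'
#' \code{sessionFrameCount} converts a session duration to frames
#' (a 4-hour session at 60 fps has 864,000 frames); \code{framesToSeconds}
#' converts a frame count to seconds (the 100-frame grooming minimum is
#' about 1.67 s at 60 fps).
#'
#' @param hours Session duration in hours.
#' @param fps Frame rate.
#' @return Integer frame count / numeric seconds.
#' @export
sessionFrameCount <- function(hours, fps = 60) {
  as.integer(round(hours * 3600 * fps))
}

#' @rdname sessionFrameCount
#' @param frames Frame count.
#' @export
framesToSeconds <- function(frames, fps = 60) frames / fps

#' @rdname sessionFrameCount
#' @param seconds Duration in seconds.
#' @export
secondsToFrames <- function(seconds, fps = 60) {
  as.integer(round(seconds * fps))
}
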
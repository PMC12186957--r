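#' @include kinematics.R
NULL

# centered rolling mean with clipped (partial) windows at the edges
rollingMean <- function(v, window) {
  n <- length(v)
  if (n == 0L) return(numeric())
  half <- as.integer(window) %/% 2L
  cs <- cumsum(v)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Detect head-weaving stereotypy episodes
#'
#' Head weaving is a rhythmic lateral oscillation of the body-axis-to-nose
#' angle. Detection: (i) the angle is centred by a rolling mean (window
#' \code{rollWindowS}, robust to slow postural drift); (ii) a tolerance
#' band of \code{bandK} times a reference standard deviation is placed
#' about the centre, where the reference SD is measured on a known quiet
#' segment of the same session (\code{referenceFrames}) and floored at
#' \code{sdFloorDeg} so keypoint jitter cannot produce a vanishing band;
#' (iii) frames where the centred angle alternately crosses the upper and
#' lower band edges, with consecutive alternations at most
#' \code{cycleMaxGapS} apart and at least \code{minCycles} alternations per
#' bout, are weaving candidates; (iv) candidate bouts overlapping a
#' locomotor run of \code{locomotorMaxS} seconds or longer are discarded
#' (weaving is defined in opposition to locomotion; brief locomotor events
#' are tolerated); (v) bouts separated by less than \code{mergeGapS}
#' seconds are merged into a single episode spanning the gap, regardless
#' of intervening behavior.
#'
#' @param angles Per-frame head angle (degrees), as from
#'   \code{\link{headAngleSeries}}.
#' @param motionLabels Per-snippet labels from \code{\link{classifyMotion}}
#'   covering the same session.
#' @param fps Frame rate.
#' @param snippetFrames Snippet length used for \code{motionLabels}.
#' @param referenceFrames Integer frame indices (1-based into
#'   \code{angles}) of a quiet reference segment for the band SD; default
#'   the first 10 s.
#' @param bandK Band half-width in reference SDs, default 2.
#' @param sdFloorDeg Floor on the reference SD (degrees), default 2.5.
#' @param minCycles Minimum alternating band crossings per bout, default 2.
#' @param cycleMaxGapS Maximum seconds between successive alternations of
#'   one bout, default 2.
#' @param mergeGapS Episodes closer than this many seconds are merged,
#'   default 10.
#' @param locomotorMaxS Longest locomotor run (seconds) tolerated inside a
#'   weaving bout, default 10.
#' @param rollWindowS Rolling-mean window (seconds), default 10.
#' @param smoothWindowS Low-pass window (seconds) applied to the angle
#'   before band crossing detection, default 0.25. Keypoint jitter is
#'   white frame-to-frame noise while weaving is a smooth oscillation
#'   well below the Nyquist rate, so a short moving average suppresses
#'   spurious band crossings without materially attenuating the signal.
#' @return Episode data.frame (state = "stereotypy", start, end; 0-based
#'   half-open frames).
#' @export
detectHeadWeaving <- function(angles, motionLabels, fps = 60,
                              snippetFrames = 600L,
                              referenceFrames = NULL,
                              bandK = 2, sdFloorDeg = 2.5,
                              minCycles = 2L, cycleMaxGapS = 2,
                              mergeGapS = 10, locomotorMaxS = 10,
                              rollWindowS = 10, smoothWindowS = 0.25) {
  n <- length(angles)
  empty <- data.frame(state = character(), start = integer(),
                      end = integer())
  window <- as.integer(round(rollWindowS * fps))
  if (n < window) {
    warning("session shorter than the rolling window: no weaving detected")
    return(empty)
  }
  if (is.null(referenceFrames))
    referenceFrames <- seq_len(min(n, as.integer(10 * fps)))
  smooth <- rollingMean(as.numeric(angles),
                        max(1L, as.integer(round(smoothWindowS * fps))))
  centre <- rollingMean(smooth, window)
  dev <- smooth - centre
  refSd <- stats::sd(dev[referenceFrames])
  if (is.na(refSd)) refSd <- 0
  half <- bandK * max(refSd, sdFloorDeg)

  exc <- integer(n)
  exc[dev > half] <- 1L
  exc[dev < -half] <- -1L
  r <- rle(exc)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths          # 0-based start of each run
  ev <- which(r$values != 0L)
  if (length(ev) < 2L) return(empty)
  evStart <- runStart[ev]                 # 0-based frame of excursion onset
  evEnd <- runEnd[ev]                     # 0-based half-open end
  evSign <- r$values[ev]

  # chains of alternating-sign excursions with bounded inter-event gaps
  m <- length(ev)
  alt <- c(FALSE, evSign[-1] != evSign[-m] &
                  (evStart[-1] - evStart[-m]) <= cycleMaxGapS * fps)
  bouts <- list()
  i <- 1L
  while (i <= m) {
    j <- i
    while (j < m && alt[j + 1L]) j <- j + 1L
    nAlt <- j - i                          # alternations in chain i..j
    if (nAlt >= minCycles)
      bouts[[length(bouts) + 1L]] <- c(evStart[i], evEnd[j])
    i <- j + 1L
  }
  if (!length(bouts)) return(empty)
  b <- do.call(rbind, bouts)

  # discard bouts containing a major locomotor event: a candidate is kept
  # only when every locomotor run spends less than locomotorMaxS seconds
  # inside it
  frameMotion <- expandMotionLabels(motionLabels, n, snippetFrames)
  lr <- rle(frameMotion)
  lEnd <- cumsum(lr$lengths); lStart <- lEnd - lr$lengths
  loco <- which(lr$values == "locomotion")
  keep <- rep(TRUE, nrow(b))
  for (k in loco) {
    ov <- pmin(b[, 2], lEnd[k]) - pmax(b[, 1], lStart[k])
    keep <- keep & ov <= locomotorMaxS * fps
  }
  b <- b[keep, , drop = FALSE]
  if (!nrow(b)) return(empty)

  mergeWeavingEpisodes(
    data.frame(state = "stereotypy", start = as.integer(b[, 1]),
               end = as.integer(b[, 2])),
    fps = fps, mergeGapS = mergeGapS)
}

#' Merge nearby stereotypy episodes
#'
#' Episodes separated by less than \code{mergeGapS} seconds belong to the
#' same continuous head-weaving episode and are merged, spanning the gap
#' regardless of intervening labels. Idempotent.
#'
#' @param eps Episode data.frame (state, start, end), sorted or not.
#' @param fps Frame rate.
#' @param mergeGapS Merge gap in seconds, default 10.
#' @return Merged episode data.frame.
#' @export
mergeWeavingEpisodes <- function(eps, fps = 60, mergeGapS = 10) {
  if (nrow(eps) <= 1L) return(eps)
  eps <- eps[order(eps$start), , drop = FALSE]
  gapF <- mergeGapS * fps
  out <- eps[1, , drop = FALSE]
  for (i in 2:nrow(eps)) {
    last <- nrow(out)
    if (eps$start[i] - out$end[last] < gapF)
      out$end[last] <- max(out$end[last], eps$end[i])
    else
      out <- rbind(out, eps[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

booleanRunsToEpisodes <- function(flag, state) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  k <- which(r$values)
  data.frame(state = rep(state, length(k)),
             start = as.integer(starts[k]), end = as.integer(ends[k]))
}

#' Detect rearing episodes from likelihood occlusion
#'
#' From the bottom-up camera, a rearing rat lifts its nose and forepaws
#' out of view while the hind paws stay planted. A frame is rearing when
#' the nose likelihood and at least one forepaw likelihood fall below
#' \code{occludedMax} while both hind paw likelihoods exceed
#' \code{visibleMin}. Raw (uncleaned) likelihoods must be used: occlusion
#' is the signal. Runs of any length are returned; sub-minimum runs are
#' absorbed later during ethogram assembly.
#'
#' @param track A \linkS4class{KeypointTrack} with raw likelihoods.
#' @param occludedMax Occlusion threshold, default 0.80.
#' @param visibleMin Visibility threshold for hind paws, default 0.90.
#' @return Episode data.frame (state = "rearing", start, end).
#' @export
detectRearing <- function(track, occludedMax = 0.80, visibleMin = 0.90) {
  lik <- likelihoods(track)
  flag <- lik[, "nose"] < occludedMax &
    (lik[, "forepaw_left"] < occludedMax |
     lik[, "forepaw_right"] < occludedMax) &
    lik[, "hindpaw_left"] > visibleMin &
    lik[, "hindpaw_right"] > visibleMin
  booleanRunsToEpisodes(flag, "rearing")
}

directionReversals <- function(v) {
  d <- diff(v)
  d <- d[d != 0]
  if (length(d) < 2L) return(0L)
  sum(diff(sign(d)) != 0)
}

#' Detect grooming episodes
#'
#' Grooming is self-directed forepaw scratching: one or both forepaw
#' keypoints drop to low likelihood (rapid occluded motion against the
#' face or body) while every other tracked point stays high-likelihood and
#' the body stationary. A frame is a candidate when at least one forepaw
#' likelihood is below \code{forepawMax} and all five non-forepaw parts
#' exceed \code{visibleMin}; a candidate run becomes a grooming episode
#' when it lasts at least \code{minFrames} consecutive frames and the
#' forepaw coordinate series reverses direction at a rate of at least
#' \code{minOscillationHz} cycles per second over the run.
#'
#' @param track A \linkS4class{KeypointTrack} with raw likelihoods.
#' @param fps Frame rate.
#' @param forepawMax Forepaw occlusion threshold, default 0.79.
#' @param visibleMin Visibility threshold for the other parts, default 0.90.
#' @param minFrames Minimum run length in frames, default 100.
#' @param minOscillationHz Minimum forepaw oscillation rate, default 2.
#' @return Episode data.frame (state = "grooming", start, end).
#' @export
detectGrooming <- function(track, fps = 60, forepawMax = 0.79,
                           visibleMin = 0.90, minFrames = 100L,
                           minOscillationHz = 2) {
  lik <- likelihoods(track)
  others <- setdiff(bodyPartNames(), c("forepaw_left", "forepaw_right"))
  flag <- (lik[, "forepaw_left"] < forepawMax |
           lik[, "forepaw_right"] < forepawMax) &
    apply(lik[, others, drop = FALSE] > visibleMin, 1L, all)
  runs <- booleanRunsToEpisodes(flag, "grooming")
  if (!nrow(runs)) return(runs)
  x <- xCoords(track); y <- yCoords(track)
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    len <- runs$end[i] - runs$start[i]
    if (len < minFrames) next
    idx <- (runs$start[i] + 1L):runs$end[i]
    dur <- len / fps
    rev_rate <- max(
      directionReversals(x[idx, "forepaw_left"]),
      directionReversals(y[idx, "forepaw_left"]),
      directionReversals(x[idx, "forepaw_right"]),
      directionReversals(y[idx, "forepaw_right"])) / (2 * dur)
    keep[i] <- rev_rate >= minOscillationHz
  }
  out <- runs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
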
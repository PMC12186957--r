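#' @include AllClasses.R
NULL

#' Per-frame centroid of selected body parts
#'
#' Arithmetic mean of the selected parts' coordinates, frame by frame. The
#' locomotion analysis uses the four paws; the head-angle analysis uses the
#' pelvic centroid (hind paws + tail base).
#'
#' @param track A \linkS4class{KeypointTrack} (clean the relevant parts
#'   first with \code{\link{cleanTrack}} for locomotion use).
#' @param parts Character vector of at least 2 body part names.
#' @return Numeric matrix (frames x 2) with columns \code{x}, \code{y}.
#' @export
centroidSeries <- function(track,
                           parts = c("forepaw_left", "forepaw_right",
                                     "hindpaw_left", "hindpaw_right")) {
  if (length(parts) < 2L)
    stop("argument error: need at least 2 parts for a centroid")
  bad <- setdiff(parts, bodyPartNames())
  if (length(bad)) stop("unknown body part(s): ", paste(bad, collapse = ", "))
  cx <- rowMeans(xCoords(track)[, parts, drop = FALSE])
  cy <- rowMeans(yCoords(track)[, parts, drop = FALSE])
  cbind(x = cx, y = cy)
}

#' Per-step Euclidean displacement of a centroid series
#'
#' d(i) is the Euclidean norm of centroid(i+1) - centroid(i), in pixels;
#' the series has length frames - 1.
#'
#' @param centroids Matrix (frames x 2) as from \code{\link{centroidSeries}}.
#' @return Numeric vector of per-step distances (px), possibly empty.
#' @export
displacementSeries <- function(centroids) {
  if (nrow(centroids) < 2L) {
    warning("fewer than 2 frames: empty displacement series")
    return(numeric())
  }
  sqrt(diff(centroids[, 1])^2 + diff(centroids[, 2])^2)
}

#' Mean speed per fixed-length snippet
#'
#' Displacements are segmented into snippets of \code{snippetFrames} steps
#' (default 600 frames = 10 s at 60 fps); the snippet speed is the mean
#' per-step displacement converted to cm/s. A trailing partial snippet is
#' included and marked in the \code{"partial"} attribute.
#'
#' @param displacements Per-step distances in px.
#' @param fps Frame rate.
#' @param snippetFrames Snippet length in frames, default 600.
#' @param cmPerPx Pixel-to-cm scale, default 0.078.
#' @return Numeric vector of snippet speeds (cm/s) with logical attribute
#'   \code{partial}, one flag per snippet.
#' @export
snippetSpeeds <- function(displacements, fps = 60, snippetFrames = 600L,
                          cmPerPx = defaultArena()$cm_per_px) {
  n <- length(displacements)
  if (n == 0L) return(structure(numeric(), partial = logical()))
  grp <- (seq_len(n) - 1L) %/% snippetFrames
  m <- tapply(displacements, grp, mean)
  sizes <- tabulate(grp + 1L)
  speeds <- as.numeric(m) * fps * cmPerPx
  structure(speeds, partial = sizes < snippetFrames)
}

#' Calibrate the quiet-awake speed threshold
#'
#' The threshold separating quiet-awake from locomotion is the maximum
#' snippet speed observed within a known quiet interval (e.g., the
#' pre-injection baseline of a habituated animal, or a scripted quiet
#' segment of synthetic data).
#'
#' @param track A \linkS4class{KeypointTrack}.
#' @param quietSegment Integer vector \code{c(start, end)}: 0-based,
#'   half-open frame interval known to be quiet; must span at least one
#'   full snippet.
#' @param snippetFrames,cmPerPx,likelihoodMin As elsewhere; paw points
#'   below \code{likelihoodMin} are interpolated before the centroid.
#' @return Speed threshold in cm/s.
#' @export
calibrateSpeedThreshold <- function(track, quietSegment,
                                    snippetFrames = 600L,
                                    cmPerPx = arena(track)$cm_per_px,
                                    likelihoodMin = 0.95) {
  stopifnot(length(quietSegment) == 2L)
  start <- as.integer(quietSegment[1]); end <- as.integer(quietSegment[2])
  if (end - start < snippetFrames)
    stop("calibration error: quiet segment shorter than one snippet (",
         snippetFrames, " frames)")
  paws <- c("forepaw_left", "forepaw_right", "hindpaw_left", "hindpaw_right")
  cl <- cleanTrack(track, parts = paws, likelihoodMin = likelihoodMin)
  cen <- centroidSeries(cl, paws)[(start + 1L):end, , drop = FALSE]
  disp <- displacementSeries(cen)
  sp <- snippetSpeeds(disp, fps = fps(track), snippetFrames = snippetFrames,
                      cmPerPx = cmPerPx)
  sp <- sp[!attr(sp, "partial")]
  if (!length(sp))
    stop("calibration error: no full snippet inside the quiet segment")
  max(sp)
}

#' Classify snippets as quiet-awake or locomotion
#'
#' Snippet mean speed at or below the threshold is quiet-awake; above is
#' locomotion. A trailing partial snippet is labelled by the same rule and
#' flagged.
#'
#' @param displacements Per-step distances (px).
#' @param fps Frame rate.
#' @param snippetFrames Snippet length in frames, default 600.
#' @param threshold Speed threshold in cm/s (> 0), from
#'   \code{\link{calibrateSpeedThreshold}}.
#' @param cmPerPx Pixel-to-cm scale.
#' @return Character vector of per-snippet labels in
#'   \{quiet_awake, locomotion\} with attributes \code{partial} (logical
#'   per snippet) and \code{speeds} (cm/s).
#' @export
classifyMotion <- function(displacements, fps = 60, snippetFrames = 600L,
                           threshold, cmPerPx = defaultArena()$cm_per_px) {
  stopifnot(threshold >= 0)
  sp <- snippetSpeeds(displacements, fps, snippetFrames, cmPerPx)
  lab <- ifelse(sp <= threshold, "quiet_awake", "locomotion")
  structure(lab, partial = attr(sp, "partial"), speeds = as.numeric(sp))
}

#' Expand per-snippet motion labels to per-frame labels
#'
#' @param motionLabels From \code{\link{classifyMotion}}.
#' @param nFrames Total frames in the session.
#' @param snippetFrames Snippet length in frames.
#' @return Character vector of length \code{nFrames}.
#' @export
expandMotionLabels <- function(motionLabels, nFrames,
                               snippetFrames = 600L) {
  if (length(motionLabels) == 0L)
    return(rep("quiet_awake", nFrames))
  idx <- pmin((seq_len(nFrames) - 1L) %/% snippetFrames + 1L,
              length(motionLabels))
  as.character(motionLabels)[idx]
}

#' Signed body-axis-to-nose head angle per frame
#'
#' A pelvic centroid is computed from the two hind paws and the tail base;
#' the body axis is the vector from this centroid to the column point, and
#' the head angle is the signed angle (degrees) between the body axis and
#' the vector from the pelvic centroid to the nose. Zero means the nose
#' lies on the body axis; the sign distinguishes left/right excursions
#' (positive = counter-clockwise in image coordinates). Frames where the
#' nose or column coincides with the pelvic centroid carry the previous
#' frame's angle and are recorded in the \code{"degenerate"} attribute.
#'
#' An alternative front-centroid convention (forepaws + nose) is available
#' via \code{reference = "front"} but is not the default.
#'
#' @param track A \linkS4class{KeypointTrack}.
#' @param reference \code{"pelvic"} (default) or \code{"front"}.
#' @return Numeric vector of angles in degrees, |angle| <= 180, with
#'   integer attribute \code{degenerate} (0-based frame indices).
#' @export
headAngleSeries <- function(track, reference = c("pelvic", "front")) {
  reference <- match.arg(reference)
  x <- xCoords(track); y <- yCoords(track)
  ref <- if (reference == "pelvic")
    c("hindpaw_left", "hindpaw_right", "tail_base")
  else c("forepaw_left", "forepaw_right", "nose")
  cpx <- rowMeans(x[, ref, drop = FALSE])
  cpy <- rowMeans(y[, ref, drop = FALSE])
  ax <- x[, "column"] - cpx
  ay <- y[, "column"] - cpy
  vx <- x[, "nose"] - cpx
  vy <- y[, "nose"] - cpy
  cross <- ax * vy - ay * vx
  dot <- ax * vx + ay * vy
  ang <- atan2(cross, dot) * 180 / pi
  degen <- which((vx == 0 & vy == 0) | (ax == 0 & ay == 0))
  if (length(degen)) {
    for (i in degen) ang[i] <- if (i > 1L) ang[i - 1L] else 0
  }
  structure(ang, degenerate = as.integer(degen - 1L))
}
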
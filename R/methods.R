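#' @include AllGenerics.R
NULL

#' @describeIn nFrames rows of the assay matrices
#' @export
setMethod("nFrames", "KeypointTrack", function(object) nrow(object))

#' @describeIn nFrames length of the label vector
#' @export
setMethod("nFrames", "Ethogram", function(object) length(object@labels))

#' @describeIn fps from track metadata
#' @export
setMethod("fps", "KeypointTrack",
          function(object) S4Vectors::metadata(object)$fps)

#' @describeIn fps ethogram slot
#' @export
setMethod("fps", "Ethogram", function(object) object@fps)

#' @describeIn fps script slot
#' @export
setMethod("fps", "SyntheticScript", function(object) object@fps)

#' @describeIn sessionMeta from track metadata
#' @export
setMethod("sessionMeta", "KeypointTrack",
          function(object) S4Vectors::metadata(object)$sessionMeta)

#' @describeIn arena from track metadata
#' @export
setMethod("arena", "KeypointTrack",
          function(object) S4Vectors::metadata(object)$arena)

#' @describeIn arena script slot
#' @export
setMethod("arena", "SyntheticScript", function(object) object@arena)

#' Coordinate and likelihood matrices of a track
#'
#' @param track A \linkS4class{KeypointTrack}.
#' @return Numeric matrix (frames x 7).
#' @export
xCoords <- function(track) SummarizedExperiment::assay(track, "x")

#' @rdname xCoords
#' @export
yCoords <- function(track) SummarizedExperiment::assay(track, "y")

#' @rdname xCoords
#' @export
likelihoods <- function(track) SummarizedExperiment::assay(track, "likelihood")

#' @describeIn stateLabels ethogram slot
#' @export
setMethod("stateLabels", "Ethogram", function(object) object@labels)

#' @describeIn injectionFrame ethogram slot
#' @export
setMethod("injectionFrame", "Ethogram",
          function(object) object@injectionFrame)

labelsToEpisodes <- function(labels, fps, offset = 0L) {
  if (length(labels) == 0L)
    return(data.frame(state = character(), start = integer(),
                      end = integer(), duration_s = numeric()))
  r <- rle(as.character(labels))
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(state = r$values,
             start = as.integer(start + offset),
             end = as.integer(end + offset),
             duration_s = r$lengths / fps)
}

#' @describeIn episodes run-length encode the labels; with
#'   \code{postInjectionOnly = TRUE} only frames at or after the injection
#'   frame are encoded (indices stay session-relative).
#' @param postInjectionOnly Logical.
#' @export
setMethod("episodes", "Ethogram",
          function(object, postInjectionOnly = FALSE) {
  lab <- object@labels
  off <- 0L
  if (postInjectionOnly && object@injectionFrame > 0L) {
    lab <- lab[(object@injectionFrame + 1L):length(lab)]
    off <- object@injectionFrame
  }
  labelsToEpisodes(lab, object@fps, off)
})

#' @describeIn occupancy fraction of post-injection frames spent in each
#'   state (always sums to 1). Set \code{postInjectionOnly = FALSE} to use
#'   the whole session.
#' @param postInjectionOnly Logical, default TRUE.
#' @export
setMethod("occupancy", "Ethogram",
          function(object, postInjectionOnly = TRUE) {
  lab <- object@labels
  if (postInjectionOnly && object@injectionFrame > 0L)
    lab <- lab[(object@injectionFrame + 1L):length(lab)]
  tab <- table(lab)
  as.numeric(tab) / length(lab) -> frac
  names(frac) <- names(tab)
  frac[behaviorStates()]
})

#' @describeIn stereotypyOnset minutes from the injection frame to the
#'   first post-injection stereotypy episode (0 when one spans the
#'   injection); NA when the session has none.
#' @export
setMethod("stereotypyOnset", "Ethogram", function(object) {
  ep <- episodes(object, postInjectionOnly = TRUE)
  ep <- ep[ep$state == "stereotypy", , drop = FALSE]
  if (nrow(ep) == 0L) return(NA_real_)
  (ep$start[1] - object@injectionFrame) / object@fps / 60
})

#' @describeIn transitionCountsMatrix slot accessor
#' @export
setMethod("transitionCountsMatrix", "TransitionMatrix",
          function(object) object@counts)

#' @describeIn transitionProbs slot accessor
#' @export
setMethod("transitionProbs", "TransitionMatrix",
          function(object) object@probabilities)

setMethod("show", "KeypointTrack", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("KeypointTrack: %d frames x %d parts @ %g fps (%.1f min)\n",
              nrow(object), ncol(object), md$fps,
              nrow(object) / md$fps / 60))
  sm <- md$sessionMeta
  if (length(sm))
    cat("  sessionMeta:", paste(names(sm), collapse = ", "), "\n")
})

setMethod("show", "Ethogram", function(object) {
  cat(sprintf("Ethogram: %d frames @ %g fps, injection at frame %d\n",
              length(object@labels), object@fps, object@injectionFrame))
  if (length(object@labels)) {
    occ <- occupancy(object)
    cat("  post-injection occupancy:",
        paste(sprintf("%s %.1f%%", names(occ), 100 * occ),
              collapse = ", "), "\n")
  }
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d transitions pooled from %d session(s)\n",
              sum(object@counts), object@nSessions))
  if (length(object@zeroRows))
    cat("  states with no outgoing transitions:",
        paste(object@zeroRows, collapse = ", "), "\n")
})

setMethod("show", "SyntheticScript", function(object) {
  cat(sprintf(
    "SyntheticScript: %.0f s baseline + %d post-injection bouts (%.0f s) @ %g fps, seed %d\n",
    object@baselineS, nrow(object@states), sum(object@states$duration_s),
    object@fps, object@seed))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d points, k = %d (elbow strength %.2f)\n",
              nrow(object@embedding), object@k, object@elbowStrength))
})
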
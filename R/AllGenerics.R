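#' @include AllClasses.R
NULL

#' Number of frames in a track or ethogram
#' @param object A KeypointTrack or Ethogram.
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' Frame rate accessor
#' @param object A KeypointTrack, Ethogram or SyntheticScript.
#' @return Frames per second.
#' @export
setGeneric("fps", function(object) standardGeneric("fps"))

#' Per-frame state labels of an ethogram
#' @param object An Ethogram.
#' @return Factor vector over the five-state alphabet, one value per frame.
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))

#' Episode list derived from per-frame labels
#'
#' Episodes are maximal runs of a single state; they tile the label array
#' exactly and adjacent episodes always differ in state. Frame indices are
#' 0-based, intervals half-open [start, end).
#'
#' @param object An Ethogram.
#' @param ... Passed to methods (\code{postInjectionOnly}).
#' @return data.frame with columns state, start, end, duration_s.
#' @export
setGeneric("episodes", function(object, ...) standardGeneric("episodes"))

#' Injection frame accessor
#' @param object An Ethogram.
#' @return 0-based index of the first post-injection frame.
#' @export
setGeneric("injectionFrame",
           function(object) standardGeneric("injectionFrame"))

#' Per-state occupancy fractions
#' @param object An Ethogram.
#' @param ... Passed to methods.
#' @return Named numeric vector over the 5 states summing to 1.
#' @export
setGeneric("occupancy", function(object, ...) standardGeneric("occupancy"))

#' Stereotypy onset latency
#' @param object An Ethogram.
#' @return Minutes from injection to the start of the first post-injection
#'   stereotypy episode, or NA when the session has none (censored).
#' @export
setGeneric("stereotypyOnset",
           function(object) standardGeneric("stereotypyOnset"))

#' Transition count matrix accessor
#' @param object A TransitionMatrix.
#' @return 5x5 matrix of run-to-run transition counts.
#' @export
setGeneric("transitionCountsMatrix",
           function(object) standardGeneric("transitionCountsMatrix"))

#' Transition probability matrix accessor
#' @param object A TransitionMatrix.
#' @return 5x5 row-stochastic matrix (all-zero rows for states without
#'   outgoing transitions).
#' @export
setGeneric("transitionProbs",
           function(object) standardGeneric("transitionProbs"))

#' Session metadata accessor
#' @param object A KeypointTrack.
#' @return Named list of session metadata.
#' @export
setGeneric("sessionMeta", function(object) standardGeneric("sessionMeta"))

#' Arena geometry accessor
#' @param object A KeypointTrack or SyntheticScript.
#' @return List with width_px, height_px, cm_per_px.
#' @export
setGeneric("arena", function(object) standardGeneric("arena"))
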
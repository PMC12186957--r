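#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

#' Canonical body part names
#'
#' The seven keypoints tracked on the ventral view of the animal, in
#' canonical column order: the nose, both forepaws, both hind paws, the
#' column (the central point between the two hind paws and the base of the
#' tail) and the tail base.
#'
#' @return Character vector of length 7.
#' @export
bodyPartNames <- function() {
  c("nose", "forepaw_left", "forepaw_right",
    "hindpaw_left", "hindpaw_right", "column", "tail_base")
}

#' Behavioral state alphabet
#'
#' The five mutually exclusive behavioral states of the ethogram, in
#' precedence order used elsewhere in the package (highest first for
#' stereotypy). Rendering colors follow the conventional scheme:
#' stereotypy black, quiet-awake red, locomotion blue, grooming cyan,
#' rearing magenta.
#'
#' @return Character vector of length 5.
#' @export
behaviorStates <- function() {
  c("stereotypy", "quiet_awake", "locomotion", "grooming", "rearing")
}

#' @rdname behaviorStates
#' @return \code{behaviorStateColors}: named character vector of display
#'   colors, one per state.
#' @export
behaviorStateColors <- function() {
  c(stereotypy = "black", quiet_awake = "red", locomotion = "blue",
    grooming = "cyan", rearing = "magenta")
}

#' KeypointTrack: per-frame keypoint coordinates for one session
#'
#' A \linkS4class{SummarizedExperiment} with frames as rows and the seven
#' canonical body parts as columns, carrying three assays: \code{x} and
#' \code{y} (pixel coordinates, image convention: origin top-left, y grows
#' downward) and \code{likelihood} (per-keypoint tracking confidence in
#' [0, 1]). Session-level metadata (fps, arena geometry, animal metadata,
#' cleaning flags) lives in \code{metadata()}.
#'
#' @seealso \code{\link{KeypointTrack}} for the constructor,
#'   \code{\link{readPoseTrack}} for file input.
#' @export
setClass("KeypointTrack", contains = "SummarizedExperiment")

setValidity("KeypointTrack", function(object) {
  msg <- character()
  if (!identical(colnames(object), bodyPartNames()))
    msg <- c(msg, sprintf(
      "body parts must be exactly %s in canonical order",
      paste(bodyPartNames(), collapse = ", ")))
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("x", "y", "likelihood") %in% an))
    msg <- c(msg, "assays 'x', 'y' and 'likelihood' are required")
  if ("likelihood" %in% an) {
    lik <- SummarizedExperiment::assay(object, "likelihood")
    if (length(lik) && (min(lik) < 0 || max(lik) > 1))
      msg <- c(msg, "likelihood values must lie in [0, 1]")
  }
  fps <- S4Vectors::metadata(object)$fps
  if (is.null(fps) || !is.numeric(fps) || fps <= 0)
    msg <- c(msg, "metadata fps must be a positive number")
  bef <- S4Vectors::metadata(object)$sessionMeta$baseline_end_frame
  if (!is.null(bef) && bef >= nrow(object))
    msg <- c(msg, "baseline_end_frame must be < number of frames")
  if (length(msg)) msg else TRUE
})

#' Construct a KeypointTrack
#'
#' @param x,y Numeric matrices (frames x 7) of pixel coordinates, columns in
#'   the canonical \code{\link{bodyPartNames}} order (or named and
#'   reorderable).
#' @param likelihood Numeric matrix of per-keypoint confidences in [0, 1],
#'   same shape as \code{x}.
#' @param fps Frames per second (default 60).
#' @param sessionMeta Named list of free-form session metadata (rat id, sex,
#'   drug, dose, day, \code{baseline_end_frame}, ...).
#' @param arena List with \code{width_px}, \code{height_px} and
#'   \code{cm_per_px}; coordinates are clamped into the arena on
#'   construction. Default 720 x 480 px at 0.078 cm/px.
#'
#' @return A \linkS4class{KeypointTrack}.
#' @export
KeypointTrack <- function(x, y, likelihood, fps = 60,
                          sessionMeta = list(),
                          arena = defaultArena()) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  stopifnot(all(dim(x) == dim(y)), all(dim(x) == dim(likelihood)))
  parts <- bodyPartNames()
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), parts))
      stop("unknown or missing body parts: ",
           paste(symdiff_(colnames(x), parts), collapse = ", "))
    x <- x[, parts, drop = FALSE]
    y <- y[, parts, drop = FALSE]
    likelihood <- likelihood[, parts, drop = FALSE]
  } else if (ncol(x) == length(parts)) {
    colnames(x) <- colnames(y) <- colnames(likelihood) <- parts
  } else {
    stop("expected ", length(parts), " body parts, got ", ncol(x))
  }
  x <- pmin(pmax(x, 0), arena$width_px)
  y <- pmin(pmax(y, 0), arena$height_px)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = x, y = y, likelihood = likelihood),
    colData = S4Vectors::DataFrame(part = parts, row.names = parts))
  md <- list(fps = fps, arena = arena, sessionMeta = sessionMeta)
  S4Vectors::metadata(se) <- md
  methods::new("KeypointTrack", se)
}

#' Default open-field arena geometry
#'
#' 720 x 480 px video frames; the 39 cm arena spans roughly 500 px, giving
#' 0.078 cm per pixel.
#'
#' @return List with \code{width_px}, \code{height_px}, \code{cm_per_px}.
#' @export
defaultArena <- function() {
  list(width_px = 720, height_px = 480, cm_per_px = 39 / 500)
}

symdiff_ <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Ethogram: per-frame behavioral state labels for one session
#'
#' Holds one label per frame over the closed five-state alphabet
#' (\code{\link{behaviorStates}}), the frame rate, and the injection frame
#' separating the pre-injection baseline from the treatment period.
#' Episodes (maximal runs of one state) are derived on demand with
#' \code{\link{episodes}}, so labels and episodes can never disagree.
#'
#' @slot labels factor vector, one level set = \code{behaviorStates()}.
#' @slot fps numeric frame rate.
#' @slot injectionFrame integer 0-based frame index of the injection;
#'   frames \code{[0, injectionFrame)} are baseline.
#' @export
setClass("Ethogram",
         representation(labels = "factor", fps = "numeric",
                        injectionFrame = "integer"))

setValidity("Ethogram", function(object) {
  msg <- character()
  if (!identical(levels(object@labels), behaviorStates()))
    msg <- c(msg, "labels must be a factor over the 5-state alphabet")
  if (anyNA(object@labels))
    msg <- c(msg, "labels must not contain NA")
  if (length(object@fps) != 1 || object@fps <= 0)
    msg <- c(msg, "fps must be a single positive number")
  if (object@injectionFrame < 0 ||
      (length(object@labels) > 0 &&
       object@injectionFrame >= length(object@labels)))
    msg <- c(msg, "injectionFrame must lie inside the session")
  if (length(msg)) msg else TRUE
})

#' Construct an Ethogram
#'
#' @param labels Character or factor vector of per-frame states, values in
#'   \code{behaviorStates()}.
#' @param fps Frames per second.
#' @param injectionFrame 0-based index of the first post-injection frame
#'   (default 0: whole session is post-injection).
#' @return An \linkS4class{Ethogram}.
#' @export
Ethogram <- function(labels, fps = 60, injectionFrame = 0L) {
  if (!is.factor(labels))
    labels <- factor(as.character(labels), levels = behaviorStates())
  else labels <- factor(as.character(labels), levels = behaviorStates())
  methods::new("Ethogram", labels = labels, fps = as.numeric(fps),
               injectionFrame = as.integer(injectionFrame))
}

#' TransitionMatrix: run-to-run behavioral transition counts/probabilities
#'
#' Counts are indexed (end state of a run -> start state of the next run);
#' because adjacent runs always differ in state, the diagonal is
#' structurally zero. Probabilities are row-normalized counts; rows with no
#' outgoing transition stay all-zero and are recorded in \code{zeroRows}.
#'
#' @slot counts 5x5 numeric matrix of non-negative integers.
#' @slot probabilities 5x5 numeric matrix (may be all-NA before
#'   normalization).
#' @slot nSessions integer, number of sessions pooled into the counts.
#' @slot zeroRows character, states with no outgoing transitions.
#' @export
setClass("TransitionMatrix",
         representation(counts = "matrix", probabilities = "matrix",
                        nSessions = "integer", zeroRows = "character"))

setValidity("TransitionMatrix", function(object) {
  st <- behaviorStates()
  msg <- character()
  if (!identical(dim(object@counts), c(5L, 5L)) ||
      !identical(rownames(object@counts), st) ||
      !identical(colnames(object@counts), st))
    msg <- c(msg, "counts must be 5x5 with state-name dimnames")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (any(diag(object@counts) != 0))
    msg <- c(msg, "diagonal of counts must be structurally zero")
  if (!all(is.na(object@probabilities))) {
    rs <- rowSums(object@probabilities)
    ok <- abs(rs - 1) < 1e-9 | abs(rs) < 1e-12
    if (!all(ok))
      msg <- c(msg, "probability rows must sum to 1 (or be all-zero)")
  }
  if (length(msg)) msg else TRUE
})

emptyStateMatrix <- function() {
  st <- behaviorStates()
  matrix(0, 5, 5, dimnames = list(st, st))
}

#' SyntheticScript: ground-truth recipe for one rendered session
#'
#' Describes a synthetic open-field session: a pre-injection quiet baseline,
#' an ordered post-injection state sequence with durations, and the
#' kinematic parameters used to render each state into keypoint
#' coordinates and likelihoods.
#'
#' @slot seed integer RNG seed making rendering reproducible.
#' @slot fps numeric frame rate.
#' @slot baselineS numeric, seconds of quiet-awake baseline before the
#'   injection frame.
#' @slot states data.frame with columns \code{state} (in
#'   \code{behaviorStates()}) and \code{duration_s} (> 0), covering the
#'   post-injection period.
#' @slot params named list of kinematic parameters (see
#'   \code{\link{defaultKinematicParams}}).
#' @slot arena arena geometry list as in \code{\link{defaultArena}}.
#' @export
setClass("SyntheticScript",
         representation(seed = "integer", fps = "numeric",
                        baselineS = "numeric", states = "data.frame",
                        params = "list", arena = "list"))

setValidity("SyntheticScript", function(object) {
  msg <- character()
  st <- object@states
  if (!all(c("state", "duration_s") %in% names(st)))
    msg <- c(msg, "states needs columns state, duration_s")
  else {
    if (!all(st$state %in% behaviorStates()))
      msg <- c(msg, "unknown state in script")
    if (any(st$duration_s <= 0))
      msg <- c(msg, "state durations must be > 0")
  }
  if (object@baselineS < 0) msg <- c(msg, "baselineS must be >= 0")
  p <- object@params
  for (nm in c("lik_visible", "lik_occluded"))
    if (!is.null(p[[nm]]) && (p[[nm]] < 0 || p[[nm]] > 1))
      msg <- c(msg, paste(nm, "must lie in [0, 1]"))
  if (length(msg)) msg else TRUE
})

#' ClusterResult: embedding, labels and elbow diagnostics
#'
#' @slot embedding n x 2 matrix of t-SNE coordinates.
#' @slot labels integer cluster id per row, in 1..k.
#' @slot k integer chosen cluster count.
#' @slot wss numeric within-cluster sum-of-squares curve over k = 1..kMax.
#' @slot elbowStrength numeric, second difference at the chosen elbow
#'   normalized by total WSS; small values mean no dominant elbow.
#' @slot linkage the hclust merge record.
#' @slot seed integer seed used for the embedding.
#' @export
setClass("ClusterResult",
         representation(embedding = "matrix", labels = "integer",
                        k = "integer", wss = "numeric",
                        elbowStrength = "numeric", linkage = "ANY",
                        seed = "integer"))
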
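#' @include methods.R
NULL

#' Extract the run sequence of an ethogram
#'
#' Run-length encodes the (by default post-injection) label array into
#' maximal runs ("chains") of a single state. Adjacent runs always differ
#' in state and run lengths sum to the encoded frame count.
#'
#' @param etho An \linkS4class{Ethogram}.
#' @param postInjectionOnly Count only post-injection frames (default
#'   TRUE; the pre-injection baseline can be included with FALSE).
#' @return data.frame with columns \code{state}, \code{length} (frames).
#' @export
extractRuns <- function(etho, postInjectionOnly = TRUE) {
  stopifnot(methods::is(etho, "Ethogram"))
  if (nFrames(etho) == 0L) stop("empty ethogram")
  lab <- as.character(stateLabels(etho))
  if (postInjectionOnly && injectionFrame(etho) > 0L)
    lab <- lab[(injectionFrame(etho) + 1L):length(lab)]
  r <- rle(lab)
  data.frame(state = r$values, length = as.integer(r$lengths))
}

#' Run-to-run transition counts
#'
#' count[a, b] is the number of adjacent run pairs (a run of state a
#' followed by a run of state b). With r runs there are exactly r - 1
#' transitions; the diagonal is structurally zero because adjacent runs
#' differ.
#'
#' @param runs data.frame from \code{\link{extractRuns}}, or a character
#'   vector of run states.
#' @return A \linkS4class{TransitionMatrix} with counts only (probabilities
#'   all-NA until \code{\link{poolAndNormalize}}).
#' @export
transitionCounts <- function(runs) {
  states <- if (is.data.frame(runs)) as.character(runs$state)
            else as.character(runs)
  cm <- emptyStateMatrix()
  if (length(states) < 2L) {
    warning("fewer than 2 runs: zero transition matrix")
  } else {
    from <- factor(states[-length(states)], levels = behaviorStates())
    to <- factor(states[-1], levels = behaviorStates())
    cm <- cm + table(from, to)
  }
  pm <- emptyStateMatrix(); pm[] <- NA_real_
  methods::new("TransitionMatrix", counts = unclass(as.matrix(cm)),
               probabilities = pm, nSessions = 1L,
               zeroRows = character())
}

#' Pool transition matrices and row-normalize
#'
#' Counts are summed element-wise across sessions first (the accumulated
#' matrix), then each row is divided by its row sum, giving the average
#' transition probability from each end state. Rows with no outgoing
#' transitions stay all-zero and are recorded in the \code{zeroRows} slot.
#'
#' @param matrices A \linkS4class{TransitionMatrix} or list of them.
#' @return A \linkS4class{TransitionMatrix} with probabilities filled in.
#' @export
poolAndNormalize <- function(matrices) {
  if (methods::is(matrices, "TransitionMatrix"))
    matrices <- list(matrices)
  if (!length(matrices)) stop("need at least one transition matrix")
  total <- emptyStateMatrix()
  nses <- 0L
  for (m in matrices) {
    stopifnot(methods::is(m, "TransitionMatrix"))
    cm <- transitionCountsMatrix(m)
    if (!identical(dim(cm), dim(total)))
      stop("shape mismatch in transition matrices")
    total <- total + cm
    nses <- nses + m@nSessions
  }
  rs <- rowSums(total)
  probs <- total
  nz <- rs > 0
  probs[nz, ] <- total[nz, , drop = FALSE] / rs[nz]
  probs[!nz, ] <- 0
  methods::new("TransitionMatrix", counts = total, probabilities = probs,
               nSessions = nses,
               zeroRows = rownames(total)[!nz])
}

#' Export a behavioral transition network
#'
#' Builds a directed weighted graph with one node per behavioral state
#' (node attribute \code{size} = occupancy fraction, \code{color} = the
#' conventional state color) and one edge per transition probability.
#' Writes a GraphML file and a TSV edge list; edges below
#' \code{displayThreshold} are omitted from both files but retained in the
#' matrix object.
#'
#' @param tm A normalized \linkS4class{TransitionMatrix}.
#' @param occupancy Named per-state occupancy fractions (summing to 1).
#' @param path Output path prefix; \code{<path>.graphml} and
#'   \code{<path>_edges.tsv} are written.
#' @param displayThreshold Minimum probability for an exported edge,
#'   default 0.01.
#' @return Invisible list with the igraph object and the written paths.
#' @export
exportNetwork <- function(tm, occupancy, path, displayThreshold = 0.01) {
  probs <- transitionProbs(tm)
  if (all(is.na(probs)))
    stop("probabilities not computed: run poolAndNormalize first")
  g <- igraph::graph_from_adjacency_matrix(probs, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  occ <- occupancy[igraph::V(g)$name]
  igraph::V(g)$size <- as.numeric(occ)
  igraph::V(g)$color <- unname(behaviorStateColors()[igraph::V(g)$name])
  g <- igraph::delete_edges(
    g, igraph::E(g)[igraph::E(g)$weight < displayThreshold])
  graphmlPath <- paste0(path, ".graphml")
  edgePath <- paste0(path, "_edges.tsv")
  igraph::write_graph(g, graphmlPath, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  names(el) <- c("from", "to", "weight")
  data.table::fwrite(el, edgePath, sep = "\t")
  invisible(list(graph = g, graphml = graphmlPath, edges = edgePath))
}

#' Transition matrices as CSV
#'
#' Writes counts and (if computed) probabilities as CSV matrices with
#' state-name headers.
#'
#' @param tm A \linkS4class{TransitionMatrix}.
#' @param countsPath,probsPath Output paths (NULL to skip either).
#' @return Invisible character vector of paths written.
#' @export
writeTransitionMatrix <- function(tm, countsPath = NULL, probsPath = NULL) {
  out <- character()
  if (!is.null(countsPath)) {
    utils::write.csv(transitionCountsMatrix(tm), countsPath)
    out <- c(out, countsPath)
  }
  if (!is.null(probsPath) && !all(is.na(transitionProbs(tm)))) {
    utils::write.csv(transitionProbs(tm), probsPath)
    out <- c(out, probsPath)
  }
  invisible(out)
}
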
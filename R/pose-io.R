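#' @include AllClasses.R
NULL

#' Read a DeepLabCut-format pose table
#'
#' Parses the DLC CSV dialect: three header rows (scorer / bodyparts /
#' coords) followed by one numeric row per frame, the first column being
#' the frame index and then an x, y, likelihood triplet per body part.
#' Parts are normalized to the canonical \code{\link{bodyPartNames}} order;
#' files with missing or unknown parts are rejected.
#'
#' @param path Path to a DLC CSV file.
#' @param fps Frame rate of the recording (default 60).
#' @param sessionMeta Optional named list of session metadata to attach.
#' @param arena Arena geometry, see \code{\link{defaultArena}}.
#' @return A validated \linkS4class{KeypointTrack}; frame index 0-based.
#' @export
readPoseTrack <- function(path, fps = 60, sessionMeta = list(),
                          arena = defaultArena()) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L)
    stop("format error: expected 3 header rows (scorer/bodyparts/coords), ",
         "found ", length(hdr))
  split1 <- strsplit(hdr, ",", fixed = TRUE)
  lab <- vapply(split1, `[`, "", 1L)
  if (!identical(tolower(lab), c("scorer", "bodyparts", "coords")))
    stop("format error: header rows must be labelled ",
         "'scorer', 'bodyparts', 'coords'; found ",
         paste(lab, collapse = ", "))
  parts_row <- split1[[2]][-1]
  coords_row <- split1[[3]][-1]
  if (length(parts_row) == 0L || length(parts_row) %% 3L != 0L)
    stop("format error: expected x,y,likelihood triplets per body part")
  fileParts <- unique(parts_row)
  canonical <- bodyPartNames()
  unknown <- setdiff(fileParts, canonical)
  if (length(unknown))
    stop("schema error: unknown body part(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(canonical, fileParts)
  if (length(missing))
    stop("schema error: missing body part(s): ",
         paste(missing, collapse = ", "))

  nLines <- length(readLines(path))
  raw <- if (nLines > 3L)
    utils::read.csv(path, skip = 3L, header = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  else data.frame()
  if (nrow(raw) == 0L) {
    z <- matrix(numeric(), 0, 7, dimnames = list(NULL, canonical))
    return(KeypointTrack(z, z, z, fps = fps, sessionMeta = sessionMeta,
                         arena = arena))
  }
  num <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
  bad <- which(is.na(num) & !is.na(as.matrix(raw)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("parse error: non-numeric cell at data row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  if (anyNA(num))
    stop(sprintf("parse error: empty cell at data row %d",
                 which(is.na(num), arr.ind = TRUE)[1, 1]))
  dat <- num[, -1, drop = FALSE]
  get <- function(part, coord) {
    j <- which(parts_row == part & coords_row == coord)
    if (length(j) != 1L)
      stop("schema error: expected one '", coord, "' column for part '",
           part, "'")
    dat[, j]
  }
  x <- vapply(canonical, get, numeric(nrow(dat)), coord = "x")
  y <- vapply(canonical, get, numeric(nrow(dat)), coord = "y")
  lik <- vapply(canonical, get, numeric(nrow(dat)), coord = "likelihood")
  if (nrow(dat) == 1L) {   # vapply drops to vector-shaped matrix fine; guard
    x <- matrix(x, 1, dimnames = list(NULL, canonical))
    y <- matrix(y, 1, dimnames = list(NULL, canonical))
    lik <- matrix(lik, 1, dimnames = list(NULL, canonical))
  }
  KeypointTrack(x, y, lik, fps = fps, sessionMeta = sessionMeta,
                arena = arena)
}

#' Write a KeypointTrack as a DeepLabCut-format CSV
#'
#' Emits the 3-header-row dialect accepted by \code{\link{readPoseTrack}}.
#' Values are written at full double precision so that a write/read
#' round trip is lossless.
#'
#' @param track A \linkS4class{KeypointTrack}.
#' @param path Output file path.
#' @param scorer Scorer string for the first header row.
#' @return \code{path}, invisibly.
#' @export
writePoseTrack <- function(track, path, scorer = "PoseEthogram") {
  stopifnot(methods::is(track, "KeypointTrack"))
  parts <- bodyPartNames()
  h1 <- c("scorer", rep(scorer, 21L))
  h2 <- c("bodyparts", rep(parts, each = 3L))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), times = 7L))
  ok <- tryCatch({
    writeLines(c(paste(h1, collapse = ","),
                 paste(h2, collapse = ","),
                 paste(h3, collapse = ",")), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop("I/O error: cannot open '", path, "' for writing")
  n <- nFrames(track)
  if (n > 0L) {
    x <- xCoords(track); y <- yCoords(track); lik <- likelihoods(track)
    cols <- vector("list", 22L)
    cols[[1]] <- 0:(n - 1L)
    for (i in seq_along(parts)) {
      cols[[3 * i - 1L]] <- x[, i]
      cols[[3 * i]] <- y[, i]
      cols[[3 * i + 1L]] <- lik[, i]
    }
    dt <- data.table::as.data.table(cols)
    data.table::fwrite(dt, path, append = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' Clean a track by likelihood-thresholded interpolation
#'
#' For each requested part, frames with likelihood below
#' \code{likelihoodMin} have their x and y replaced by linear interpolation
#' between the nearest flanking frames at or above the threshold (nearest
#' good value at the session edges). Likelihood values themselves are
#' preserved. Gaps longer than \code{maxGap} frames are still filled but
#' recorded in \code{sessionMeta(track)$cleaning_flags}. Cleaning is
#' per-analysis, not global: locomotion centroids use it, while the
#' rearing/grooming detectors read raw likelihoods because occlusion is
#' their signal.
#'
#' @param track A \linkS4class{KeypointTrack}.
#' @param parts Body parts to clean (default: the four paws, as used for
#'   locomotion centroids).
#' @param likelihoodMin Threshold in (0, 1), default 0.95.
#' @param maxGap Longest gap (frames) filled without flagging, default 60.
#' @return A cleaned \linkS4class{KeypointTrack}; idempotent.
#' @export
cleanTrack <- function(track,
                       parts = c("forepaw_left", "forepaw_right",
                                 "hindpaw_left", "hindpaw_right"),
                       likelihoodMin = 0.95, maxGap = 60L) {
  stopifnot(methods::is(track, "KeypointTrack"),
            likelihoodMin > 0, likelihoodMin < 1)
  bad_parts <- setdiff(parts, bodyPartNames())
  if (length(bad_parts))
    stop("unknown body part(s): ", paste(bad_parts, collapse = ", "))
  x <- xCoords(track); y <- yCoords(track); lik <- likelihoods(track)
  n <- nrow(x)
  flags <- list()
  for (p in parts) {
    good <- lik[, p] >= likelihoodMin
    if (!any(good))
      stop("irrecoverable part: every frame of '", p,
           "' is below the likelihood threshold")
    if (all(good)) next
    idx <- seq_len(n)
    x[, p] <- stats::approx(idx[good], x[good, p], xout = idx,
                            rule = 2)$y
    y[, p] <- stats::approx(idx[good], y[good, p], xout = idx,
                            rule = 2)$y
    r <- rle(!good)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    long <- which(r$values & r$lengths > maxGap)
    for (j in long)
      flags[[length(flags) + 1L]] <-
        data.frame(part = p, start = starts[j], end = ends[j],
                   gap_frames = r$lengths[j])
  }
  md <- S4Vectors::metadata(track)
  sm <- md$sessionMeta
  if (length(flags))
    sm$cleaning_flags <- do.call(rbind, flags)
  KeypointTrack(x, y, lik, fps = md$fps, sessionMeta = sm,
                arena = md$arena)
}

#' Write an ethogram as a per-frame TSV and an episode CSV
#'
#' The TSV has columns frame (0-based), time_s and state; the episode CSV
#' has columns state, start_frame, end_frame (half-open) and duration_s.
#'
#' @param etho An \linkS4class{Ethogram}.
#' @param tsvPath,episodeCsvPath Output paths (either may be NULL to skip).
#' @return Invisible character vector of the paths written.
#' @export
writeEthogram <- function(etho, tsvPath = NULL, episodeCsvPath = NULL) {
  stopifnot(methods::is(etho, "Ethogram"))
  out <- character()
  if (!is.null(tsvPath)) {
    n <- nFrames(etho)
    dt <- data.table::data.table(
      frame = if (n) 0:(n - 1L) else integer(),
      time_s = (if (n) 0:(n - 1L) else integer()) / fps(etho),
      state = as.character(stateLabels(etho)))
    data.table::fwrite(dt, tsvPath, sep = "\t")
    out <- c(out, tsvPath)
  }
  if (!is.null(episodeCsvPath)) {
    ep <- episodes(etho)
    names(ep) <- c("state", "start_frame", "end_frame", "duration_s")
    data.table::fwrite(ep, episodeCsvPath)
    out <- c(out, episodeCsvPath)
  }
  invisible(out)
}

#' Read an ethogram TSV written by \code{\link{writeEthogram}}
#'
#' @param path TSV with columns frame, time_s, state.
#' @param fps Frame rate.
#' @param injectionFrame 0-based injection frame.
#' @return An \linkS4class{Ethogram}.
#' @export
readEthogram <- function(path, fps = 60, injectionFrame = 0L) {
  dt <- data.table::fread(path, sep = "\t")
  Ethogram(dt$state, fps = fps, injectionFrame = injectionFrame)
}
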
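#' @include ethogram.R transitions.R profiles.R
NULL

#' Pipeline configuration
#'
#' All tunables of the per-session and cohort analyses, with the published
#' values as defaults where the study prints them (frame rate 60 fps,
#' 600-frame snippets, 10-frame minimum episode, likelihood thresholds
#' 0.95 / 0.80 / 0.79 / 0.90, 100-frame grooming minimum, +/- 2 SD weaving
#' band, 10-s merge gap, 0.078 cm/px).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    fps = 60,
    cm_per_px = 39 / 500,
    snippet_frames = 600L,
    min_duration_frames = 10L,
    likelihood_min = 0.95,        # paw cleaning for locomotion centroids
    max_gap_frames = 60L,
    rearing_occluded_max = 0.80,
    grooming_forepaw_max = 0.79,
    visible_min = 0.90,
    grooming_min_frames = 100L,
    grooming_min_hz = 2,
    band_k = 2,
    sd_floor_deg = 2.5,
    min_cycles = 2L,
    cycle_max_gap_s = 2,
    merge_gap_s = 10,
    locomotor_max_s = 10,
    roll_window_s = 10,
    smooth_window_s = 0.25,
    weaving_reference = "pelvic",
    network_display_threshold = 0.01,
    embed_seed = 0L,
    perplexity = 15,
    k_max = 6L,
    onset_censor_min = 240)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validatePipelineConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

validatePipelineConfig <- function(cfg) {
  required <- names(pipelineConfigRanges())
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  rng <- pipelineConfigRanges()
  for (k in names(rng)) {
    v <- cfg[[k]]
    if (is.numeric(v) && (v < rng[[k]][1] || v > rng[[k]][2]))
      stop("config key '", k, "' = ", v, " outside legal range [",
           rng[[k]][1], ", ", rng[[k]][2], "]")
  }
  invisible(cfg)
}

pipelineConfigRanges <- function() {
  list(fps = c(1, 1000), cm_per_px = c(1e-4, 10),
       snippet_frames = c(2, 1e6), min_duration_frames = c(1, 1e5),
       likelihood_min = c(1e-6, 1 - 1e-6),
       rearing_occluded_max = c(0, 1), grooming_forepaw_max = c(0, 1),
       visible_min = c(0, 1), grooming_min_frames = c(1, 1e6),
       grooming_min_hz = c(0, 30), band_k = c(0.1, 10),
       sd_floor_deg = c(0, 90), min_cycles = c(1, 100),
       cycle_max_gap_s = c(0.1, 600), merge_gap_s = c(0, 3600),
       locomotor_max_s = c(0, 3600), roll_window_s = c(0.5, 3600),
       smooth_window_s = c(0, 10),
       network_display_threshold = c(0, 1), perplexity = c(2, 1000),
       k_max = c(2, 50), onset_censor_min = c(1, 1e4))
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly; unknown keys are rejected on read.
#'
#' @param cfg A \code{PipelineConfig}.
#' @param path YAML file path.
#' @return \code{writePipelineConfig}: the path, invisibly;
#'   \code{readPipelineConfig}: a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  int_keys <- c("snippet_frames", "min_duration_frames", "max_gap_frames",
                "grooming_min_frames", "min_cycles", "embed_seed", "k_max")
  for (k in intersect(int_keys, names(vals)))
    vals[[k]] <- as.integer(vals[[k]])
  do.call(pipelineConfig, vals)
}

configHash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = "|"), ""), collapse = ";")
  # small deterministic polynomial hash; avoids an extra dependency
  h <- 7
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the per-session ethogram pipeline on a pose CSV
#'
#' Reads a DLC-format pose table, computes the five-state ethogram and
#' writes the per-frame TSV, the episode CSV and an occupancy/onset JSON
#' into \code{outDir}. Deterministic given the config; the applied
#' thresholds (and a hash of the full config) are stored in the JSON log.
#'
#' @param poseCsv Path to the pose table.
#' @param config A \code{\link{pipelineConfig}}.
#' @param outDir Output directory (created if needed).
#' @param injectionFrame 0-based first post-injection frame (required
#'   unless 0 is intended and the first snippet is quiet).
#' @param quietSegment Optional \code{c(start, end)} quiet calibration
#'   interval; defaults to the baseline.
#' @return Invisible list with the ethogram, occupancy, onset and output
#'   paths.
#' @export
runEthogram <- function(poseCsv, config = pipelineConfig(),
                        outDir = ".", injectionFrame = 0L,
                        quietSegment = NULL) {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  track <- readPoseTrack(poseCsv, fps = config$fps)
  etho <- computeEthogram(track, injectionFrame = injectionFrame,
                          quietSegment = quietSegment, config = config)
  base <- tools::file_path_sans_ext(basename(poseCsv))
  tsv <- file.path(outDir, paste0(base, "_ethogram.tsv"))
  epi <- file.path(outDir, paste0(base, "_episodes.csv"))
  occJson <- file.path(outDir, paste0(base, "_occupancy.json"))
  writeEthogram(etho, tsvPath = tsv, episodeCsvPath = epi)
  occ <- occupancy(etho)
  onset <- stereotypyOnset(etho)
  jsonlite::write_json(
    list(occupancy = as.list(occ),
         stereotypy_onset_min = if (is.na(onset)) "censored" else onset,
         injection_frame = injectionFrame(etho),
         config_hash = configHash(config),
         thresholds = config[c("likelihood_min", "rearing_occluded_max",
                               "grooming_forepaw_max", "visible_min",
                               "band_k", "merge_gap_s",
                               "min_duration_frames")]),
    occJson, auto_unbox = TRUE, digits = NA)
  invisible(list(ethogram = etho, occupancy = occ, onset = onset,
                 paths = c(ethogram = tsv, episodes = epi,
                           occupancy = occJson)))
}

#' Run the cohort analysis over a session manifest
#'
#' The manifest lists one session per row: either precomputed ethogram
#' TSVs or pose CSVs (columns: \code{path}, \code{kind} in
#' \{"pose", "ethogram"\}, \code{rat_id}, \code{sex}, \code{group},
#' \code{day}, \code{injection_frame}, \code{fps}). Produces the pooled
#' transition matrix and network files, the profile embedding table and a
#' per-session summary CSV.
#'
#' @param manifest data.frame or path to a manifest CSV.
#' @param config A \code{\link{pipelineConfig}}.
#' @param outDir Output directory.
#' @param cluster Run the embedding/clustering step (needs >= 8
#'   sessions), default TRUE.
#' @return Invisible list with profiles, the pooled
#'   \linkS4class{TransitionMatrix}, the \linkS4class{ClusterResult} (or
#'   NULL) and output paths.
#' @export
runCohort <- function(manifest, config = pipelineConfig(), outDir = ".",
                      cluster = TRUE) {
  validatePipelineConfig(config)
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest")
  if (!is.null(manifest$fps) && length(unique(manifest$fps)) > 1L)
    stop("sessions with mismatched fps in one cohort")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  profiles <- list(); counts <- list(); occSum <- rep(0, 5)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    inj <- if (is.null(row$injection_frame)) 0L
           else as.integer(row$injection_frame)
    etho <- if (identical(row$kind, "ethogram"))
      readEthogram(row$path, fps = config$fps, injectionFrame = inj)
    else
      runEthogram(row$path, config, outDir = outDir,
                  injectionFrame = inj)$ethogram
    profiles[[i]] <- behaviorProfile(etho, rat_id = row$rat_id,
                                     sex = row$sex, group = row$group,
                                     day = row$day)
    counts[[i]] <- transitionCounts(extractRuns(etho))
    occSum <- occSum + occupancy(etho)
  }
  profiles <- do.call(rbind, profiles)
  pooled <- poolAndNormalize(counts)
  meanOcc <- occSum / nrow(manifest)
  names(meanOcc) <- behaviorStates()
  net <- exportNetwork(pooled, meanOcc,
                       file.path(outDir, "transition_network"),
                       displayThreshold = config$network_display_threshold)
  writeTransitionMatrix(pooled,
                        countsPath = file.path(outDir,
                                               "transition_counts.csv"),
                        probsPath = file.path(outDir,
                                              "transition_probs.csv"))
  data.table::fwrite(profiles, file.path(outDir, "profiles.csv"))
  cres <- NULL
  if (cluster && nrow(profiles) >= 8L) {
    cres <- clusterProfiles(profiles, seed = config$embed_seed,
                            kMax = min(config$k_max, nrow(profiles) - 1L),
                            perplexity = config$perplexity,
                            censorMin = config$onset_censor_min)
    embDf <- data.frame(rat_id = profiles$rat_id,
                        dim1 = cres@embedding[, 1],
                        dim2 = cres@embedding[, 2],
                        cluster = cres@labels)
    data.table::fwrite(embDf, file.path(outDir, "embedding.csv"))
  }
  invisible(list(profiles = profiles, transitions = pooled,
                 clustering = cres,
                 paths = c(network = net$graphml,
                           counts = file.path(outDir,
                                              "transition_counts.csv"),
                           profiles = file.path(outDir, "profiles.csv"))))
}
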
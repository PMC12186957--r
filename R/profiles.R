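#' @include methods.R
NULL

#' Build a behavior profile from one ethogram
#'
#' @param etho An \linkS4class{Ethogram}.
#' @param rat_id,sex,group,day Session metadata (sex in \{"M","F"\}).
#' @return One-row data.frame with occupancy columns (\code{occ_<state>}),
#'   \code{onset_min} (NA when censored) and the metadata.
#' @export
behaviorProfile <- function(etho, rat_id, sex, group, day) {
  occ <- occupancy(etho)
  df <- data.frame(rat_id = rat_id, sex = sex, group = group,
                   day = as.integer(day))
  for (s in behaviorStates()) df[[paste0("occ_", s)]] <- occ[[s]]
  df$onset_min <- stereotypyOnset(etho)
  df
}

#' Build the numeric profile matrix for embedding
#'
#' One row per rat-session. Columns: the five state occupancies, the
#' stereotypy onset (censored onsets encoded as \code{censorMin} with an
#' indicator column, so non-stereotypic animals are retained), the day,
#' and one-hot encodings of treatment group and sex. All non-constant
#' columns are z-scored; constant columns are set to zero and noted in the
#' schema.
#'
#' @param profiles data.frame with columns rat_id, sex, group, day,
#'   occ_* (5 states) and onset_min.
#' @param censorMin Sentinel (minutes) for censored onsets; default 240,
#'   the 4-hour session length.
#' @param includeMetadata Include day/group/sex columns (default TRUE,
#'   mirroring the original feature set; FALSE gives an occupancy-only
#'   map).
#' @return List with \code{matrix} (numeric, z-scored) and \code{schema}
#'   (column descriptions, encodings and censoring flags).
#' @export
buildProfileMatrix <- function(profiles, censorMin = 240,
                               includeMetadata = TRUE) {
  if (nrow(profiles) < 2L)
    stop("need at least 2 profiles to build a matrix")
  occCols <- paste0("occ_", behaviorStates())
  stopifnot(all(occCols %in% names(profiles)),
            "onset_min" %in% names(profiles))
  censored <- is.na(profiles$onset_min)
  onset <- ifelse(censored, censorMin, profiles$onset_min)
  m <- as.matrix(profiles[, occCols])
  m <- cbind(m, onset_min = onset, onset_censored = as.numeric(censored))
  if (includeMetadata) {
    m <- cbind(m, day = as.numeric(profiles$day))
    for (g in sort(unique(as.character(profiles$group)))) {
      m <- cbind(m, as.numeric(profiles$group == g))
      colnames(m)[ncol(m)] <- paste0("group_", g)
    }
    for (s in sort(unique(as.character(profiles$sex)))) {
      m <- cbind(m, as.numeric(profiles$sex == s))
      colnames(m)[ncol(m)] <- paste0("sex_", s)
    }
  }
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  constant <- sdv < 1e-12
  z <- sweep(m, 2, mu)
  z[, !constant] <- sweep(z[, !constant, drop = FALSE], 2,
                          sdv[!constant], "/")
  z[, constant] <- 0
  list(matrix = z,
       schema = list(columns = colnames(m), center = mu, scale = sdv,
                     constant = colnames(m)[constant],
                     censor_sentinel_min = censorMin,
                     censored_rows = which(censored),
                     include_metadata = includeMetadata))
}

#' Embed profiles with PCA then t-SNE
#'
#' PCA retains the smallest number of components explaining at least
#' \code{varTarget} of the variance (capped at \code{nPcs}, minimum 2);
#' the retained scores are embedded in 2-D with exact t-SNE. Deterministic
#' given \code{seed}. When the row count is below 3 x perplexity + 1 the
#' perplexity is shrunk automatically and recorded in the attributes.
#'
#' @param mat Numeric matrix from \code{\link{buildProfileMatrix}}.
#' @param seed Integer RNG seed, default 0.
#' @param nPcs Maximum principal components, default 10.
#' @param perplexity t-SNE perplexity, default 15.
#' @param varTarget Variance fraction the PCs must explain, default 0.9.
#' @return n x 2 matrix (columns dim1, dim2) with attributes
#'   \code{perplexity}, \code{nPcs}, \code{varianceExplained}, \code{seed}.
#' @export
embedProfiles <- function(mat, seed = 0L, nPcs = 10L, perplexity = 15,
                          varTarget = 0.9) {
  if (nrow(mat) < 4L) stop("too few rows to embed")
  if (all(apply(mat, 2, stats::sd) < 1e-12))
    stop("degenerate matrix: all rows identical")
  pca <- stats::prcomp(mat, center = FALSE, scale. = FALSE)
  varFrac <- pca$sdev^2 / sum(pca$sdev^2)
  k <- which(cumsum(varFrac) >= varTarget)[1]
  if (is.na(k)) k <- length(varFrac)
  k <- max(2L, min(k, nPcs, ncol(pca$x)))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  maxPerp <- floor((nrow(mat) - 1) / 3)
  usedPerp <- min(perplexity, maxPerp)
  if (usedPerp < perplexity)
    message("perplexity shrunk to ", usedPerp, " for ", nrow(mat), " rows")
  set.seed(as.integer(seed))
  ts <- Rtsne::Rtsne(scores, dims = 2, perplexity = usedPerp,
                     theta = 0, pca = FALSE, max_iter = 1000,
                     check_duplicates = FALSE)
  emb <- ts$Y
  colnames(emb) <- c("dim1", "dim2")
  structure(emb, perplexity = usedPerp, nPcs = k,
            varianceExplained = sum(varFrac[seq_len(k)]),
            seed = as.integer(seed))
}

wssForLabels <- function(embedding, labels) {
  tot <- 0
  for (l in unique(labels)) {
    pts <- embedding[labels == l, , drop = FALSE]
    ctr <- colMeans(pts)
    tot <- tot + sum(sweep(pts, 2, ctr)^2)
  }
  tot
}

#' Cluster a 2-D embedding with elbow-based k selection
#'
#' Agglomerative clustering (Ward linkage, Euclidean distance) on the
#' embedding. The within-cluster sum of squares (WSS) is computed for
#' k = 1..kMax; the cluster count is the k with the maximum second
#' difference of the WSS curve (ties to the smaller k). The elbow strength
#' -- the winning second difference normalized by the total sum of squares
#' -- is reported; when it falls below \code{minStrength} the curve has no
#' dominant elbow and a single cluster (k = 1) is returned with the low
#' strength score.
#'
#' @param embedding n x 2 matrix from \code{\link{embedProfiles}}.
#' @param kMax Largest k examined, default 6 (must be >= 2; needs at least
#'   kMax + 1 points).
#' @param minStrength Elbow-strength floor below which k = 1 is reported,
#'   default 0.4.
#' @param seed Seed recorded in the result (labels are deterministic).
#' @return A \linkS4class{ClusterResult}.
#' @export
clusterEmbedding <- function(embedding, kMax = 6L, minStrength = 0.4,
                             seed = 0L) {
  if (kMax < 2L) stop("argument error: kMax must be >= 2")
  n <- nrow(embedding)
  if (n < kMax + 1L) stop("need at least kMax + 1 points")
  hc <- stats::hclust(stats::dist(embedding), method = "ward.D2")
  wss <- vapply(seq_len(kMax), function(k)
    wssForLabels(embedding, stats::cutree(hc, k = k)), numeric(1))
  if (kMax >= 3L) {
    ks <- 2:(kMax - 1L)
    d2 <- wss[ks - 1L] - 2 * wss[ks] + wss[ks + 1L]
    kStar <- ks[which.max(d2)]
    strength <- max(d2) / max(wss[1], .Machine$double.eps)
  } else {
    kStar <- 2L
    strength <- (wss[1] - wss[2]) / max(wss[1], .Machine$double.eps)
  }
  if (strength < minStrength) {
    k <- 1L
    labels <- rep(1L, n)
  } else {
    k <- as.integer(kStar)
    labels <- as.integer(stats::cutree(hc, k = k))
  }
  methods::new("ClusterResult", embedding = embedding, labels = labels,
               k = k, wss = wss, elbowStrength = strength,
               linkage = hc, seed = as.integer(seed))
}

#' Embed and cluster a profile table in one call
#'
#' @param profiles Profile data.frame (see \code{\link{behaviorProfile}}).
#' @param seed Seed for the embedding.
#' @param ... Passed on to \code{\link{buildProfileMatrix}},
#'   \code{\link{embedProfiles}} and \code{\link{clusterEmbedding}}.
#' @param kMax,perplexity See the component functions.
#' @return A \linkS4class{ClusterResult}; the embedding rows follow the
#'   profile rows.
#' @export
clusterProfiles <- function(profiles, seed = 0L, kMax = 6L,
                            perplexity = 15, ...) {
  pm <- buildProfileMatrix(profiles, ...)
  emb <- embedProfiles(pm$matrix, seed = seed, perplexity = perplexity)
  clusterEmbedding(emb, kMax = kMax, seed = seed)
}
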
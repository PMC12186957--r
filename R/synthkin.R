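#' @include ethogram.R
NULL

#' Default kinematic parameters for the synthetic generator
#'
#' Units: degrees, Hz, cm/s, px. Likelihoods are modelled as two noisy
#' levels -- visible (about 0.975) and occluded (about 0.40) -- because
#' the detection rules only reference thresholds, not full confidence
#' distributions. Weaving amplitude (25 deg) and frequency (1.5 Hz) are
#' plausible values for rhythmic head weaving; they are configuration, not
#' claims about real animals.
#'
#' @return Named list of parameters.
#' @export
defaultKinematicParams <- function() {
  list(
    weaving_amp_deg = 25,      # head-angle oscillation amplitude
    weaving_freq_hz = 1.5,     # head-angle oscillation frequency
    locomotion_speed_cms = 8,  # forward speed during locomotion
    heading_sd = 0.06,         # per-frame heading random-walk SD (rad)
    grooming_hz = 6,           # forepaw scratch oscillation frequency
    grooming_amp_px = 6,       # forepaw scratch oscillation amplitude
    jitter_px = 1,             # per-keypoint Gaussian jitter SD
    lik_visible = 0.975,       # mean likelihood of a visible keypoint
    lik_visible_sd = 0.008,
    lik_occluded = 0.40,       # mean likelihood of an occluded keypoint
    lik_occluded_sd = 0.08)
}

#' Construct a SyntheticScript
#'
#' A script is the ground truth for one rendered session: a quiet
#' pre-injection baseline of \code{baselineS} seconds followed by the
#' given post-injection state sequence.
#'
#' @param states data.frame with columns \code{state} (one of
#'   \code{behaviorStates()}) and \code{duration_s}.
#' @param seed Integer RNG seed.
#' @param fps Frame rate, default 60.
#' @param baselineS Baseline duration in seconds, default 900, matching
#'   the study's 15-minute pre-injection baseline; the 90 quiet snippets
#'   it provides make the calibrated speed threshold stable.
#' @param params Kinematic parameters; entries override
#'   \code{\link{defaultKinematicParams}}.
#' @param arena Arena geometry, see \code{\link{defaultArena}}.
#' @return A \linkS4class{SyntheticScript}.
#' @export
syntheticScript <- function(states, seed = 1L, fps = 60, baselineS = 900,
                            params = list(), arena = defaultArena()) {
  p <- defaultKinematicParams()
  p[names(params)] <- params
  methods::new("SyntheticScript", seed = as.integer(seed),
               fps = as.numeric(fps), baselineS = as.numeric(baselineS),
               states = as.data.frame(states), params = p, arena = arena)
}

#' Ground-truth per-frame labels of a script
#'
#' @param script A \linkS4class{SyntheticScript}.
#' @return An \linkS4class{Ethogram} with the scripted labels (baseline
#'   frames are quiet-awake) and the injection frame at the end of the
#'   baseline.
#' @export
scriptTruth <- function(script) {
  f <- fps(script)
  baseFrames <- secondsToFrames(script@baselineS, f)
  stFrames <- secondsToFrames(script@states$duration_s, f)
  labels <- c(rep("quiet_awake", baseFrames),
              rep(script@states$state, stFrames))
  Ethogram(labels, fps = f, injectionFrame = baseFrames)
}

# body geometry in px, bottom view, relative to the column point and the
# heading unit vector u = (cos th, sin th), lateral vector w = (-sin, cos)
bodyOffsets <- function() {
  list(nose = c(60, 0),
       forepaw_left = c(35, -15), forepaw_right = c(35, 15),
       hindpaw_left = c(-25, -15), hindpaw_right = c(-25, 15),
       column = c(0, 0), tail_base = c(-45, 0))
}

#' Render a synthetic keypoint session from a script
#'
#' Renders the seven-keypoint track frame by frame. The body frame
#' (column, hind paws, tail base) follows a smooth trajectory: stationary
#' with jitter during quiet-awake, grooming, rearing and weaving; a
#' heading-persistent walk at the scripted speed during locomotion
#' (reflecting off the arena walls, with reflections logged). Head weaving
#' swings the nose about the body axis as A sin(2 pi f t). Rearing draws
#' nose and forepaw likelihoods from the occluded level while the hind
#' paws stay visible; grooming oscillates the forepaws at the scripted
#' frequency with occluded likelihood while everything else stays visible
#' and stationary. Reproducible given the script seed.
#'
#' @param script A \linkS4class{SyntheticScript}.
#' @return List with \code{track} (\linkS4class{KeypointTrack}),
#'   \code{truth} (\linkS4class{Ethogram}) and \code{script}.
#' @export
generateSession <- function(script) {
  stopifnot(methods::is(script, "SyntheticScript"))
  p <- script@params
  f <- fps(script)
  ar <- script@arena
  truth <- scriptTruth(script)
  labels <- as.character(stateLabels(truth))
  n <- length(labels)
  parts <- bodyPartNames()
  off <- bodyOffsets()

  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(script@seed)

  # body trajectory: position of the column point + heading
  margin <- 90
  px <- numeric(n); py <- numeric(n); th <- numeric(n)
  px[1] <- ar$width_px / 2; py[1] <- ar$height_px / 2
  th[1] <- stats::runif(1, 0, 2 * pi)
  stepPx <- p$locomotion_speed_cms / ar$cm_per_px / f
  dth <- stats::rnorm(n, 0, p$heading_sd)
  for (i in seq_len(n)[-1]) {
    if (labels[i] == "locomotion") {
      th[i] <- th[i - 1] + dth[i]
      px[i] <- px[i - 1] + stepPx * cos(th[i])
      py[i] <- py[i - 1] + stepPx * sin(th[i])
      # reflect at the walls (body must stay inside the arena)
      if (px[i] < margin || px[i] > ar$width_px - margin) {
        th[i] <- pi - th[i]
        px[i] <- min(max(px[i], margin), ar$width_px - margin)
      }
      if (py[i] < margin || py[i] > ar$height_px - margin) {
        th[i] <- -th[i]
        py[i] <- min(max(py[i], margin), ar$height_px - margin)
      }
    } else {
      th[i] <- th[i - 1]
      px[i] <- px[i - 1]
      py[i] <- py[i - 1]
    }
  }

  # head angle about the body axis: sinusoidal during weaving, 0 otherwise
  tSec <- (seq_len(n) - 1) / f
  alpha <- numeric(n)
  weav <- labels == "stereotypy"
  if (any(weav))
    alpha[weav] <- p$weaving_amp_deg * pi / 180 *
      sin(2 * pi * p$weaving_freq_hz * tSec[weav])

  ux <- cos(th); uy <- sin(th)    # heading unit vector
  wx <- -uy; wy <- ux             # lateral unit vector

  x <- matrix(0, n, 7, dimnames = list(NULL, parts))
  y <- matrix(0, n, 7, dimnames = list(NULL, parts))
  for (part in parts) {
    o <- off[[part]]
    x[, part] <- px + o[1] * ux + o[2] * wx
    y[, part] <- py + o[1] * uy + o[2] * wy
  }
  # weaving: swing the nose about the pelvic centroid so that the
  # recovered body-axis-to-nose angle equals alpha
  pcx <- rowMeans(x[, c("hindpaw_left", "hindpaw_right", "tail_base")])
  pcy <- rowMeans(y[, c("hindpaw_left", "hindpaw_right", "tail_base")])
  rNose <- sqrt((x[, "nose"] - pcx)^2 + (y[, "nose"] - pcy)^2)
  x[, "nose"] <- pcx + rNose * cos(th + alpha)
  y[, "nose"] <- pcy + rNose * sin(th + alpha)

  # grooming: forepaws scratch back and forth along the body axis
  groom <- labels == "grooming"
  if (any(groom)) {
    osc <- p$grooming_amp_px * sin(2 * pi * p$grooming_hz * tSec[groom])
    for (part in c("forepaw_left", "forepaw_right")) {
      x[groom, part] <- x[groom, part] + osc * ux[groom]
      y[groom, part] <- y[groom, part] + osc * uy[groom]
    }
  }

  if (p$jitter_px > 0) {
    x <- x + matrix(stats::rnorm(n * 7, 0, p$jitter_px), n, 7)
    y <- y + matrix(stats::rnorm(n * 7, 0, p$jitter_px), n, 7)
  }

  lik <- matrix(stats::rnorm(n * 7, p$lik_visible, p$lik_visible_sd),
                n, 7, dimnames = list(NULL, parts))
  rear <- labels == "rearing"
  occl <- function(k) stats::rnorm(k, p$lik_occluded, p$lik_occluded_sd)
  if (any(rear))
    for (part in c("nose", "forepaw_left", "forepaw_right"))
      lik[rear, part] <- occl(sum(rear))
  if (any(groom))
    for (part in c("forepaw_left", "forepaw_right"))
      lik[groom, part] <- occl(sum(groom))
  lik <- pmin(pmax(lik, 0), 1)

  track <- KeypointTrack(
    x, y, lik, fps = f,
    sessionMeta = list(baseline_end_frame = injectionFrame(truth),
                       seed = script@seed),
    arena = ar)
  list(track = track, truth = truth, script = script)
}

#' Sample a random post-injection state sequence
#'
#' Draws a sequence of behavioral bouts whose expected occupancy matches
#' the target fractions: bout states are sampled proportionally to the
#' targets (never repeating the previous state), bout durations are
#' exponential with state-specific means. Used to script whole synthetic
#' sessions.
#'
#' @param targetOccupancy Named numeric vector over (a subset of) the five
#'   states, summing to 1.
#' @param durationS Total duration to fill (seconds).
#' @param meanBoutS Named mean bout duration per state (seconds); default
#'   20 s for every state, 10 s for grooming and rearing.
#' @param minBoutS Minimum bout duration, default 2 s.
#' @return data.frame(state, duration_s) summing to \code{durationS}.
#' @export
sampleStateSequence <- function(targetOccupancy, durationS,
                                meanBoutS = NULL, minBoutS = 2) {
  targetOccupancy <- targetOccupancy[targetOccupancy > 0]
  states <- names(targetOccupancy)
  if (is.null(meanBoutS)) {
    meanBoutS <- stats::setNames(rep(20, length(states)), states)
    meanBoutS[intersect(states, c("grooming", "rearing"))] <- 10
  }
  # exact time allocation per state, split into randomly sized bouts and
  # shuffled; occupancy therefore matches the target by construction
  # (adjacent same-state bouts simply merge into one longer run)
  targetOccupancy <- targetOccupancy / sum(targetOccupancy)
  allState <- character(); allDur <- numeric()
  for (s in states) {
    total <- targetOccupancy[[s]] * durationS
    nb <- max(1L, as.integer(round(total / meanBoutS[[s]])))
    while (nb > 1L && total / nb < minBoutS) nb <- nb - 1L
    w <- stats::rexp(nb) + 0.3
    d <- total * w / sum(w)
    # enforce the minimum bout length, preserving the total
    if (nb > 1L) {
      d <- pmax(d, minBoutS)
      d <- d * total / sum(d)
    }
    allState <- c(allState, rep(s, nb))
    allDur <- c(allDur, d)
  }
  ord <- sample(length(allState))
  data.frame(state = allState[ord], duration_s = allDur[ord])
}

#' Simulate run sequences from a known run-level transition kernel
#'
#' Generates sessions whose run-to-run transitions follow \code{kernel}
#' exactly (a 5x5 row-stochastic matrix with zero diagonal) with
#' geometric run lengths, returning ground-truth ethograms. Used to
#' verify that the transition-matrix pipeline recovers a known kernel.
#'
#' @param kernel 5x5 row-stochastic matrix (states x states, zero
#'   diagonal).
#' @param nSessions Number of sessions.
#' @param runsPerSession Runs per session.
#' @param meanRunFrames Mean geometric run length in frames, default 300.
#' @param fps Frame rate, default 60.
#' @param seed RNG seed.
#' @return List of \linkS4class{Ethogram} objects.
#' @export
simulateKernelSessions <- function(kernel, nSessions = 20L,
                                   runsPerSession = 100L,
                                   meanRunFrames = 300, fps = 60,
                                   seed = 1L) {
  st <- behaviorStates()
  stopifnot(identical(dim(kernel), c(5L, 5L)),
            all(abs(rowSums(kernel) - 1) < 1e-9),
            all(diag(kernel) == 0))
  set.seed(as.integer(seed))
  lapply(seq_len(nSessions), function(i) {
    s <- sample(5L, 1L)
    states <- integer(runsPerSession)
    states[1] <- s
    for (r in 2:runsPerSession)
      states[r] <- sample(5L, 1L, prob = kernel[states[r - 1L], ])
    lens <- 1L + stats::rgeom(runsPerSession, 1 / meanRunFrames)
    Ethogram(rep(st[states], lens), fps = fps, injectionFrame = 0L)
  })
}

#' Built-in cohort archetypes for validation
#'
#' Two contrasting motor profiles: a stereotypy-dominant archetype
#' (modelled on a dopaminergic appetite suppressant: most of the session
#' spent head weaving with a short onset) and a quiet-dominant archetype
#' (modelled on vehicle treatment: mostly quiet-awake with exploratory
#' locomotion and rearing, no stereotypy).
#'
#' @return Named list of archetype definitions (target occupancies, onset
#'   range in minutes, group label).
#' @export
archetypeTemplates <- function() {
  list(
    stereotypy_dominant = list(
      group = "stereotypy_dominant",
      occupancy = c(stereotypy = 0.60, quiet_awake = 0.15,
                    locomotion = 0.10, grooming = 0.07, rearing = 0.08),
      onset_range_min = c(1, 2.5)),
    quiet_dominant = list(
      group = "quiet_dominant",
      occupancy = c(quiet_awake = 0.65, locomotion = 0.18,
                    grooming = 0.09, rearing = 0.08),
      onset_range_min = c(NA, NA)))
}

jitterOccupancy <- function(occ, sd = 0.05) {
  o <- pmax(occ * exp(stats::rnorm(length(occ), 0, sd)), 1e-3)
  o / sum(o)
}

#' Generate a synthetic cohort with ground-truth profiles
#'
#' Draws \code{n} sessions per archetype with per-session jittered target
#' occupancies, returning the scripts, ground-truth ethograms and the
#' ground-truth \code{BehaviorProfile} table. Rendering full keypoint
#' tracks is optional (\code{render = TRUE}); profile-level analyses only
#' need the truth ethograms.
#'
#' @param archetypes List as from \code{\link{archetypeTemplates}}.
#' @param n Sessions per archetype, default 20.
#' @param seed RNG seed.
#' @param sessionMin Post-injection session length in minutes, default 10.
#' @param days Treatment days cycled across sessions (1..7).
#' @param render Render keypoint tracks (slow); default FALSE.
#' @param fps Frame rate.
#' @return List with \code{sessions} (each: script, truth and optionally
#'   track) and \code{profiles} (ground-truth profile data.frame).
#' @export
generateCohort <- function(archetypes = archetypeTemplates(), n = 20L,
                           seed = 1L, sessionMin = 10, days = 1:7,
                           render = FALSE, fps = 60) {
  stopifnot(length(archetypes) >= 1L)
  set.seed(as.integer(seed))
  sessions <- list(); profiles <- list()
  id <- 0L
  for (arch in archetypes) {
    for (j in seq_len(n)) {
      id <- id + 1L
      occ <- jitterOccupancy(arch$occupancy)
      day <- days[(j - 1L) %% length(days) + 1L]
      sex <- c("M", "F")[(j %% 2L) + 1L]
      durS <- sessionMin * 60
      if ("stereotypy" %in% names(occ) && !is.na(arch$onset_range_min[1])) {
        onset <- stats::runif(1, arch$onset_range_min[1],
                              min(arch$onset_range_min[2], sessionMin * 0.25))
        preS <- onset * 60
        pre <- sampleStateSequence(
          occ[setdiff(names(occ), "stereotypy")] /
            sum(occ[setdiff(names(occ), "stereotypy")]), preS)
        # inflate the post-onset stereotypy share so the whole-session
        # occupancy still hits the archetype target
        postOcc <- occ
        postOcc["stereotypy"] <- min(0.9, occ[["stereotypy"]] *
                                       durS / (durS - preS))
        postOcc <- postOcc / sum(postOcc)
        post <- sampleStateSequence(postOcc, durS - preS)
        # the first post-onset bout is stereotypy, at the scripted onset
        post <- rbind(data.frame(state = "stereotypy", duration_s = 20),
                      post)
        post$duration_s <- post$duration_s * (durS - preS) /
          sum(post$duration_s)
        states <- rbind(pre, post)
      } else {
        states <- sampleStateSequence(occ, durS)
      }
      scr <- syntheticScript(states, seed = seed * 10000L + id,
                             fps = fps, baselineS = 900)
      truth <- scriptTruth(scr)
      ses <- if (render) generateSession(scr)
             else list(track = NULL, truth = truth, script = scr)
      sessions[[id]] <- ses
      profiles[[id]] <- behaviorProfile(
        truth, rat_id = sprintf("rat%03d", id), sex = sex,
        group = arch$group, day = day)
    }
  }
  list(sessions = sessions, profiles = do.call(rbind, profiles))
}
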
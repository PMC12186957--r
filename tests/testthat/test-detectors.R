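quietMotion <- function(nSnippets) {
  structure(rep("quiet_awake", nSnippets),
            partial = rep(FALSE, nSnippets))
}

test_that("a constant angle yields no weaving episodes", {
  ang <- rep(3, 36000)
  eps <- detectHeadWeaving(ang, quietMotion(60))
  expect_equal(nrow(eps), 0L)
})

test_that("the 10-s rule merges close bouts and keeps distant ones apart", {
  # synthetic angle: two 30-s sinusoidal bouts around a flat trace
  mkAngle <- function(gapS) {
    t1 <- seq(0, 30, by = 1 / 60)[-1]
    bout <- 25 * sin(2 * pi * 1.5 * t1)
    c(rep(0, 36000), bout, rep(0, gapS * 60), bout, rep(0, 6000))
  }
  angClose <- mkAngle(5)
  epsClose <- detectHeadWeaving(angClose,
                                quietMotion(ceiling(length(angClose) / 600)),
                                referenceFrames = 1:36000)
  expect_equal(nrow(epsClose), 1L)

  angFar <- mkAngle(15)
  epsFar <- detectHeadWeaving(angFar,
                              quietMotion(ceiling(length(angFar) / 600)),
                              referenceFrames = 1:36000)
  expect_equal(nrow(epsFar), 2L)
  # merging the already-merged episodes changes nothing
  expect_equal(mergeWeavingEpisodes(epsFar), epsFar)
  expect_equal(mergeWeavingEpisodes(epsClose), epsClose)
})

test_that("weaving bouts containing a major locomotor event are rejected", {
  t1 <- seq(0, 60, by = 1 / 60)[-1]
  ang <- c(rep(0, 6000), 25 * sin(2 * pi * 1.5 * t1), rep(0, 6000))
  nSnip <- ceiling(length(ang) / 600)
  # a 20-s locomotor block in the middle of the bout
  motion <- rep("quiet_awake", nSnip)
  motion[13:14] <- "locomotion"
  eps <- detectHeadWeaving(ang, structure(motion,
                                          partial = rep(FALSE, nSnip)),
                           referenceFrames = 1:6000)
  expect_equal(nrow(eps), 0L)
  # a single 10-s event is a minor interruption and is tolerated
  motion2 <- rep("quiet_awake", nSnip)
  motion2[13] <- "locomotion"
  eps2 <- detectHeadWeaving(ang, structure(motion2,
                                           partial = rep(FALSE, nSnip)),
                            referenceFrames = 1:6000)
  expect_equal(nrow(eps2), 1L)
})

test_that("weaving occupancy is recovered within 5 points on scripted sessions", {
  for (seed in c(2, 6)) {
    states <- data.frame(
      state = c("quiet_awake", "stereotypy", "quiet_awake", "stereotypy",
                "quiet_awake"),
      duration_s = c(40, 100, 60, 100, 200))   # 40% weaving
    ses <- generateSession(syntheticScript(states, seed = seed,
                                           baselineS = 900))
    etho <- computeEthogram(ses$track)
    occ <- occupancy(etho)
    expect_lt(abs(occ[["stereotypy"]] - 0.4), 0.05)
  }
})

test_that("rearing follows the occlusion rule exactly", {
  tr <- makeStillTrack(200)
  expect_equal(nrow(detectRearing(tr)), 0L)

  l <- likelihoods(tr)
  l[61:120, "nose"] <- 0.3
  l[61:120, "forepaw_left"] <- 0.5
  tr2 <- KeypointTrack(xCoords(tr), yCoords(tr), l)
  eps <- detectRearing(tr2)
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$start, 60L)
  expect_equal(eps$end, 120L)

  # a hind paw dipping to 0.85 excludes those frames
  l[81:90, "hindpaw_right"] <- 0.85
  tr3 <- KeypointTrack(xCoords(tr), yCoords(tr), l)
  eps3 <- detectRearing(tr3)
  expect_equal(nrow(eps3), 2L)
  expect_false(any(eps3$start < 90 & eps3$end > 80))
})

test_that("grooming requires 100 consecutive candidate frames", {
  mkGroomTrack <- function(runLen) {
    tr <- makeStillTrack(300)
    x <- xCoords(tr); l <- likelihoods(tr)
    idx <- 101:(100 + runLen)
    l[idx, "forepaw_left"] <- 0.4
    t <- (seq_along(idx) - 1) / 60
    x[idx, "forepaw_left"] <- x[idx, "forepaw_left"] +
      6 * sin(2 * pi * 6 * t)
    KeypointTrack(x, yCoords(tr), l)
  }
  expect_equal(nrow(detectGrooming(mkGroomTrack(99))), 0L)
  eps <- detectGrooming(mkGroomTrack(100))
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$end - eps$start, 100L)
})

test_that("still occluded forepaws are not grooming", {
  tr <- makeStillTrack(300)
  l <- likelihoods(tr)
  l[50:250, "forepaw_left"] <- 0.4    # occluded but not oscillating
  tr2 <- KeypointTrack(xCoords(tr), yCoords(tr), l)
  expect_equal(nrow(detectGrooming(tr2)), 0L)
})

test_that("scripted grooming bouts are recovered at the frame level", {
  states <- data.frame(
    state = c("quiet_awake", "grooming", "quiet_awake", "grooming",
              "quiet_awake"),
    duration_s = c(30, 20, 30, 15, 25))
  ses <- generateSession(syntheticScript(states, seed = 9, baselineS = 0))
  eps <- detectGrooming(ses$track)
  got <- rep(FALSE, nFrames(ses$track))
  for (i in seq_len(nrow(eps))) got[(eps$start[i] + 1):eps$end[i]] <- TRUE
  truth <- as.character(stateLabels(ses$truth)) == "grooming"
  expect_gt(mean(got == truth), 0.9)
})
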
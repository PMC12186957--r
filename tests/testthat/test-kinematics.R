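test_that("centroid is the arithmetic mean of the selected parts", {
  tr <- makeStillTrack(4)
  x <- xCoords(tr); y <- yCoords(tr)
  x[, "forepaw_left"] <- 0; y[, "forepaw_left"] <- 0
  x[, "forepaw_right"] <- 2; y[, "forepaw_right"] <- 0
  tr2 <- KeypointTrack(x, y, likelihoods(tr))
  cen <- centroidSeries(tr2, c("forepaw_left", "forepaw_right"))
  expect_equal(unname(cen[, "x"]), rep(1, 4))
  expect_equal(unname(cen[, "y"]), rep(0, 4))

  # all paws at one point -> centroid is that point
  paws <- c("forepaw_left", "forepaw_right", "hindpaw_left",
            "hindpaw_right")
  for (p in paws) { x[, p] <- 7; y[, p] <- 11 }
  tr3 <- KeypointTrack(x, y, likelihoods(tr))
  cen3 <- centroidSeries(tr3, paws)
  expect_equal(unname(cen3[, "x"]), rep(7, 4))
  expect_equal(unname(cen3[, "y"]), rep(11, 4))

  expect_error(centroidSeries(tr, character()), "at least 2")
})

test_that("centroid matches a brute-force per-frame mean on random data", {
  tr <- randomTrack(30, seed = 8)
  paws <- c("forepaw_left", "forepaw_right", "hindpaw_left",
            "hindpaw_right")
  cen <- centroidSeries(tr, paws)
  for (i in c(1, 13, 30)) {
    expect_equal(unname(cen[i, "x"]), mean(xCoords(tr)[i, paws]))
    expect_equal(unname(cen[i, "y"]), mean(yCoords(tr)[i, paws]))
  }
})

test_that("displacement is the per-step Euclidean norm", {
  still <- cbind(x = rep(3, 10), y = rep(4, 10))
  expect_equal(displacementSeries(still), rep(0, 9))

  moving <- cbind(x = 3 * (0:9), y = 4 * (0:9))
  expect_equal(displacementSeries(moving), rep(5, 9))

  set.seed(4)
  rw <- cbind(x = cumsum(rnorm(50)), y = cumsum(rnorm(50)))
  d <- displacementSeries(rw)
  byHand <- vapply(1:49, function(i)
    sqrt(sum((rw[i + 1, ] - rw[i, ])^2)), numeric(1))
  expect_equal(d, byHand)
  expect_true(all(d >= 0))

  expect_warning(out <- displacementSeries(rw[1, , drop = FALSE]),
                 "fewer than 2")
  expect_length(out, 0)
})

test_that("speed threshold calibration reproduces a brute-force maximum", {
  scr <- syntheticScript(
    data.frame(state = "quiet_awake", duration_s = 60),
    seed = 21, baselineS = 60)
  ses <- generateSession(scr)
  thr <- calibrateSpeedThreshold(ses$track, c(0, 7200))
  paws <- c("forepaw_left", "forepaw_right", "hindpaw_left",
            "hindpaw_right")
  cen <- centroidSeries(cleanTrack(ses$track, parts = paws), paws)
  disp <- displacementSeries(cen[1:7200, ])   # 7199 steps: 11 full snippets
  brute <- max(vapply(0:10, function(k)
    mean(disp[(k * 600 + 1):((k + 1) * 600)]) * 60 * defaultArena()$cm_per_px,
    numeric(1)))
  expect_equal(thr, brute, tolerance = 1e-9)

  # zero jitter -> the animal is perfectly still -> threshold 0
  scr0 <- syntheticScript(
    data.frame(state = "quiet_awake", duration_s = 60),
    seed = 21, baselineS = 60, params = list(jitter_px = 0))
  ses0 <- generateSession(scr0)
  expect_equal(calibrateSpeedThreshold(ses0$track, c(0, 7200)), 0)

  expect_error(calibrateSpeedThreshold(ses$track, c(0, 300)),
               "calibration error")
})

test_that("threshold grows with keypoint jitter", {
  thrAt <- function(sigma, seed) {
    scr <- syntheticScript(
      data.frame(state = "quiet_awake", duration_s = 30),
      seed = seed, baselineS = 120, params = list(jitter_px = sigma))
    calibrateSpeedThreshold(generateSession(scr)$track, c(0, 7200))
  }
  for (seed in c(3, 14, 25)) {
    expect_lt(thrAt(0.5, seed), thrAt(2, seed))
  }
})

test_that("motion classification applies the threshold rule exactly", {
  # all-zero displacement -> every snippet quiet
  lab <- classifyMotion(rep(0, 1800), threshold = 1)
  expect_equal(as.character(lab), rep("quiet_awake", 3))

  # one snippet at twice the threshold -> exactly that snippet locomotion
  cmpx <- defaultArena()$cm_per_px
  stepFor <- function(cms) cms / 60 / cmpx
  disp <- c(rep(stepFor(0.5), 600), rep(stepFor(2), 600),
            rep(stepFor(0.5), 600))
  lab2 <- classifyMotion(disp, threshold = 1)
  expect_equal(as.character(lab2),
               c("quiet_awake", "locomotion", "quiet_awake"))

  # trailing partial snippet labelled by the same rule and flagged
  lab3 <- classifyMotion(c(disp, rep(stepFor(2), 100)), threshold = 1)
  expect_equal(as.character(lab3)[4], "locomotion")
  expect_equal(attr(lab3, "partial"), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("motion classification agrees with a per-snippet mean-speed oracle", {
  set.seed(77)
  disp <- abs(rnorm(4200, 1.2, 0.8))
  thr <- 4
  lab <- classifyMotion(disp, threshold = thr)
  oracle <- vapply(seq_along(lab), function(k) {
    idx <- ((k - 1) * 600 + 1):min(k * 600, length(disp))
    sp <- mean(disp[idx]) * 60 * defaultArena()$cm_per_px
    if (sp <= thr) "quiet_awake" else "locomotion"
  }, "")
  expect_equal(as.character(lab), oracle)
})

test_that("head angle is zero on-axis and +/-90 degrees perpendicular", {
  tr <- makeStillTrack(1)
  # geometry: pelvic centroid at (328.33, 240), column at (360, 240),
  # so the body axis points along +x
  ang0 <- headAngleSeries(tr)
  expect_equal(unname(ang0[1]), 0, tolerance = 1e-9)

  x <- xCoords(tr); y <- yCoords(tr)
  pc <- c(mean(x[1, c("hindpaw_left", "hindpaw_right", "tail_base")]),
          mean(y[1, c("hindpaw_left", "hindpaw_right", "tail_base")]))
  # nose perpendicular to the axis at equal distance
  x[1, "nose"] <- pc[1]
  y[1, "nose"] <- pc[2] + 50
  tr90 <- KeypointTrack(x, y, likelihoods(tr))
  expect_equal(abs(unname(headAngleSeries(tr90)[1])), 90,
               tolerance = 1e-9)
})

test_that("head angle recovers a scripted weaving amplitude within 5%", {
  amp <- 25
  scr <- syntheticScript(
    data.frame(state = "stereotypy", duration_s = 30),
    seed = 10, baselineS = 0, params = list(jitter_px = 0.3))
  ang <- headAngleSeries(generateSession(scr)$track)
  # a sinusoid of amplitude A has SD A / sqrt(2); sd is robust to the
  # occasional jitter extreme that a max would pick up
  got <- sd(ang) * sqrt(2)
  expect_gt(got, amp * 0.95)
  expect_lt(got, amp * 1.05)
})

test_that("degenerate frames carry the previous angle and are flagged", {
  tr <- makeStillTrack(3)
  x <- xCoords(tr); y <- yCoords(tr)
  pcx <- mean(x[1, c("hindpaw_left", "hindpaw_right", "tail_base")])
  pcy <- mean(y[1, c("hindpaw_left", "hindpaw_right", "tail_base")])
  x[2, "nose"] <- pcx; y[2, "nose"] <- pcy
  tr2 <- KeypointTrack(x, y, likelihoods(tr))
  ang <- headAngleSeries(tr2)
  expect_equal(ang[2], ang[1])
  expect_equal(attr(ang, "degenerate"), 1L)
})
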
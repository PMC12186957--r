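test_that("a DLC-format CSV parses to an identical track", {
  f <- withr::local_tempfile(fileext = ".csv")
  scorer <- rep("net", 21)
  parts <- rep(partNames, each = 3)
  coords <- rep(c("x", "y", "likelihood"), 7)
  rows <- c(paste(c("scorer", scorer), collapse = ","),
            paste(c("bodyparts", parts), collapse = ","),
            paste(c("coords", coords), collapse = ","),
            paste(c(0, rep(c(100, 200, 0.91), 7)), collapse = ","),
            paste(c(1, rep(c(101, 201, 0.92), 7)), collapse = ","))
  writeLines(rows, f)
  tr <- readPoseTrack(f)
  expect_s4_class(tr, "KeypointTrack")
  expect_equal(nFrames(tr), 2L)
  expect_equal(unname(xCoords(tr)[1, ]), rep(100, 7))
  expect_equal(unname(yCoords(tr)[2, ]), rep(201, 7))
  expect_equal(unname(likelihoods(tr)[, "nose"]), c(0.91, 0.92))
})

test_that("write/read round trip is lossless and byte-stable", {
  ses <- generateSession(syntheticScript(
    data.frame(state = "quiet_awake", duration_s = 10),
    seed = 5, baselineS = 0))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writePoseTrack(ses$track, f1)
  back <- readPoseTrack(f1)
  expect_equal(xCoords(back), xCoords(ses$track), tolerance = 1e-12)
  expect_equal(yCoords(back), yCoords(ses$track), tolerance = 1e-12)
  expect_equal(likelihoods(back), likelihoods(ses$track),
               tolerance = 1e-12)
  writePoseTrack(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("parser and writer invert each other on random tracks", {
  for (seed in c(2, 9, 31)) {
    tr <- randomTrack(frames = 25, seed = seed)
    f <- withr::local_tempfile(fileext = ".csv")
    writePoseTrack(tr, f)
    back <- readPoseTrack(f)
    expect_equal(xCoords(back), xCoords(tr), tolerance = 1e-9)
    expect_equal(likelihoods(back), likelihoods(tr), tolerance = 1e-9)
  }
})

test_that("an empty track writes a header-only, re-readable file", {
  z <- matrix(numeric(), 0, 7, dimnames = list(NULL, partNames))
  tr <- KeypointTrack(z, z, z)
  f <- withr::local_tempfile(fileext = ".csv")
  writePoseTrack(tr, f)
  expect_length(readLines(f), 3L)
  expect_equal(nFrames(readPoseTrack(f)), 0L)
})

test_that("malformed files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  # six-part file: missing the column point
  parts6 <- setdiff(partNames, "column")
  writeLines(c(
    paste(c("scorer", rep("net", 18)), collapse = ","),
    paste(c("bodyparts", rep(parts6, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), 6)), collapse = ","),
    paste(c(0, rep(1, 18)), collapse = ",")), f)
  expect_error(readPoseTrack(f), "missing body part.*column")

  # unknown body part
  writeLines(c(
    paste(c("scorer", rep("net", 3)), collapse = ","),
    paste(c("bodyparts", rep("whisker", 3)), collapse = ","),
    paste(c("coords", "x", "y", "likelihood"), collapse = ","),
    paste(c(0, 1, 1, 1), collapse = ",")), f)
  expect_error(readPoseTrack(f), "unknown body part")

  # missing header row
  writeLines(c("a,b", "1,2"), f)
  expect_error(readPoseTrack(f), "format error")

  # non-numeric cell, reported with its row
  tr <- makeStillTrack(3)
  writePoseTrack(tr, f)
  lines <- readLines(f)
  lines[5] <- sub("^1,[0-9.]+", "1,oops", lines[5])
  writeLines(lines, f)
  expect_error(readPoseTrack(f), "parse error.*row 2")
})

test_that("cleaning interpolates low-likelihood frames linearly", {
  tr <- makeStillTrack(3)
  x <- xCoords(tr); y <- yCoords(tr); l <- likelihoods(tr)
  x[, "forepaw_left"] <- c(0, 500, 2)
  y[, "forepaw_left"] <- c(0, 500, 2)
  l[2, "forepaw_left"] <- 0.2
  tr <- KeypointTrack(x, y, l)
  out <- cleanTrack(tr, parts = "forepaw_left")
  expect_equal(unname(xCoords(out)[, "forepaw_left"]), c(0, 1, 2))
  expect_equal(unname(yCoords(out)[, "forepaw_left"]), c(0, 1, 2))
  # likelihoods preserved
  expect_equal(likelihoods(out), l)
})

test_that("cleaning is the identity when nothing is below threshold, and idempotent", {
  tr <- randomTrack(40, seed = 3)
  l <- likelihoods(tr)
  l[] <- 0.99
  hi <- KeypointTrack(xCoords(tr), yCoords(tr), l)
  expect_equal(xCoords(cleanTrack(hi)), xCoords(hi))
  once <- cleanTrack(tr, likelihoodMin = 0.5)
  twice <- cleanTrack(once, likelihoodMin = 0.5)
  expect_equal(xCoords(twice), xCoords(once))
  expect_equal(yCoords(twice), yCoords(once))
})

test_that("long gaps are filled but flagged with their length", {
  tr <- makeStillTrack(8)
  x <- xCoords(tr); l <- likelihoods(tr)
  x[, "nose"] <- c(0, 9, 9, 9, 4, 5, 6, 7)
  l[2:4, "nose"] <- 0.1
  tr <- KeypointTrack(x, yCoords(tr), l)
  out <- cleanTrack(tr, parts = "nose", maxGap = 2L)
  expect_equal(unname(xCoords(out)[, "nose"]), c(0, 1, 2, 3, 4, 5, 6, 7))
  flags <- sessionMeta(out)$cleaning_flags
  expect_equal(flags$gap_frames, 3L)
  expect_equal(flags$part, "nose")
})

test_that("a part entirely below threshold is irrecoverable", {
  tr <- makeStillTrack(5)
  l <- likelihoods(tr)
  l[, "tail_base"] <- 0.3
  tr <- KeypointTrack(xCoords(tr), yCoords(tr), l)
  expect_error(cleanTrack(tr, parts = "tail_base"), "irrecoverable")
})

test_that("ethogram TSV output round trips", {
  etho <- Ethogram(rep(c("quiet_awake", "locomotion"), c(30, 20)),
                   fps = 60, injectionFrame = 10L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEthogram(etho, tsvPath = f)
  back <- readEthogram(f, fps = 60, injectionFrame = 10L)
  expect_equal(stateLabels(back), stateLabels(etho))
})
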
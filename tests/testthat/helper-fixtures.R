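# small deterministic fixtures built in code

partNames <- bodyPartNames()

# a track with every part at a fixed layout, all likelihoods high
makeStillTrack <- function(frames, fps = 60, lik = 0.99) {
  layout <- rbind(nose = c(420, 240),
                  forepaw_left = c(395, 225),
                  forepaw_right = c(395, 255),
                  hindpaw_left = c(335, 225),
                  hindpaw_right = c(335, 255),
                  column = c(360, 240),
                  tail_base = c(315, 240))
  x <- matrix(rep(layout[partNames, 1], each = frames), frames, 7,
              dimnames = list(NULL, partNames))
  y <- matrix(rep(layout[partNames, 2], each = frames), frames, 7,
              dimnames = list(NULL, partNames))
  l <- matrix(lik, frames, 7, dimnames = list(NULL, partNames))
  KeypointTrack(x, y, l, fps = fps)
}

# standard multi-behavior script used by several recovery tests
recoveryScript <- function(seed, baselineS = 900) {
  states <- data.frame(
    state = c("quiet_awake", "locomotion", "stereotypy", "quiet_awake",
              "grooming", "rearing", "stereotypy", "locomotion",
              "quiet_awake"),
    duration_s = c(30, 40, 60, 30, 20, 15, 60, 30, 25))
  syntheticScript(states, seed = seed, baselineS = baselineS)
}

randomTrack <- function(frames, seed) {
  set.seed(seed)
  ar <- defaultArena()
  x <- matrix(runif(frames * 7, 0, ar$width_px), frames, 7,
              dimnames = list(NULL, partNames))
  y <- matrix(runif(frames * 7, 0, ar$height_px), frames, 7,
              dimnames = list(NULL, partNames))
  l <- matrix(runif(frames * 7), frames, 7,
              dimnames = list(NULL, partNames))
  KeypointTrack(x, y, l)
}

expectEpisodesTile <- function(etho) {
  ep <- episodes(etho)
  expect_equal(ep$start[1], 0L)
  expect_equal(ep$end[nrow(ep)], nFrames(etho))
  if (nrow(ep) > 1) {
    expect_equal(ep$start[-1], ep$end[-nrow(ep)])
    expect_true(all(ep$state[-1] != ep$state[-nrow(ep)]))
  }
  reconstructed <- rep(ep$state, ep$end - ep$start)
  expect_equal(reconstructed, as.character(stateLabels(etho)))
}
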
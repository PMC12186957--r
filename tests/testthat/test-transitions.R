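test_that("run extraction is a run-length encoding that conserves length", {
  lab <- rep(c("quiet_awake", "locomotion", "quiet_awake"), c(30, 20, 10))
  etho <- Ethogram(lab)
  runs <- extractRuns(etho)
  expect_equal(runs$state, c("quiet_awake", "locomotion", "quiet_awake"))
  expect_equal(runs$length, c(30L, 20L, 10L))
  expect_equal(sum(runs$length), nFrames(etho))

  one <- extractRuns(Ethogram(rep("rearing", 50)))
  expect_equal(nrow(one), 1L)

  set.seed(5)
  lab2 <- sample(behaviorStates(), 4000, replace = TRUE)
  runs2 <- extractRuns(Ethogram(lab2))
  expect_equal(sum(runs2$length), 4000L)
  expect_true(all(runs2$state[-1] != runs2$state[-nrow(runs2)]))
})

test_that("transition counts tally adjacent run pairs", {
  tm <- transitionCounts(c("quiet_awake", "locomotion", "quiet_awake"))
  cm <- transitionCountsMatrix(tm)
  expect_equal(cm["quiet_awake", "locomotion"], 1)
  expect_equal(cm["locomotion", "quiet_awake"], 1)
  expect_equal(sum(cm), 2)

  expect_warning(z <- transitionCounts("rearing"), "fewer than 2")
  expect_equal(sum(transitionCountsMatrix(z)), 0)
})

test_that("counts equal a brute-force pairwise tally on random sequences", {
  set.seed(11)
  st <- behaviorStates()
  runs <- st[1 + (cumsum(sample(1:4, 200, replace = TRUE)) %% 5)]
  runs <- rle(runs)$values     # remove accidental repeats
  cm <- transitionCountsMatrix(transitionCounts(runs))
  brute <- matrix(0, 5, 5, dimnames = list(st, st))
  for (i in seq_len(length(runs) - 1))
    brute[runs[i], runs[i + 1]] <- brute[runs[i], runs[i + 1]] + 1
  expect_equal(unname(cm), unname(brute))
  expect_equal(sum(cm), length(runs) - 1)
  expect_true(all(diag(cm) == 0))
})

test_that("pooling sums counts before normalizing and is scale-invariant", {
  tm <- transitionCounts(c("quiet_awake", "locomotion"))
  p1 <- poolAndNormalize(tm)
  expect_equal(transitionProbs(p1)["quiet_awake", "locomotion"], 1)

  # pooling k copies leaves probabilities unchanged
  p3 <- poolAndNormalize(list(tm, tm, tm))
  expect_equal(transitionProbs(p3), transitionProbs(p1))
  expect_equal(sum(transitionCountsMatrix(p3)), 3)

  # all-zero rows stay zero and are flagged
  expect_true("rearing" %in% p1@zeroRows)
})

test_that("pooling is associative and order-invariant", {
  set.seed(21)
  st <- behaviorStates()
  mk <- function() {
    r <- rle(sample(st, 60, replace = TRUE))$values
    transitionCounts(r)
  }
  a <- mk(); b <- mk(); c_ <- mk()
  ab_c <- poolAndNormalize(list(poolAndNormalize(list(a, b)), c_))
  a_bc <- poolAndNormalize(list(a, poolAndNormalize(list(b, c_))))
  cba <- poolAndNormalize(list(c_, b, a))
  expect_equal(transitionProbs(ab_c), transitionProbs(a_bc))
  expect_equal(transitionProbs(ab_c), transitionProbs(cba))
})

test_that("row-normalized matrices are stochastic on supported rows", {
  for (seed in c(2, 8, 19)) {
    set.seed(seed)
    lab <- rep(sample(behaviorStates(), 50, replace = TRUE),
               sample(5:50, 50, replace = TRUE))
    tm <- poolAndNormalize(transitionCounts(extractRuns(Ethogram(lab))))
    probs <- transitionProbs(tm)
    rs <- rowSums(probs)
    supported <- rowSums(transitionCountsMatrix(tm)) > 0
    expect_equal(unname(rs[supported]),
                 rep(1, sum(supported)), tolerance = 1e-9)
    expect_equal(unname(rs[!supported]),
                 rep(0, sum(!supported)))
  }
})

test_that("a known two-state kernel is recovered exactly", {
  st <- behaviorStates()
  lab <- rep(rep(c("quiet_awake", "locomotion"), 50), each = 1) # QLQL...
  sessions <- replicate(10, Ethogram(rep(lab, each = 30)),
                        simplify = FALSE)
  pooled <- poolAndNormalize(lapply(sessions, function(e)
    transitionCounts(extractRuns(e))))
  probs <- transitionProbs(pooled)
  expect_equal(probs["quiet_awake", "locomotion"], 1)
  expect_equal(probs["locomotion", "quiet_awake"], 1)
})

test_that("a known five-state kernel is recovered within 0.05", {
  st <- behaviorStates()
  K <- matrix(c(0, .4, .3, .2, .1,
                .5, 0, .2, .2, .1,
                .3, .3, 0, .2, .2,
                .25, .25, .25, 0, .25,
                .1, .2, .3, .4, 0),
              5, 5, byrow = TRUE, dimnames = list(st, st))
  sessions <- simulateKernelSessions(K, nSessions = 20,
                                     runsPerSession = 500, seed = 3)
  pooled <- poolAndNormalize(lapply(sessions, function(e)
    transitionCounts(extractRuns(e))))
  expect_lt(max(abs(transitionProbs(pooled) - K)), 0.05)
})

test_that("network export writes a parseable GraphML round trip", {
  st <- behaviorStates()
  set.seed(1)
  lab <- rep(sample(st, 80, replace = TRUE),
             sample(20:100, 80, replace = TRUE))
  etho <- Ethogram(lab)
  tm <- poolAndNormalize(transitionCounts(extractRuns(etho)))
  occ <- occupancy(etho, postInjectionOnly = FALSE)
  d <- withr::local_tempdir()
  out <- exportNetwork(tm, occ, file.path(d, "net"),
                       displayThreshold = 0.01)
  expect_true(file.exists(out$graphml))
  expect_true(file.exists(out$edges))

  g <- igraph::read_graph(out$graphml, format = "graphml")
  expect_equal(sum(igraph::V(g)$size), 1, tolerance = 1e-9)
  probs <- transitionProbs(tm)
  for (e in seq_len(igraph::ecount(g))) {
    ends <- igraph::ends(g, e)
    expect_equal(igraph::E(g)$weight[e], probs[ends[1], ends[2]],
                 tolerance = 1e-9)
  }
  # edges below the display threshold are absent from the file only
  el <- igraph::as_data_frame(g)
  expect_true(all(el$weight >= 0.01))
})

test_that("a two-state deterministic chain exports two unit edges", {
  tm <- poolAndNormalize(transitionCounts(
    rep(c("quiet_awake", "locomotion"), 10)))
  occ <- c(stereotypy = 0, quiet_awake = 0.5, locomotion = 0.5,
           grooming = 0, rearing = 0)
  d <- withr::local_tempdir()
  out <- exportNetwork(tm, occ, file.path(d, "chain"))
  expect_equal(igraph::ecount(out$graph), 2)
  expect_equal(sort(igraph::E(out$graph)$weight), c(1, 1))
})
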
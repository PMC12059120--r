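test_that("single-trial responses are baseline-corrected window means", {
  arr <- array(0, c(1, 1, 120))
  expect_equal(unname(singleTrialResponses(makeDffTensor(arr))[1, 1]), 0)
  arr[1, 1, 61:90] <- 0.4  # response window only
  expect_equal(unname(singleTrialResponses(makeDffTensor(arr))[1, 1]), 0.4)
  ## a planted transient integrates to the quadrature oracle value
  k <- calciumKernel(0.05, 1.0)
  arr2 <- array(0, c(1, 1, 150))
  arr2[1, 1, 61:150] <- 0.5 * k((0:89) / 30)
  got <- unname(singleTrialResponses(makeDffTensor(arr2))[1, 1])
  expect_equal(got, kernelWindowMeanOracle(0.5), tolerance = 0.015)
  expect_error(singleTrialResponses(makeDffTensor(arr), anchorFrames = 5L),
               class = "validationError")
})

test_that("the shuffle null is centered, reproducible and degenerate-safe", {
  set.seed(21)
  sigma <- 0.1
  arr <- array(rnorm(2 * 20 * 240, sd = sigma), c(2, 20, 240))
  dff <- makeDffTensor(arr)
  null <- buildNull(dff, nDraws = 1000, seed = 5L)
  se <- sigma * sqrt(2 / 30) / sqrt(1000)
  expect_lt(abs(mean(nullValues(null)[1, ])), 3 * se)
  ## reproducible given the seed
  null2 <- buildNull(dff, nDraws = 1000, seed = 5L)
  expect_identical(nullValues(null), nullValues(null2))
  ## constant session -> every draw exactly zero
  nullC <- buildNull(makeDffTensor(array(0.7, c(1, 5, 240))), nDraws = 100,
                     seed = 1L)
  expect_lt(max(abs(nullValues(nullC))), 1e-10)
  ## too-short session
  expect_error(buildNull(makeDffTensor(array(0, c(1, 2, 40)), t0 = 20L)),
               class = "validationError")
})

test_that("planted responders are classified responsive, noise is not", {
  set.seed(22)
  arr <- array(rnorm(2 * 20 * 240, sd = 0.05), c(2, 20, 240))
  k <- calciumKernel(0.05, 1.0)
  for (j in 1:20)  # neuron 1 responds on every trial at frame 121
    arr[1, j, 121:240] <- arr[1, j, 121:240] + 0.5 * k((0:119) / 30)
  dff <- makeDffTensor(arr)
  null <- buildNull(dff, nDraws = 500, seed = 2L)
  rec <- classifySession(dff, null, trialIdx = 1:20, anchorFrames = 121L)
  expect_true(rec$responsive[1])
  expect_true(rec$selected[1])
  expect_gt(rec$odd_mean[1], 0)
  expect_false(rec$responsive[2])

  ## fewer than five trials: flagged, not an exception
  rec3 <- classifySession(dff, null, trialIdx = 1:3, anchorFrames = 121L)
  expect_true(all(rec3$insufficient))
  expect_true(all(is.na(rec3$p_value)))
  expect_false(any(rec3$responsive))
})

test_that("classification false-positive rate on noise is near alpha", {
  cfg <- simConfig(nNeurons = 300L, sessionSizes = c(whisker = 30L),
                   categoryFractions = c(whisker = 0),
                   nOverlapMatchedMismatch = 0L, seed = 23L)
  sim <- simulateExperiment(cfg)
  rec <- classifyRecording(sim$recording, sim$trials, nDraws = 500, seed = 23L)
  frac <- mean(rec$responsive)
  band <- 2.576 * sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(frac - 0.05), band + 0.01)
})

test_that("cross-validated selection reports even trials and filters on odd", {
  set.seed(24)
  arr <- array(rnorm(3 * 20 * 240, sd = 0.05), c(3, 20, 240))
  k <- calciumKernel(0.05, 1.0)
  for (j in 1:20)
    arr[1, j, 121:240] <- arr[1, j, 121:240] + 0.5 * k((0:119) / 30)
  for (j in 1:20)  # neuron 3: strong *negative* modulation
    arr[3, j, 121:240] <- arr[3, j, 121:240] - 0.5 * k((0:119) / 30)
  dff <- makeDffTensor(arr)
  null <- buildNull(dff, nDraws = 500, seed = 3L)
  rec <- classifySession(dff, null, trialIdx = 1:20, anchorFrames = 121L)
  sel <- crossvalSelect(rec)
  expect_identical(sel$neuron_id, "n1")
  expect_equal(sel$even_report, sel$even_mean)
  ## the negatively modulated neuron is significant but never selected
  expect_true(rec$responsive[3])
  expect_false(rec$selected[3])
})

test_that("category labels follow the sessions a neuron is selected in", {
  cfg <- tinyConfig(categoryFractions = c(whisker = 0.2, matched = 0.2,
                                          mismatch = 0.1),
                    nOverlapMatchedMismatch = 1L)
  sim <- simulateExperiment(cfg)
  rec <- classifyRecording(sim$recording, sim$trials, nDraws = 400, seed = 4L)
  cats <- categorize(rec)
  tc <- truthCategories(sim$truth)
  whiskerTrue <- names(tc)[vapply(tc, function(s) identical(s, "whisker"),
                                  logical(1))]
  for (id in whiskerTrue)
    expect_true("whisker" %in% cats[[id]], label = id)
  ## the planted overlap neuron carries both labels (high SNR fixture)
  both <- names(tc)[vapply(tc, function(s)
    all(c("matched", "mismatch") %in% s), logical(1))]
  expect_identical(length(both), 1L)
  expect_true(all(c("matched", "mismatch") %in% cats[[both]]))
  ## unlabelled neurons get an empty set
  noneIds <- names(tc)[lengths(tc) == 0]
  expect_true(any(lengths(cats[noneIds]) == 0))
})

test_that("detection rate is monotone in amplitude and trial count", {
  rate <- function(ampMean, ntr, seed) {
    cfg <- simConfig(nNeurons = 60L, sessionSizes = c(whisker = ntr),
                     categoryFractions = c(whisker = 1),
                     nOverlapMatchedMismatch = 0L, reliability = 1,
                     amplitudeMeanlog = log(ampMean), amplitudeSdlog = 0.1,
                     seed = seed)
    sim <- simulateExperiment(cfg)
    rec <- classifyRecording(sim$recording, sim$trials, nDraws = 300,
                             seed = seed)
    mean(rec$selected)
  }
  byAmp <- vapply(c(0.01, 0.05, 0.4), rate, numeric(1), ntr = 24L, seed = 31L)
  expect_true(all(diff(byAmp) >= 0))
  byTrials <- vapply(c(6L, 14L, 40L), function(ntr)
    rate(0.04, ntr, seed = 32L), numeric(1))
  expect_true(all(diff(byTrials) >= 0))
})

test_that("identical seeds give identical classification records", {
  cfg <- tinyConfig()
  sim <- simulateExperiment(cfg)
  r1 <- classifyRecording(sim$recording, sim$trials, nDraws = 200, seed = 7L)
  r2 <- classifyRecording(sim$recording, sim$trials, nDraws = 200, seed = 7L)
  expect_identical(r1, r2)
})
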
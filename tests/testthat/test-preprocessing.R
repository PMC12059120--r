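test_that("alignment geometry follows the frame-rounding rule", {
  cfg <- tinyConfig()
  sim <- simulateExperiment(cfg)
  d <- sessionTrials(sim$trials, "whisker")
  al <- alignTrials(sim$recording, d, anchor = "stim_onset", pre = 2, post = 2)
  expect_identical(nFrames(al), 120L)  # 4 s at 30 Hz
  expect_identical(anchorFrame(al), 61L)  # 60 frames before the anchor
  expect_identical(nTrials(al), nrow(d))
  ## snippet content equals a manual slice of the recording
  a0 <- round(d$stim_onset_s[1] * 30)
  expect_equal(tensorValues(al)[, 1, ],
               fluorescence(sim$recording)[, (a0 - 59):(a0 + 60)],
               ignore_attr = TRUE)
})

test_that("out-of-bounds alignment names the offending trial", {
  rec <- CalciumRecording(matrix(100, 2, 200), frameRate = 30)
  d <- smallTrialFrame()[2, ]
  d$cue_onset_s <- 0.3; d$stim_onset_s <- 0.5; d$trial_id <- 99L
  err <- tryCatch(alignTrials(rec, d, "stim_onset", pre = 2, post = 2),
                  error = identity)
  expect_s3_class(err, "validationError")
  expect_match(conditionMessage(err), "99")
})

test_that("omission trials align at the scheduled onset like matched trials", {
  cfg <- tinyConfig(categoryFractions = c(matched = 0.5), noiseSd = 0)
  sim <- simulateExperiment(cfg)
  d <- sessionTrials(sim$trials, "interleaved")
  al <- alignTrials(sim$recording, d, anchor = "stim_onset", pre = 2, post = 2)
  om <- which(d$trial_type == "mismatch_omission")
  expect_gt(length(om), 0)
  a0 <- round(d$stim_onset_s[om[1]] * 30)
  expect_equal(tensorValues(al)[, om[1], ],
               fluorescence(sim$recording)[, (a0 - 59):(a0 + 60)],
               ignore_attr = TRUE)
})

test_that("dF/F uses each trial's own pre-cue baseline", {
  ## constant F -> dF/F identically zero; a 10% excursion -> 0.1
  rec <- CalciumRecording(matrix(100, 1, 400), frameRate = 30)
  d <- smallTrialFrame()[2, ]; d$cue_onset_s <- 5; d$stim_onset_s <- 7
  al <- alignTrials(rec, d, "stim_onset", pre = 4, post = 2)
  dff <- computeDff(al, d)
  expect_true(all(tensorValues(dff) == 0))

  F <- matrix(100, 1, 400); F[1, 211] <- 110  # one frame at stim onset
  rec <- CalciumRecording(F, frameRate = 30)
  dff <- computeDff(alignTrials(rec, d, "stim_onset", pre = 4, post = 2), d)
  expect_equal(tensorValues(dff)[1, 1, 121], 0.1)
})

test_that("dF/F is exactly invariant to per-neuron rescaling of F", {
  cfg <- tinyConfig(nNeurons = 5L)
  sim <- simulateExperiment(cfg)
  d <- sessionTrials(sim$trials, "whisker")
  al <- alignTrials(sim$recording, d, "cue_onset", pre = 2, post = 4)
  dff1 <- computeDff(al, d)
  scaled <- CalciumRecording(fluorescence(sim$recording) * 3.7,
                             frameRate = 30,
                             neuronIds = neuronIds(sim$recording))
  al2 <- alignTrials(scaled, d, "cue_onset", pre = 2, post = 4)
  dff2 <- computeDff(al2, d)
  expect_equal(tensorValues(dff2), tensorValues(dff1), tolerance = 1e-12)
})

test_that("degenerate baselines raise a named error", {
  F <- matrix(100, 2, 400); F[2, 120:150] <- 0  # kills n2's pre-cue window
  rec <- CalciumRecording(F, frameRate = 30)
  d <- smallTrialFrame()[2, ]; d$cue_onset_s <- 5; d$stim_onset_s <- 7
  al <- alignTrials(rec, d, "stim_onset", pre = 4, post = 2)
  err <- tryCatch(computeDff(al, d), error = identity)
  expect_s3_class(err, "validationError")
  expect_match(conditionMessage(err), "n2")
})

test_that("alignment and dF/F commute with trial reordering", {
  cfg <- tinyConfig(nNeurons = 4L)
  sim <- simulateExperiment(cfg)
  d <- sessionTrials(sim$trials, "whisker")
  dff1 <- computeDff(alignTrials(sim$recording, d, "cue_onset", 2, 4), d)
  perm <- c(3, 1, 2, 4:nrow(d))
  ## reordered trials violate table monotonicity, so align the raw frame
  dp <- d[perm, ]
  dff2 <- computeDff(alignTrials(sim$recording, dp, "cue_onset", 2, 4), dp)
  expect_equal(tensorValues(dff2), tensorValues(dff1)[, perm, ],
               tolerance = 1e-12)
})

test_that("order-1 Savitzky-Golay reproduces constants and lines exactly", {
  x <- seq(0, 5, length.out = 100)
  expect_equal(sgSmooth(3 + 2 * x), 3 + 2 * x, tolerance = 1e-10)
  expect_equal(sgSmooth(rep(1.5, 50)), rep(1.5, 50), tolerance = 1e-12)
})

test_that("SG smoothing matches the reference filter and the impulse law", {
  ## interior of an order-1 SG on a 5-frame window is a moving average:
  ## a centered unit impulse smooths to 1/5
  x <- numeric(21); x[11] <- 1
  expect_equal(sgSmooth(x)[11], 0.2)
  ## cross-check the whole series against signal::sgolayfilt
  set.seed(2)
  y <- rnorm(80)
  expect_equal(sgSmooth(y), as.numeric(signal::sgolayfilt(y, p = 1, n = 5)),
               tolerance = 1e-10)
  expect_error(sgSmooth(rnorm(3)), class = "validationError")
})
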
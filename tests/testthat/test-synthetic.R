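test_that("default schedule reproduces the session structure", {
  cfg <- simConfig(nNeurons = 2L)
  sched <- makeTrialSchedule(cfg)
  d <- trialData(sched)
  expect_identical(nrow(d), 270L)  # 25+25+50+20+120+30
  expect_identical(as.integer(table(factor(d$session, SESSION_LEVELS))),
                   c(50L, 50L, 20L, 150L))
  expect_identical(sum(d$trial_type == "matched"), 120L)
  expect_identical(sum(d$trial_type == "mismatch_omission"), 30L)
  ## per-trial event geometry: cue 2 s after trial start, sound 1 s after
  ## cue, 1 s long, stimulus at sound offset
  has <- !is.na(d$sound_onset_s)
  expect_equal(d$sound_onset_s[has] - d$cue_onset_s[has], rep(1, sum(has)))
  expect_equal(d$sound_offset_s[has] - d$sound_onset_s[has], rep(1, sum(has)))
  both <- has & !is.na(d$stim_onset_s)
  expect_equal(d$stim_onset_s[both], d$sound_offset_s[both])
  ## omissions keep the scheduled onset with intensity zero
  om <- d$trial_type == "mismatch_omission"
  expect_true(all(!is.na(d$stim_onset_s[om])))
  expect_true(all(d$intensity_pct[om] == 0))
})

test_that("a configured sound-to-stimulus delay shifts every scheduled onset", {
  cfg <- simConfig(nNeurons = 2L, delay = 1.0)
  d <- trialData(makeTrialSchedule(cfg))
  both <- !is.na(d$sound_offset_s) & !is.na(d$stim_onset_s)
  expect_equal(d$stim_onset_s[both] - d$sound_offset_s[both],
               rep(1.0, sum(both)))
})

test_that("schedule, truth and traces are deterministic given the seed", {
  cfg <- tinyConfig()
  a <- simulateExperiment(cfg, seed = 9L)
  b <- simulateExperiment(cfg, seed = 9L)
  expect_identical(trialData(a$trials), trialData(b$trials))
  expect_identical(a$truth, b$truth)
  expect_identical(fluorescence(a$recording), fluorescence(b$recording))
  c <- simulateExperiment(cfg, seed = 10L)
  expect_false(identical(fluorescence(a$recording), fluorescence(c$recording)))
})

test_that("category counts follow largest-remainder rounding", {
  cfg <- simConfig(nNeurons = 100L, categoryFractions = c(whisker = 0.2),
                   nOverlapMatchedMismatch = 0L)
  truth <- assignGroundTruth(cfg)
  expect_identical(sum(truth$categories == "whisker"), 20L)

  cfg <- simConfig(nNeurons = 834L, categoryFractions = c(whisker = 0.394),
                   nOverlapMatchedMismatch = 0L)
  truth <- assignGroundTruth(cfg)
  expect_identical(sum(truth$categories == "whisker"), 329L)

  cfg <- simConfig(nNeurons = 50L, categoryFractions = c(whisker = 0),
                   nOverlapMatchedMismatch = 0L)
  truth <- assignGroundTruth(cfg)
  expect_true(all(truth$categories == "none"))
  expect_true(all(truth$true_amplitude == 0))

  expect_error(simConfig(categoryFractions = c(whisker = 0.7, matched = 0.4)))
  expect_error(simConfig(sessionSizes = c(matched = 0L, mismatch = 10L)))
})

test_that("all-none truth with zero noise and drift gives a constant trace", {
  cfg <- tinyConfig(categoryFractions = c(whisker = 0), noiseSd = 0)
  sim <- simulateExperiment(cfg)
  expect_true(all(fluorescence(sim$recording) == cfg@baselineF))
  ## and dF/F computed downstream is identically zero
  st <- sessionTensor(sim$recording, sim$trials, "whisker")
  expect_true(all(tensorValues(st$dff) == 0))
})

test_that("a fully reliable whisker responder peaks at its planted amplitude", {
  cfg <- tinyConfig(nNeurons = 4L, categoryFractions = c(whisker = 0.25),
                    noiseSd = 0, reliability = 1,
                    amplitudeMeanlog = log(0.5), amplitudeSdlog = 0)
  sim <- simulateExperiment(cfg)
  st <- sessionTensor(sim$recording, sim$trials, "whisker")
  af <- eventFrame(st$dff, st$trials, "stim_onset")[1]
  snips <- tensorValues(st$dff)[1, , af:(af + 30)]
  peaks <- apply(snips, 1, max)
  ## every whisker trial carries the transient; peak within kernel
  ## discretization of 0.5
  expect_true(all(abs(peaks - 0.5) < 0.02))
  ## non-responders stay flat
  expect_true(all(abs(tensorValues(st$dff)[4, , ]) < 1e-9))
})

test_that("per-trial hit rate matches the configured reliability", {
  cfg <- simConfig(nNeurons = 200L, sessionSizes = c(whisker = 50L),
                   categoryFractions = c(whisker = 1),
                   nOverlapMatchedMismatch = 0L,
                   reliability = 0.35, noiseSd = 0, driftAmplitude = 0,
                   amplitudeMeanlog = log(0.5), amplitudeSdlog = 0.1,
                   seed = 6L)
  sim <- simulateExperiment(cfg)
  st <- sessionTensor(sim$recording, sim$trials, "whisker")
  af <- eventFrame(st$dff, st$trials, "stim_onset")[1]
  post <- tensorValues(st$dff)[, , af:(af + 15)]
  hits <- apply(post, c(1, 2), max) > 0.05
  frac <- mean(hits)
  se <- sqrt(0.35 * 0.65 / (50 * 200))
  expect_lt(abs(frac - 0.35), 3 * se)
})

test_that("planted peak amplitudes follow the configured lognormal law", {
  cfg <- simConfig(nNeurons = 300L, sessionSizes = c(whisker = 3L),
                   categoryFractions = c(whisker = 1),
                   nOverlapMatchedMismatch = 0L, reliability = 1,
                   noiseSd = 0, driftAmplitude = 0, seed = 8L)
  sim <- simulateExperiment(cfg)
  st <- sessionTensor(sim$recording, sim$trials, "whisker")
  af <- eventFrame(st$dff, st$trials, "stim_onset")[1]
  peaks <- apply(tensorValues(st$dff)[, 1, af:(af + 30)], 1, max)
  k <- calciumKernel(cfg@kernelRise, cfg@kernelDecay)
  kMax <- max(k((0:60) / 30))  # discretized kernel peak
  ks <- suppressWarnings(stats::ks.test(peaks / kMax, stats::plnorm,
                                        cfg@amplitudeMeanlog,
                                        cfg@amplitudeSdlog))
  expect_gt(ks$p.value, 0.01)
})

test_that("inconsistent ground truth is a consistency error", {
  cfg <- tinyConfig()
  truth <- assignGroundTruth(cfg)
  sched <- makeTrialSchedule(cfg)
  expect_error(synthesizeTraces(sched, truth[1:5, ], cfg),
               class = "consistencyError")
})
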
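test_that("response probability saturates at extreme SNR and stays in [0, 1]", {
  cfg <- simConfig(nNeurons = 5L, sessionSizes = c(whisker = 20L),
                   categoryFractions = c(whisker = 0.6),
                   nOverlapMatchedMismatch = 0L, reliability = 1,
                   noiseSd = 0.01, driftAmplitude = 0,
                   amplitudeMeanlog = log(0.5), amplitudeSdlog = 0.1,
                   seed = 41L)
  sim <- simulateExperiment(cfg)
  st <- sessionTensor(sim$recording, sim$trials, "whisker")
  af <- eventFrame(st$dff, st$trials, "stim_onset")
  rp <- responseProbability(st$dff, anchorFrames = af)
  tc <- truthCategories(sim$truth)
  responders <- names(tc)[lengths(tc) > 0]
  expect_true(all(rp$probability[rp$neuron_id %in% responders] == 1.0))
  expect_true(all(rp$probability >= 0 & rp$probability <= 1))
  expect_equal(rp$probability, rp$n_responsive_trials / rp$n_trials)
  ## not enough frames on either side of the stimulus
  expect_error(responseProbability(st$dff, anchorFrames = 10L),
               class = "validationError")
})

test_that("response probability recovers planted reliability in the noise-free regime", {
  cfg <- simConfig(nNeurons = 8L, sessionSizes = c(whisker = 100L),
                   categoryFractions = c(whisker = 1),
                   nOverlapMatchedMismatch = 0L, reliability = 0.35,
                   noiseSd = 0, driftAmplitude = 0,
                   amplitudeMeanlog = log(0.5), amplitudeSdlog = 0.2,
                   seed = 42L)
  sim <- simulateExperiment(cfg)
  st <- sessionTensor(sim$recording, sim$trials, "whisker")
  af <- eventFrame(st$dff, st$trials, "stim_onset")
  rp <- responseProbability(st$dff, anchorFrames = af)
  est <- sum(rp$n_responsive_trials) / sum(rp$n_trials)
  n <- sum(rp$n_trials)
  expect_lt(abs(est - 0.35), 3 * sqrt(0.35 * 0.65 / n))
})

test_that("population averages are baseline-anchored with across-neuron SEM", {
  arr <- array(0, c(4, 6, 120))
  for (i in 1:4) arr[i, , 61:90] <- 0.2  # identical responses
  dff <- makeDffTensor(arr)
  pa <- populationAverage(dff, 1:4, 1:6, baselineFrames = 31:60)
  expect_true(all(pa$sem_trace == 0))
  expect_equal(mean(pa$mean_trace[31:60]), 0, tolerance = 1e-12)
  expect_identical(pa$n_neurons, 4L)
  ## heterogeneous cohort: baseline mean still exactly zero
  set.seed(43)
  arr2 <- array(rnorm(5 * 6 * 120, sd = 0.1), c(5, 6, 120))
  pa2 <- populationAverage(makeDffTensor(arr2), 1:5, 1:6, 31:60)
  expect_equal(mean(pa2$mean_trace[31:60]), 0, tolerance = 1e-12)
  expect_true(all(pa2$sem_trace >= 0))
  ## empty neuron set flags, not errors
  expect_true(populationAverage(dff, integer(0), 1:6, 31:60)$empty)
})

test_that("mean stimulus response is raise-invariant and matches the kernel oracle", {
  k <- calciumKernel(0.05, 1.0)
  trace <- c(numeric(60), 0.5 * k((0:89) / 30))
  m <- rbind(trace, trace - 0.3)  # second neuron dips below zero
  v <- meanStimulusResponse(m, anchorFrame = 61L, frameRate = 30)
  expect_equal(v[1], kernelWindowMeanOracle(0.5), tolerance = 0.015,
               ignore_attr = TRUE)
  ## adding a constant never changes the baseline-corrected response
  expect_equal(unname(v[2]), unname(v[1]), tolerance = 1e-12)
  ## exclusion mode drops traces with negative minima instead
  v2 <- meanStimulusResponse(m, 61L, 30, mode = "exclude")
  expect_false(is.na(v2[1]))
  expect_true(is.na(v2[2]))
})

test_that("pre-stimulus window detects a planted expectation ramp", {
  cfg <- simConfig(nNeurons = 20L,
                   sessionSizes = c(pairing = 10L, matched = 30L, mismatch = 6L),
                   categoryFractions = c(ramp = 1),
                   nOverlapMatchedMismatch = 0L, noiseSd = 0.02,
                   driftAmplitude = 0, seed = 44L)
  sim <- simulateExperiment(cfg)
  vals <- list()
  for (sess in c("pairing", "interleaved")) {
    st <- sessionTensor(sim$recording, sim$trials, sess)
    ty <- if (sess == "pairing") "paired" else "matched"
    rows <- which(st$trials$trial_type == ty)
    af <- eventFrame(st$dff, st$trials, "stim_onset")[rows][1]
    s0 <- eventFrame(st$dff, st$trials, "sound_onset")[rows][1]
    s1 <- eventFrame(st$dff, st$trials, "sound_offset")[rows][1]
    vals[[sess]] <- prestimulusResponse(st$dff, NULL, rows, af, s0:(s1 - 1))
  }
  ## ramp present only in interleaved matched trials
  expect_gt(mean(vals$interleaved - vals$pairing), 0.03)
  expect_lt(compareGroups(vals$interleaved, vals$pairing, paired = TRUE)$p_value,
            0.05)
  ## no planted ramp: paired difference centered on zero
  cfg0 <- simConfig(nNeurons = 20L,
                    sessionSizes = c(pairing = 10L, matched = 30L, mismatch = 6L),
                    categoryFractions = c(whisker = 0),
                    nOverlapMatchedMismatch = 0L, noiseSd = 0.02,
                    driftAmplitude = 0, seed = 45L)
  sim0 <- simulateExperiment(cfg0)
  v0 <- list()
  for (sess in c("pairing", "interleaved")) {
    st <- sessionTensor(sim0$recording, sim0$trials, sess)
    ty <- if (sess == "pairing") "paired" else "matched"
    rows <- which(st$trials$trial_type == ty)
    af <- eventFrame(st$dff, st$trials, "stim_onset")[rows][1]
    s0 <- eventFrame(st$dff, st$trials, "sound_onset")[rows][1]
    s1 <- eventFrame(st$dff, st$trials, "sound_offset")[rows][1]
    v0[[sess]] <- prestimulusResponse(st$dff, NULL, rows, af, s0:(s1 - 1))
  }
  dd <- v0$interleaved - v0$pairing
  expect_lt(abs(mean(dd)), 3 * stats::sd(dd) / sqrt(length(dd)))
})

test_that("overlap counts are plain set arithmetic", {
  asg <- list(a = c("x", "y"), b = c("y", "z"), c = character(0))
  ov <- overlapCounts(asg)
  expect_equal(ov$sizes, c(x = 1, y = 2, z = 1))
  expect_identical(ov$pairs[["x&y"]], 1L)
  expect_identical(ov$pairs[["x&z"]], 0L)
  expect_identical(ov$triples[["x&y&z"]], 0L)
  ## disjoint sets have empty intersections
  ov2 <- overlapCounts(list(a = "x", b = "y"))
  expect_identical(ov2$pairs[["x&y"]], 0L)
})

test_that("category recovery maps planted categories onto detected labels", {
  truth <- data.frame(neuron_id = c("n1", "n2", "n3", "n4"),
                      categories = c("whisker", "sound", "matched,ramp", "none"),
                      true_amplitude = c(0.3, 0.3, 0.3, 0),
                      true_reliability = c(0.5, 0.5, 0.5, 0),
                      stringsAsFactors = FALSE)
  asg <- list(n1 = "whisker", n2 = "looming", n3 = "matched", n4 = character(0))
  recv <- categoryRecovery(asg, truth)
  expect_true(all(recv$jaccard == 1))
  ## a miss and a false positive both lower the index
  asg2 <- list(n1 = character(0), n2 = "looming", n3 = "matched", n4 = "whisker")
  recv2 <- categoryRecovery(asg2, truth)
  expect_equal(recv2$jaccard[recv2$category == "whisker"], 0)
})
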
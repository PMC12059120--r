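## Synthetic-data generator: trial schedule, planted ground truth, and a
## forward model producing raw fluorescence with GECI-like transients,
## multiplicative slow drift and additive white noise.

#' Construct a SimConfig
#'
#' All arguments default to the study conditions of the auditory-tactile
#' sequence protocol (see \linkS4class{SimConfig}).
#'
#' @param nNeurons number of neurons.
#' @param frameRate sampling rate, Hz.
#' @param sessionSizes named integer vector: trials per condition.
#' @param mismatchMode "omission", "decreased" or "increased".
#' @param delay seconds between sound offset and (scheduled) whisker onset.
#' @param itiRange inter-trial interval range, seconds.
#' @param trialLenRange trial length range, seconds.
#' @param kernelRise,kernelDecay transient rise/decay time constants, seconds.
#' @param categoryFractions named fractions of planted responders per
#'   category; remainder are non-responders.
#' @param nOverlapMatchedMismatch mismatch neurons that also respond on
#'   matched trials.
#' @param amplitudeMeanlog,amplitudeSdlog lognormal peak dF/F amplitude.
#' @param categoryAmpScale named per-category amplitude multipliers.
#' @param reliability per-trial response probability.
#' @param noiseSd white-noise sd as a fraction of baseline F.
#' @param driftAmplitude slow drift amplitude, fraction of baseline F.
#' @param driftPeriod drift period, seconds.
#' @param baselineF baseline fluorescence, arbitrary units.
#' @param prestimRampAmp peak dF/F of the expectation ramp on matched trials.
#' @param seed generator seed.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nNeurons = 834L,
                      frameRate = 30,
                      sessionSizes = c(sound_looming = 25L, sound_nonlooming = 25L,
                                       whisker = 50L, pairing = 20L,
                                       matched = 120L, mismatch = 30L),
                      mismatchMode = "omission",
                      delay = 0,
                      itiRange = c(2, 5),
                      trialLenRange = c(8, 9),
                      kernelRise = 0.05,
                      kernelDecay = 1.0,
                      categoryFractions = c(whisker = 0.24, pairing = 0.12,
                                            matched = 0.14, mismatch = 0.10,
                                            sound = 0.10, sound_offset = 0.10,
                                            ramp = 0.08),
                      nOverlapMatchedMismatch = 7L,
                      amplitudeMeanlog = log(0.3),
                      amplitudeSdlog = 0.5,
                      categoryAmpScale = c(mismatch = 1.5),
                      reliability = 0.35,
                      noiseSd = 0.05,
                      driftAmplitude = 0.02,
                      driftPeriod = 300,
                      baselineF = 100,
                      prestimRampAmp = 0.2,
                      seed = 1L) {
  full <- c(sound_looming = 0L, sound_nonlooming = 0L, whisker = 0L,
            pairing = 0L, matched = 0L, mismatch = 0L)
  full[names(sessionSizes)] <- as.integer(sessionSizes)
  methods::new("SimConfig", nNeurons = as.integer(nNeurons),
               frameRate = frameRate, sessionSizes = full,
               mismatchMode = mismatchMode, delay = delay,
               itiRange = itiRange, trialLenRange = trialLenRange,
               kernelRise = kernelRise, kernelDecay = kernelDecay,
               categoryFractions = categoryFractions,
               nOverlapMatchedMismatch = as.integer(nOverlapMatchedMismatch),
               amplitudeMeanlog = amplitudeMeanlog,
               amplitudeSdlog = amplitudeSdlog,
               categoryAmpScale = categoryAmpScale,
               reliability = reliability, noiseSd = noiseSd,
               driftAmplitude = driftAmplitude, driftPeriod = driftPeriod,
               baselineF = baselineF, prestimRampAmp = prestimRampAmp,
               seed = as.integer(seed))
}

#' GECI-like calcium transient kernel
#'
#' Difference of exponentials \eqn{k(t) = A (e^{-t/\tau_d} - e^{-t/\tau_r})}
#' for \eqn{t \ge 0}, normalized to unit peak, so \eqn{k(0) = 0},
#' \eqn{\max_t k(t) = 1} and \eqn{k(t) \to 0}.
#'
#' @param tauRise rise time constant, seconds.
#' @param tauDecay decay time constant, seconds (> tauRise).
#' @return a function of time (seconds, vectorized; 0 for t < 0).
#' @export
calciumKernel <- function(tauRise = 0.05, tauDecay = 1.0) {
  stopifnot(tauDecay > tauRise, tauRise > 0)
  tPeak <- (tauRise * tauDecay / (tauDecay - tauRise)) * log(tauDecay / tauRise)
  peak <- exp(-tPeak / tauDecay) - exp(-tPeak / tauRise)
  function(t) {
    v <- (exp(-t / tauDecay) - exp(-t / tauRise)) / peak
    v[t < 0] <- 0
    v
  }
}

## stimulus intensity (percent of maximum) per trial type under a mismatch mode
.intensityFor <- function(type, mode) {
  base <- switch(mode, omission = 80, decreased = 60, increased = 60)
  switch(type,
         whisker_only = 80,
         paired = base,
         matched = base,
         mismatch_omission = 0,
         mismatch_decreased = 40,
         mismatch_increased = 80,
         NA_real_)
}

#' Generate the trial schedule of one synthetic imaging session
#'
#' Sessions follow the experimental order sound, whisker, pairing,
#' interleaved; looming/non-looming sound trials and matched/mismatch trials
#' are randomly permuted within their sessions. Every trial starts with a
#' 2 s baseline followed by the trial-start cue; the 1 s predictive sound
#' begins 1 s after the cue and the whisker stimulus follows the sound
#' offset after \code{delay} seconds. Omission trials keep their scheduled
#' stimulus onset with intensity 0. Inter-trial intervals and trial lengths
#' are drawn uniformly from their configured ranges.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed (defaults to the schedule substream of the config seed).
#' @return a \linkS4class{TrialTable}.
#' @export
makeTrialSchedule <- function(config, seed = stageSeed(config@seed, "schedule")) {
  stopifnot(methods::is(config, "SimConfig"))
  set.seed(seed)
  sz <- config@sessionSizes
  mm <- paste0("mismatch_", config@mismatchMode)
  types <- c(
    sample(rep(c("sound_looming", "sound_nonlooming"),
               c(sz[["sound_looming"]], sz[["sound_nonlooming"]]))),
    rep("whisker_only", sz[["whisker"]]),
    rep("paired", sz[["pairing"]]),
    sample(rep(c("matched", mm), c(sz[["matched"]], sz[["mismatch"]]))))
  n <- length(types)
  if (n == 0L) stopTyped("configError", "empty session sizes")
  sessions <- c(rep("sound", sz[["sound_looming"]] + sz[["sound_nonlooming"]]),
                rep("whisker", sz[["whisker"]]),
                rep("pairing", sz[["pairing"]]),
                rep("interleaved", sz[["matched"]] + sz[["mismatch"]]))
  lens <- stats::runif(n, config@trialLenRange[1], config@trialLenRange[2])
  itis <- stats::runif(n, config@itiRange[1], config@itiRange[2])
  start <- 1.0
  cue <- sound_on <- sound_off <- stim <- delay_s <- intensity <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cue[i] <- start + 2
    ty <- types[i]
    if (ty %in% c("sound_looming", "sound_nonlooming")) {
      sound_on[i] <- cue[i] + 1; sound_off[i] <- sound_on[i] + 1
    } else if (ty == "whisker_only") {
      stim[i] <- cue[i] + 2
      intensity[i] <- .intensityFor(ty, config@mismatchMode)
    } else {
      sound_on[i] <- cue[i] + 1; sound_off[i] <- sound_on[i] + 1
      stim[i] <- sound_off[i] + config@delay
      delay_s[i] <- config@delay
      intensity[i] <- .intensityFor(ty, config@mismatchMode)
    }
    start <- start + lens[i] + itis[i]
  }
  TrialTable(data.frame(
    trial_id = seq_len(n), session = sessions, trial_type = types,
    cue_onset_s = cue, sound_onset_s = sound_on, sound_offset_s = sound_off,
    stim_onset_s = stim, intensity_pct = intensity, delay_s = delay_s,
    stringsAsFactors = FALSE))
}

#' Partition neurons into planted response categories
#'
#' Category counts are the configured fractions of \code{nNeurons} with
#' largest-remainder rounding (remainder ties broken in the order the
#' fractions are given); neurons are assigned to categories in index order,
#' the rest are non-responders. The first
#' \code{nOverlapMatchedMismatch} mismatch neurons additionally carry the
#' matched category. Each responder draws one lognormal peak amplitude; the
#' per-trial response probability is the configured reliability.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed for the amplitude draws.
#' @return data.frame with columns \code{neuron_id}, \code{categories}
#'   (comma-separated; "none" for non-responders), \code{true_amplitude},
#'   \code{true_reliability}.
#' @export
assignGroundTruth <- function(config, seed = stageSeed(config@seed, "truth")) {
  stopifnot(methods::is(config, "SimConfig"))
  f <- config@categoryFractions
  if (sum(f) > 1 + 1e-12) stopTyped("configError", "categoryFractions sum > 1")
  n <- config@nNeurons
  quota <- f * n
  counts <- floor(quota)
  leftover <- round(sum(quota)) - sum(counts)
  if (leftover > 0) {
    ord <- order(-(quota - counts), seq_along(quota))
    counts[ord[seq_len(leftover)]] <- counts[ord[seq_len(leftover)]] + 1
  }
  counts <- as.integer(counts)
  cats <- rep("none", n)
  at <- 1L
  for (i in seq_along(counts)) {
    if (counts[i] > 0L) {
      cats[at:(at + counts[i] - 1L)] <- names(f)[i]
      at <- at + counts[i]
    }
  }
  ## configured matched/mismatch overlap: first overlap neurons of the
  ## mismatch block respond in both matched and mismatch trials
  nov <- min(config@nOverlapMatchedMismatch, sum(cats == "mismatch"))
  if (nov > 0L) {
    idx <- which(cats == "mismatch")[seq_len(nov)]
    cats[idx] <- "mismatch,matched"
  }
  ## ramp neurons are matched responders carrying the expectation ramp on top
  cats[cats == "ramp"] <- "matched,ramp"
  set.seed(seed)
  amp <- stats::rlnorm(n, config@amplitudeMeanlog, config@amplitudeSdlog)
  responder <- cats != "none"
  data.frame(neuron_id = paste0("n", seq_len(n)),
             categories = cats,
             true_amplitude = ifelse(responder, amp, 0),
             true_reliability = ifelse(responder, config@reliability, 0),
             stringsAsFactors = FALSE)
}

## trials and anchor times on which a planted category responds
.categoryTrials <- function(category, d) {
  switch(category,
         whisker = list(rows = which(d$trial_type == "whisker_only"),
                        anchor = "stim_onset_s"),
         pairing = list(rows = which(d$trial_type == "paired"),
                        anchor = "stim_onset_s"),
         matched = list(rows = which(d$trial_type == "matched"),
                        anchor = "stim_onset_s"),
         mismatch = list(rows = grep("^mismatch_", d$trial_type),
                         anchor = "stim_onset_s"),
         sound = list(rows = which(d$trial_type == "sound_looming"),
                      anchor = "sound_onset_s"),
         sound_offset = list(rows = which(d$trial_type == "sound_looming"),
                             anchor = "sound_offset_s"),
         ramp = list(rows = which(d$trial_type == "matched"),
                     anchor = "stim_onset_s"),
         stopTyped("consistencyError", "unknown planted category: ", category))
}

#' Synthesize a raw fluorescence recording from a schedule and ground truth
#'
#' Forward model:
#' \code{F(t) = baselineF * (1 + drift(t)) * (1 + sum of responses) + noise}.
#' Each planted responder emits, on each trial of its category with
#' Bernoulli(reliability) success, the unit-peak transient kernel scaled by
#' its ground-truth amplitude at the category's anchor (whisker/pairing/
#' matched: stimulus onset; mismatch: the *scheduled* onset on mismatch
#' trials only; sound / sound offset: the looming-sound onset/offset). Ramp
#' neurons respond like matched neurons and additionally carry a
#' deterministic linear dF/F ramp from sound onset to (scheduled) stimulus
#' onset on every matched trial, peaking at \code{prestimRampAmp}. The
#' response term is multiplicative in baseline F, so downstream dF/F is
#' baseline-invariant; noise is white Gaussian with sd
#' \code{noiseSd * baselineF}; drift is a slow sinusoid with a random phase
#' per neuron.
#'
#' @param schedule a \linkS4class{TrialTable} from \code{\link{makeTrialSchedule}}.
#' @param truth ground truth from \code{\link{assignGroundTruth}}.
#' @param config the \linkS4class{SimConfig} used for both.
#' @param seed RNG seed for reliability draws, drift phases and noise.
#' @return a \linkS4class{CalciumRecording}.
#' @export
synthesizeTraces <- function(schedule, truth, config,
                             seed = stageSeed(config@seed, "traces")) {
  stopifnot(methods::is(schedule, "TrialTable"))
  if (nrow(truth) != config@nNeurons)
    stopTyped("consistencyError", sprintf(
      "ground truth has %d neurons but config expects %d",
      nrow(truth), config@nNeurons))
  d <- trialData(schedule)
  rate <- config@frameRate
  tEnd <- max(d$cue_onset_s) + config@trialLenRange[2] - 2 + 1
  nFr <- as.integer(ceiling(tEnd * rate))
  n <- config@nNeurons
  kern <- calciumKernel(config@kernelRise, config@kernelDecay)
  kLen <- as.integer(ceiling(6 * config@kernelDecay * rate))
  kVec <- kern((seq_len(kLen) - 1) / rate)
  cats <- truthCategories(truth)
  scaleFor <- function(cat) {
    s <- config@categoryAmpScale
    if (cat %in% names(s)) s[[cat]] else 1
  }
  catInfo <- lapply(stats::setNames(nm = unique(unlist(cats))), .categoryTrials, d = d)

  set.seed(seed)
  F <- matrix(0, nrow = n, ncol = nFr)
  tFrame <- (seq_len(nFr) - 1) / rate
  for (i in seq_len(n)) {
    phase <- stats::runif(1, 0, config@driftPeriod)
    resp <- numeric(nFr)
    for (cat in cats[[i]]) {
      info <- catInfo[[cat]]
      if (!length(info$rows)) next
      anchors <- d[[info$anchor]][info$rows]
      if (cat == "ramp") {
        ## deterministic expectation ramp over sound -> (scheduled) stimulus
        for (j in seq_along(anchors)) {
          s0 <- timeToFrame0(d$sound_onset_s[info$rows[j]], rate)
          s1 <- timeToFrame0(anchors[j], rate)
          m <- s1 - s0
          if (m > 0)
            resp[(s0 + 1):(s0 + m)] <- resp[(s0 + 1):(s0 + m)] +
              config@prestimRampAmp * (seq_len(m) / m)
        }
        next
      }
      hits <- stats::runif(length(anchors)) < truth$true_reliability[i]
      amp <- truth$true_amplitude[i] * scaleFor(cat)
      for (j in which(hits)) {
        a0 <- timeToFrame0(anchors[j], rate)
        idx <- (a0 + 1):min(a0 + kLen, nFr)
        resp[idx] <- resp[idx] + amp * kVec[seq_along(idx)]
      }
    }
    drift <- if (config@driftAmplitude > 0)
      config@driftAmplitude * sin(2 * pi * (tFrame + phase) / config@driftPeriod)
    else 0
    noise <- stats::rnorm(nFr, 0, config@noiseSd * config@baselineF)
    F[i, ] <- config@baselineF * (1 + drift) * (1 + resp) + noise
  }
  CalciumRecording(F, frameRate = rate, neuronIds = truth$neuron_id,
                   blockId = "synthetic")
}

#' Run the full synthetic-experiment generator
#'
#' Schedule, ground truth and traces from one \linkS4class{SimConfig}, each
#' stage on its own reproducible seed substream.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed master seed (defaults to \code{config@seed}).
#' @return list with elements \code{recording}, \code{trials}, \code{truth},
#'   \code{config}.
#' @export
simulateExperiment <- function(config = simConfig(), seed = config@seed) {
  schedule <- makeTrialSchedule(config, stageSeed(seed, "schedule"))
  truth <- assignGroundTruth(config, stageSeed(seed, "truth"))
  rec <- synthesizeTraces(schedule, truth, config, stageSeed(seed, "traces"))
  list(recording = rec, trials = schedule, truth = truth, config = config)
}
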
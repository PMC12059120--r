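# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles never call the package's own test implementations.

# exact two-sided Mann-Whitney p by enumeration of all C(n+m, n) group
# assignments of the pooled sample (tie-free inputs only)
enumRankSumP <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  pLo <- mean(stats <= obs)
  pHi <- mean(stats >= obs)
  min(1, 2 * min(pLo, pHi))
}

# exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# patterns (tie-free, nonzero differences only)
enumSignedRankP <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.numeric(signs %*% r)
  pLo <- mean(stats <= obs)
  pHi <- mean(stats >= obs)
  min(1, 2 * min(pLo, pHi))
}

# quadrature oracle: baseline-corrected mean of the closed-form transient
# kernel over a response window [0, len) (baseline window is zero)
kernelWindowMeanOracle <- function(amp, len = 1, tauRise = 0.05, tauDecay = 1.0) {
  k <- calciumKernel(tauRise, tauDecay)
  amp * stats::integrate(k, 0, len, rel.tol = 1e-10)$value / len
}

# small synthetic experiment for fast unit tests
tinyConfig <- function(...) {
  defaults <- list(
    nNeurons = 20L,
    sessionSizes = c(sound_looming = 6L, sound_nonlooming = 6L, whisker = 10L,
                     pairing = 6L, matched = 14L, mismatch = 6L),
    categoryFractions = c(whisker = 0.25, matched = 0.25, mismatch = 0.2),
    nOverlapMatchedMismatch = 0L,
    reliability = 1, noiseSd = 0.02, driftAmplitude = 0,
    amplitudeMeanlog = log(0.5), amplitudeSdlog = 0.1, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simConfig, args)
}

# a hand-built dff tensor: values array with given per-trial snippets
makeDffTensor <- function(values, t0 = 61L, frameRate = 30) {
  methods::new("DffTensor", values = values, t0 = as.integer(t0),
               frameRate = frameRate,
               trialIds = seq_len(dim(values)[2]),
               neuronIds = paste0("n", seq_len(dim(values)[1])),
               anchor = "cue_onset",
               f0 = matrix(1, dim(values)[1], dim(values)[2]))
}

# a minimal valid trial table data.frame (one trial per session)
smallTrialFrame <- function() {
  data.frame(
    trial_id = 1:4,
    session = c("sound", "whisker", "pairing", "interleaved"),
    trial_type = c("sound_looming", "whisker_only", "paired", "matched"),
    cue_onset_s = c(3, 15, 27, 39),
    sound_onset_s = c(4, NA, 28, 40),
    sound_offset_s = c(5, NA, 29, 41),
    stim_onset_s = c(NA, 17, 29, 41),
    intensity_pct = c(NA, 80, 80, 80),
    delay_s = c(NA, NA, 0, 0),
    stringsAsFactors = FALSE)
}
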
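## Central S4 containers. One class per stage of the pipeline:
## CalciumRecording (continuous raw F), TrialTable (per-trial annotations),
## TrialTensor/DffTensor (trial-aligned snippets), NullDistribution
## (shuffle-null draws), SimConfig (generator settings).

#' Session labels in their experimental presentation order
#' @export
SESSION_LEVELS <- c("sound", "whisker", "pairing", "interleaved")

#' Trial type labels
#' @export
TRIAL_TYPE_LEVELS <- c("sound_looming", "sound_nonlooming", "whisker_only",
                       "paired", "matched", "mismatch_omission",
                       "mismatch_decreased", "mismatch_increased")

## columns of the on-disk trial table, in order
TRIAL_COLUMNS <- c("trial_id", "session", "trial_type", "cue_onset_s",
                   "sound_onset_s", "sound_offset_s", "stim_onset_s",
                   "intensity_pct", "delay_s")

#' CalciumRecording: a continuous fluorescence recording
#'
#' Raw fluorescence F for one imaging block, neurons in rows and frames in
#' columns, with the acquisition frame rate and stable neuron identifiers.
#'
#' @slot fluorescence numeric matrix, neurons x frames, arbitrary units.
#' @slot frameRate sampling rate in Hz (> 0).
#' @slot neuronIds character vector of unique neuron identifiers.
#' @slot blockId label for the imaging block / condition.
#' @export
setClass("CalciumRecording",
         representation(fluorescence = "matrix", frameRate = "numeric",
                        neuronIds = "character", blockId = "character"),
         validity = function(object) {
           msg <- character()
           if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
               object@frameRate <= 0)
             msg <- c(msg, "frameRate must be a single positive number")
           if (!is.numeric(object@fluorescence))
             msg <- c(msg, "fluorescence must be numeric")
           if (anyNA(object@fluorescence) || any(!is.finite(object@fluorescence))) {
             bad <- which(!is.finite(object@fluorescence), arr.ind = TRUE)[1, ]
             msg <- c(msg, sprintf(
               "non-finite fluorescence at neuron '%s', frame %d",
               object@neuronIds[bad[1L]], bad[2L]))
           }
           if (length(object@neuronIds) != nrow(object@fluorescence))
             msg <- c(msg, "neuronIds length must equal number of rows")
           if (anyDuplicated(object@neuronIds))
             msg <- c(msg, "neuronIds must be unique")
           if (length(msg)) msg else TRUE
         })

#' Construct a CalciumRecording
#'
#' @param fluorescence numeric matrix, neurons x frames.
#' @param frameRate sampling rate in Hz.
#' @param neuronIds optional neuron identifiers (default "n1", "n2", ...).
#' @param blockId block / condition label.
#' @return a validated \linkS4class{CalciumRecording}.
#' @export
CalciumRecording <- function(fluorescence, frameRate,
                             neuronIds = NULL, blockId = "block1") {
  fluorescence <- as.matrix(fluorescence)
  if (is.null(neuronIds)) neuronIds <- paste0("n", seq_len(nrow(fluorescence)))
  methods::new("CalciumRecording", fluorescence = fluorescence,
               frameRate = as.numeric(frameRate),
               neuronIds = as.character(neuronIds),
               blockId = as.character(blockId))
}

#' TrialTable: validated per-trial annotations
#'
#' Wraps a data.frame with one row per trial: session, trial type, event
#' times in seconds from recording start (cue onset, sound onset/offset,
#' stimulus onset -- for omission trials the *scheduled* onset), stimulus
#' intensity (percent of maximum; 0 for omissions) and the sound-to-stimulus
#' delay.
#'
#' @slot data data.frame with the canonical trial columns.
#' @export
setClass("TrialTable", representation(data = "data.frame"),
         validity = function(object) validateTrialData(object@data))

## Returns TRUE or a character vector of problems.
validateTrialData <- function(d) {
  msg <- character()
  missing <- setdiff(TRIAL_COLUMNS, names(d))
  if (length(missing))
    return(paste("missing trial table columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(d$trial_id)) msg <- c(msg, "trial_ids must be unique")
  bad <- setdiff(unique(d$session), SESSION_LEVELS)
  if (length(bad)) msg <- c(msg, paste("unknown session:", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(d$trial_type), TRIAL_TYPE_LEVELS)
  if (length(bad)) msg <- c(msg, paste("unknown trial_type:", paste(bad, collapse = ", ")))
  if (nrow(d) > 1) {
    if (any(diff(d$trial_id) <= 0))
      msg <- c(msg, "trial_ids must be strictly increasing")
    if (any(diff(d$cue_onset_s) <= 0))
      msg <- c(msg, "trials must be strictly increasing in time (cue_onset_s)")
  }
  has_sound <- !is.na(d$sound_onset_s)
  if (any(has_sound & d$cue_onset_s >= d$sound_onset_s))
    msg <- c(msg, "cue_onset_s must precede sound_onset_s")
  has_both <- has_sound & !is.na(d$stim_onset_s)
  if (any(has_both & d$sound_onset_s >= d$stim_onset_s))
    msg <- c(msg, "sound_onset_s must precede stim_onset_s")
  om <- d$trial_type == "mismatch_omission"
  if (any(om & (is.na(d$intensity_pct) | d$intensity_pct != 0)))
    msg <- c(msg, "mismatch_omission trials must have intensity_pct = 0")
  if (any(om & is.na(d$stim_onset_s)))
    msg <- c(msg, "mismatch_omission trials must carry the scheduled stim_onset_s")
  ## sessions, where present, must appear in experimental order
  pres <- unique(as.character(d$session))
  if (!identical(pres, intersect(SESSION_LEVELS, pres)))
    msg <- c(msg, "sessions must appear in the order sound, whisker, pairing, interleaved")
  if (length(msg)) msg else TRUE
}

#' Construct a TrialTable from a data.frame
#'
#' @param data data.frame with the canonical trial columns (see
#'   \linkS4class{TrialTable}).
#' @return a validated \linkS4class{TrialTable}.
#' @export
TrialTable <- function(data) {
  data <- as.data.frame(data)
  num <- c("cue_onset_s", "sound_onset_s", "sound_offset_s", "stim_onset_s",
           "intensity_pct", "delay_s")
  for (cl in intersect(num, names(data))) data[[cl]] <- as.numeric(data[[cl]])
  if ("trial_id" %in% names(data)) data$trial_id <- as.integer(data$trial_id)
  ok <- validateTrialData(data)
  if (!isTRUE(ok)) stopTyped("validationError", paste(ok, collapse = "; "))
  rownames(data) <- NULL
  methods::new("TrialTable", data = data)
}

#' WindowSpec: analysis window geometry
#'
#' Lengths of the response, baseline and pre-stimulus windows in seconds and
#' the event the windows anchor to. Windows are half-open frame intervals
#' \code{[start, end)}; lengths convert to frames with
#' \code{\link{secondsToFrames}}.
#'
#' @slot responseLen response window length, seconds.
#' @slot baselineLen baseline window length, seconds.
#' @slot prestimLen pre-stimulus window length, seconds.
#' @slot anchor one of "stim_onset", "sound_onset", "sound_offset", "cue_onset".
#' @export
setClass("WindowSpec",
         representation(responseLen = "numeric", baselineLen = "numeric",
                        prestimLen = "numeric", anchor = "character"),
         prototype(responseLen = 1.0, baselineLen = 1.0, prestimLen = 0.5,
                   anchor = "stim_onset"),
         validity = function(object) {
           msg <- character()
           if (any(c(object@responseLen, object@baselineLen, object@prestimLen) <= 0))
             msg <- c(msg, "all window lengths must be > 0")
           if (!object@anchor %in% c("stim_onset", "sound_onset", "sound_offset",
                                     "cue_onset"))
             msg <- c(msg, "unknown anchor")
           if (length(msg)) msg else TRUE
         })

#' Construct a WindowSpec
#' @param responseLen,baselineLen,prestimLen window lengths in seconds.
#' @param anchor anchoring event.
#' @return a \linkS4class{WindowSpec}.
#' @export
windowSpec <- function(responseLen = 1.0, baselineLen = 1.0, prestimLen = 0.5,
                       anchor = "stim_onset") {
  methods::new("WindowSpec", responseLen = responseLen, baselineLen = baselineLen,
               prestimLen = prestimLen, anchor = anchor)
}

#' TrialTensor: trial-aligned raw fluorescence snippets
#'
#' A neurons x trials x frames array of equal-length snippets cut around a
#' per-trial anchor event. \code{t0} is the 1-based index of the anchor frame
#' within each snippet (identical across trials).
#'
#' @slot values numeric array, neurons x trials x frames.
#' @slot t0 1-based anchor frame index within the snippet.
#' @slot frameRate Hz.
#' @slot trialIds trial ids matching the source TrialTable.
#' @slot neuronIds neuron identifiers.
#' @slot anchor the anchoring event column.
#' @export
setClass("TrialTensor",
         representation(values = "array", t0 = "integer", frameRate = "numeric",
                        trialIds = "integer", neuronIds = "character",
                        anchor = "character"),
         validity = function(object) {
           msg <- character()
           if (length(dim(object@values)) != 3L)
             msg <- c(msg, "values must be a 3-d array (neurons x trials x frames)")
           else {
             if (dim(object@values)[2] != length(object@trialIds))
               msg <- c(msg, "trialIds must match trial dimension")
             if (dim(object@values)[1] != length(object@neuronIds))
               msg <- c(msg, "neuronIds must match neuron dimension")
             if (object@t0 < 1L || object@t0 > dim(object@values)[3])
               msg <- c(msg, "t0 must lie within the snippet")
           }
           if (length(msg)) msg else TRUE
         })

#' DffTensor: trial-aligned dF/F snippets
#'
#' Same geometry as \linkS4class{TrialTensor}, but values are dF/F
#' normalized per trial by that trial's own pre-cue baseline F0.
#'
#' @slot f0 numeric matrix, neurons x trials, the per-trial baselines used.
#' @export
setClass("DffTensor", contains = "TrialTensor",
         representation(f0 = "matrix"),
         validity = function(object) {
           msg <- character()
           if (any(!is.finite(object@values)))
             msg <- c(msg, "dF/F values must be finite")
           if (any(object@f0 <= 0))
             msg <- c(msg, "per-trial F0 must be > 0")
           if (length(msg)) msg else TRUE
         })

#' NullDistribution: shuffle-null draws per neuron
#'
#' Baseline-corrected mean dF/F of windows placed at random anchors within
#' the same session's trials; \code{nDraws} draws per neuron.
#'
#' @slot values numeric matrix, neurons x draws.
#' @slot nDraws number of draws.
#' @slot seed RNG seed used, for reproducibility.
#' @export
setClass("NullDistribution",
         representation(values = "matrix", nDraws = "integer", seed = "integer"),
         validity = function(object) {
           msg <- character()
           if (ncol(object@values) != object@nDraws)
             msg <- c(msg, "values must have nDraws columns")
           if (any(!is.finite(object@values)))
             msg <- c(msg, "null values must be finite")
           if (length(msg)) msg else TRUE
         })

#' SimConfig: synthetic experiment settings
#'
#' Defaults reproduce the study conditions of the auditory-tactile sequence
#' protocol: 30 Hz sampling, 2 s pre-cue baseline, 1 s looming sound, whisker
#' stimulus at sound offset (or after a configurable delay), session sizes of
#' 25+25 sound, 50 whisker, 20 pairing and 120 matched + 30 mismatch
#' interleaved trials, 8-9 s trials with 2-5 s inter-trial intervals, and
#' GECI-like difference-of-exponential transients with per-trial reliability
#' ~0.35 and lognormal amplitude heterogeneity around a 0.3 dF/F peak.
#'
#' @slot nNeurons number of simulated neurons.
#' @slot frameRate Hz.
#' @slot sessionSizes named counts for sound_looming, sound_nonlooming,
#'   whisker, pairing, matched, mismatch.
#' @slot mismatchMode "omission", "decreased" or "increased".
#' @slot delay seconds between sound offset and (scheduled) stimulus onset.
#' @slot itiRange inter-trial interval range, seconds.
#' @slot trialLenRange trial length range, seconds.
#' @slot kernelRise,kernelDecay transient kinetics, seconds.
#' @slot categoryFractions named fractions of neurons planted per response
#'   category (whisker, pairing, matched, mismatch, sound, sound_offset,
#'   ramp); the remainder are non-responders.
#' @slot nOverlapMatchedMismatch number of mismatch neurons that additionally
#'   respond on matched trials.
#' @slot amplitudeMeanlog,amplitudeSdlog lognormal peak-amplitude parameters.
#' @slot categoryAmpScale named per-category amplitude multipliers.
#' @slot reliability per-trial response probability of planted responders.
#' @slot noiseSd additive white-noise sd, as a fraction of baseline F.
#' @slot driftAmplitude slow sinusoidal drift amplitude, fraction of baseline.
#' @slot driftPeriod drift period, seconds.
#' @slot baselineF baseline fluorescence, arbitrary units.
#' @slot prestimRampAmp peak dF/F of the pre-stimulus expectation ramp.
#' @slot seed integer generator seed.
#' @export
setClass("SimConfig",
         representation(nNeurons = "integer", frameRate = "numeric",
                        sessionSizes = "integer", mismatchMode = "character",
                        delay = "numeric", itiRange = "numeric",
                        trialLenRange = "numeric", kernelRise = "numeric",
                        kernelDecay = "numeric", categoryFractions = "numeric",
                        nOverlapMatchedMismatch = "integer",
                        amplitudeMeanlog = "numeric", amplitudeSdlog = "numeric",
                        categoryAmpScale = "numeric", reliability = "numeric",
                        noiseSd = "numeric", driftAmplitude = "numeric",
                        driftPeriod = "numeric", baselineF = "numeric",
                        prestimRampAmp = "numeric", seed = "integer"),
         validity = function(object) {
           msg <- character()
           if (object@nNeurons < 1L) msg <- c(msg, "nNeurons must be >= 1")
           if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
           if (sum(object@categoryFractions) > 1 + 1e-12)
             msg <- c(msg, "categoryFractions must sum to <= 1")
           if (any(object@categoryFractions < 0))
             msg <- c(msg, "categoryFractions must be >= 0")
           if (object@reliability < 0 || object@reliability > 1)
             msg <- c(msg, "reliability must be in [0, 1]")
           if (object@kernelRise <= 0 || object@kernelDecay <= object@kernelRise)
             msg <- c(msg, "need kernelDecay > kernelRise > 0")
           if (object@baselineF <= 0) msg <- c(msg, "baselineF must be > 0")
           if (!object@mismatchMode %in% c("omission", "decreased", "increased"))
             msg <- c(msg, "unknown mismatchMode")
           if (object@sessionSizes[["mismatch"]] > 0 &&
               object@sessionSizes[["matched"]] == 0)
             msg <- c(msg, "mismatch trials require a nonzero matched count")
           if (length(msg)) msg else TRUE
         })
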
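#' @describeIn CalciumRecording frame rate in Hz
#' @param x a CalciumRecording.
#' @export
setMethod("frameRate", "CalciumRecording", function(x) x@frameRate)

#' @describeIn CalciumRecording neuron identifiers
#' @export
setMethod("neuronIds", "CalciumRecording", function(x) x@neuronIds)

#' @describeIn CalciumRecording block / condition label
#' @export
setMethod("blockId", "CalciumRecording", function(x) x@blockId)

#' @describeIn CalciumRecording raw fluorescence matrix (neurons x frames)
#' @export
setMethod("fluorescence", "CalciumRecording", function(x) x@fluorescence)

#' @describeIn CalciumRecording number of neurons
#' @export
setMethod("nNeurons", "CalciumRecording", function(x) nrow(x@fluorescence))

#' @describeIn CalciumRecording number of frames
#' @export
setMethod("nFrames", "CalciumRecording", function(x) ncol(x@fluorescence))

setMethod("show", "CalciumRecording", function(object) {
  cat(sprintf("CalciumRecording: %d neurons x %d frames @ %g Hz (%.1f s), block '%s'\n",
              nNeurons(object), nFrames(object), frameRate(object),
              nFrames(object) / frameRate(object), blockId(object)))
})

#' @describeIn TrialTensor frame rate in Hz
#' @param x a TrialTensor or DffTensor.
#' @export
setMethod("frameRate", "TrialTensor", function(x) x@frameRate)

#' @describeIn TrialTensor neuron identifiers
#' @export
setMethod("neuronIds", "TrialTensor", function(x) x@neuronIds)

#' @describeIn TrialTensor number of neurons
#' @export
setMethod("nNeurons", "TrialTensor", function(x) dim(x@values)[1])

#' @describeIn TrialTensor number of trials
#' @export
setMethod("nTrials", "TrialTensor", function(x) dim(x@values)[2])

#' @describeIn TrialTensor snippet length in frames
#' @export
setMethod("nFrames", "TrialTensor", function(x) dim(x@values)[3])

#' @describeIn TrialTensor trial ids of the aligned trials
#' @export
setMethod("trialIds", "TrialTensor", function(x) x@trialIds)

#' @describeIn TrialTensor the neurons x trials x frames array
#' @export
setMethod("tensorValues", "TrialTensor", function(x) x@values)

#' @describeIn TrialTensor 1-based index of the anchor frame in each snippet
#' @export
setMethod("anchorFrame", "TrialTensor", function(x) x@t0)

setMethod("show", "TrialTensor", function(object) {
  cat(sprintf("%s: %d neurons x %d trials x %d frames @ %g Hz, anchored at %s (t0 = %d)\n",
              class(object), nNeurons(object), nTrials(object), nFrames(object),
              frameRate(object), object@anchor, object@t0))
})

#' @describeIn NullDistribution neurons x draws matrix of null responses
#' @param x a NullDistribution.
#' @export
setMethod("nullValues", "NullDistribution", function(x) x@values)

#' @describeIn NullDistribution number of neurons
#' @export
setMethod("nNeurons", "NullDistribution", function(x) nrow(x@values))

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: %d neurons x %d draws (seed %d)\n",
              nrow(object@values), object@nDraws, object@seed))
})
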
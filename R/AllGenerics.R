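#' @name ppcmismatch-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 containers. Use these rather
#'   than reaching into slots.
#' @param x an object.
#' @keywords internal
NULL

#' @rdname ppcmismatch-generics
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("blockId", function(x) standardGeneric("blockId"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("fluorescence", function(x) standardGeneric("fluorescence"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("anchorFrame", function(x) standardGeneric("anchorFrame"))

#' @rdname ppcmismatch-generics
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))
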
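#' @rdname NeuromastExperiment-class
#' @param object,x a \linkS4class{NeuromastExperiment}.
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname NeuromastExperiment-class
#' @export
setGeneric("stimulusLog", function(x) standardGeneric("stimulusLog"))

#' @rdname NeuromastExperiment-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname NeuromastExperiment-class
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' @rdname NeuromastExperiment-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname NeuromastExperiment-class
#' @export
setGeneric("neuromastUniverse", function(x) standardGeneric("neuromastUniverse"))

#' @rdname NeuromastExperiment-class
#' @export
setGeneric("recordingLength", function(x) standardGeneric("recordingLength"))

#' @rdname DecoderResult-class
#' @param x a \linkS4class{DecoderResult}.
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname DecoderResult-class
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname DecoderResult-class
#' @export
setGeneric("confusionMatrix",
           function(x, ...) standardGeneric("confusionMatrix"))

#' @rdname PairDecomposition-class
#' @export
setGeneric("planeAngle", function(x) standardGeneric("planeAngle"))

#' @rdname PairDecomposition-class
#' @export
setGeneric("nonlinearResidual", function(x) standardGeneric("nonlinearResidual"))
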
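#' @rdname NeuromastExperiment-class
#' @export
setMethod("traces", "NeuromastExperiment", function(x) assay(x, "traces"))

#' @rdname NeuromastExperiment-class
#' @export
setMethod("stimulusLog", "NeuromastExperiment", function(x) x@stimulusLog)

#' @rdname NeuromastExperiment-class
#' @export
setMethod("samplingRate", "NeuromastExperiment", function(x) x@samplingRate)

#' @rdname NeuromastExperiment-class
#' @export
setMethod("roiTable", "NeuromastExperiment", function(x) {
  as.data.frame(rowData(x))
})

#' @rdname NeuromastExperiment-class
#' @export
setMethod("groundTruth", "NeuromastExperiment", function(x) x@groundTruth)

#' @rdname NeuromastExperiment-class
#' @export
setMethod("neuromastUniverse", "NeuromastExperiment", function(x) {
  attr(x@stimulusLog, "universe")
})

#' @rdname NeuromastExperiment-class
#' @export
setMethod("recordingLength", "NeuromastExperiment", function(x) {
  attr(x@stimulusLog, "recording_length")
})

setMethod("show", "NeuromastExperiment", function(object) {
  cat("NeuromastExperiment:", nrow(object), "neurons x", ncol(object),
      "frames @", format(object@samplingRate, digits = 4), "Hz\n")
  log <- object@stimulusLog
  cat("  stimulus log:", nrow(log), "events,",
      length(unique(log$label)), "distinct conditions",
      sprintf("(%.1f s recording)\n",
              attr(log, "recording_length") %||% NA_real_))
  reg <- table(as.character(rowData(object)$region))
  cat("  regions:", paste(sprintf("%s=%d", names(reg), reg), collapse = ", "),
      "\n")
  cat("  ground truth:", if (length(object@groundTruth)) "present" else
      "absent", "\n")
})

#' Construct a NeuromastExperiment
#'
#' @param traces neurons x frames numeric matrix.
#' @param samplingRate frames (volumes) per second.
#' @param stimulusLog stimulus log as produced by
#'   \code{\link{buildStimulusProtocol}}.
#' @param roi data.frame with columns \code{x_um}, \code{y_um}, \code{z_um},
#'   \code{region}; one row per neuron in trace order.
#' @param groundTruth optional list of planted parameters (synthetic data).
#' @return a validated \linkS4class{NeuromastExperiment}.
#' @export
NeuromastExperiment <- function(traces, samplingRate, stimulusLog, roi,
                                groundTruth = list()) {
  traces <- as.matrix(traces)
  .assert(is.numeric(traces) && !anyNA(traces),
          "traces must be a numeric matrix with no missing values")
  .assert(nrow(roi) == nrow(traces),
          "ROI table must have one row per neuron (got ", nrow(roi),
          " rows for ", nrow(traces), " neurons)")
  if (is.null(rownames(traces)))
    rownames(traces) <- sprintf("n%04d", seq_len(nrow(traces)))
  se <- SummarizedExperiment(
    assays = list(traces = traces),
    rowData = DataFrame(roi, row.names = rownames(traces))
  )
  new("NeuromastExperiment", se, stimulusLog = stimulusLog,
      samplingRate = as.numeric(samplingRate),
      groundTruth = as.list(groundTruth))
}

#' @rdname DecoderResult-class
#' @export
setMethod("weightMatrix", "DecoderResult", function(x) x@weights)

#' @rdname DecoderResult-class
#' @export
setMethod("accuracy", "DecoderResult", function(x) x@accuracy)

#' @rdname DecoderResult-class
#' @param normalized return the row-normalized matrix (default) or raw counts.
#' @export
setMethod("confusionMatrix", "DecoderResult",
  function(x, normalized = TRUE) {
    if (normalized) x@confusion else x@confusionCounts
  })

setMethod("show", "DecoderResult", function(object) {
  cat("DecoderResult:", length(object@classLevels), "classes x",
      ncol(object@weights), "neurons\n")
  cat(sprintf("  cost C = %.3g, test accuracy = %.3f\n",
              object@cost, object@accuracy))
  cat("  per-class:",
      paste(sprintf("%s=%.2f", object@classLevels, object@classAccuracy),
            collapse = ", "), "\n")
})

#' @rdname PairDecomposition-class
#' @param x a \linkS4class{PairDecomposition}.
#' @export
setMethod("planeAngle", "PairDecomposition", function(x) x@angle)

#' @rdname PairDecomposition-class
#' @export
setMethod("nonlinearResidual", "PairDecomposition", function(x) x@residual)

#' @rdname PairDecomposition-class
#' @param object a \linkS4class{PairDecomposition}.
#' @export
setMethod("coef", "PairDecomposition", function(object) {
  c(alpha = object@alpha, beta = object@beta)
})

setMethod("show", "PairDecomposition", function(object) {
  cat("PairDecomposition", if (nzchar(object@pair)) paste0("(", object@pair, ")"),
      "\n")
  cat(sprintf("  alpha = %.3f, beta = %.3f, angle = %.2f deg, mean R_NL = %.4f\n",
              object@alpha, object@beta, object@angle, object@summaryRNL))
})
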
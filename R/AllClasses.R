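#' NeuromastExperiment: container for one stimulation experiment
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are segmented neurons
#' (ROIs), columns are imaging frames. The single assay \code{"traces"}
#' holds the fluorescence matrix; \code{rowData} carries the ROI table
#' (\code{x_um}, \code{y_um}, \code{z_um}, \code{region}); the stimulus log
#' and acquisition rate live in dedicated slots so that validity can tie the
#' three together. For synthetic experiments the planted ground truth is
#' retained in \code{groundTruth}.
#'
#' @slot stimulusLog a \code{data.frame} with columns \code{onset_time}
#'   (seconds), \code{label} (a \code{"+"}-joined set of neuromast
#'   identities) and \code{duration} (seconds), plus attributes
#'   \code{universe} (ordered identity labels) and \code{recording_length}
#'   (seconds).
#' @slot samplingRate acquisition rate in volumes (frames) per second.
#' @slot groundTruth a list, empty for real data; for synthetic data it
#'   holds \code{tuning} (neurons x identities amplitude matrix),
#'   \code{reliability}, \code{noise_sd}, \code{preferred}, and
#'   \code{pair_gain} (named numeric, names are pair labels).
#'
#' @seealso \code{\link{simulateExperiment}}, \code{\link{readBundle}}
#' @export
setClass("NeuromastExperiment",
  contains = "SummarizedExperiment",
  slots = c(
    stimulusLog = "data.frame",
    samplingRate = "numeric",
    groundTruth = "list"
  )
)

.REGIONS <- c("MON_ipsi", "MON_contra", "cerebellum", "TS", "OT",
              "superior_medulla", "pLLg", "other")

setValidity("NeuromastExperiment", function(object) {
  msg <- character()
  if (!"traces" %in% names(assays(object)))
    msg <- c(msg, "assay 'traces' is required")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  log <- object@stimulusLog
  needed <- c("onset_time", "label", "duration")
  if (!all(needed %in% names(log))) {
    msg <- c(msg, paste("stimulusLog must have columns",
                        paste(needed, collapse = ", ")))
  } else if (nrow(log)) {
    if (is.unsorted(log$onset_time))
      msg <- c(msg, "stimulus events must be sorted by onset_time")
    if (any(log$onset_time < 0)) msg <- c(msg, "onset_time must be >= 0")
    if (any(log$duration <= 0)) msg <- c(msg, "duration must be > 0")
    len <- attr(log, "recording_length")
    if (!is.null(len)) {
      if (any(log$onset_time + log$duration > len))
        msg <- c(msg, "every event must end before recording_length")
      expected <- as.integer(ceiling(len * object@samplingRate))
      if (ncol(object) != expected)
        msg <- c(msg, sprintf(
          "trace matrix has %d frames but recording_length %.3f s at %.3f Hz implies %d",
          ncol(object), len, object@samplingRate, expected))
    }
  }
  rd <- rowData(object)
  for (col in c("x_um", "y_um", "z_um", "region")) {
    if (!col %in% names(rd)) msg <- c(msg, paste0("rowData needs column ", col))
  }
  if (all(c("x_um", "y_um", "z_um") %in% names(rd)) && nrow(rd)) {
    if (!all(is.finite(c(rd$x_um, rd$y_um, rd$z_um))))
      msg <- c(msg, "ROI coordinates must be finite")
  }
  if ("region" %in% names(rd) && nrow(rd)) {
    bad <- setdiff(unique(as.character(rd$region)), .REGIONS)
    if (length(bad))
      msg <- c(msg, paste("unknown region labels:", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' DecoderResult: fitted linear population decoder
#'
#' Returned by \code{\link{trainDecoder}}. Weights are averaged across the
#' cross-validation folds at the selected regularization value.
#'
#' @slot weights classes x neurons weight matrix.
#' @slot intercepts per-class intercepts.
#' @slot cost selected regularization value (SVM cost C).
#' @slot cvAccuracy data.frame of mean held-out validation accuracy per
#'   candidate cost.
#' @slot accuracy overall test-set accuracy.
#' @slot classAccuracy per-class test accuracy (diagonal of the normalized
#'   confusion matrix).
#' @slot confusion row-normalized confusion matrix (true x predicted).
#' @slot confusionCounts raw confusion counts.
#' @slot classLevels class labels in training order.
#' @slot zeroTol relative threshold below which a weight is treated as zero.
#' @export
setClass("DecoderResult",
  slots = c(
    weights = "matrix", intercepts = "numeric", cost = "numeric",
    cvAccuracy = "data.frame", accuracy = "numeric",
    classAccuracy = "numeric", confusion = "matrix",
    confusionCounts = "matrix", classLevels = "character",
    zeroTol = "numeric"
  )
)

setValidity("DecoderResult", function(object) {
  msg <- character()
  if (nrow(object@weights) != length(object@classLevels))
    msg <- c(msg, "weights must have one row per class")
  if (length(object@accuracy) == 1L &&
      (object@accuracy < 0 || object@accuracy > 1))
    msg <- c(msg, "accuracy must lie in [0, 1]")
  rs <- rowSums(object@confusion)
  ok <- is.na(rs) | abs(rs - 1) < 1e-8 | rs == 0
  if (!all(ok)) msg <- c(msg, "confusion rows must sum to 1 (or be empty)")
  if (length(msg)) msg else TRUE
})

#' PairDecomposition: bounded linear decomposition of a paired response
#'
#' Returned by \code{\link{decomposePair}}. Encodes
#' \code{R(A,B) = alpha R(A,0) + beta R(0,B) + residual} with
#' \code{alpha, beta} restricted to a box (default [-1, 1]); the angle
#' between \code{R(A,B)} and the plane of the individual responses is
#' \code{asin(||residual|| / ||R(A,B)||)} in degrees.
#'
#' @slot alpha,beta bounded coefficients.
#' @slot residual per-neuron nonlinear component R_NL(A,B).
#' @slot angle angle to the individual-response plane, degrees in [0, 90].
#' @slot unconstrainedAngle same angle from the unconstrained projection,
#'   for diagnostics.
#' @slot summaryRNL mean of the residual entries (sign marks supra- vs
#'   sub-linear population tendency).
#' @slot pair label of the combined condition (may be \code{""}).
#' @export
setClass("PairDecomposition",
  slots = c(
    alpha = "numeric", beta = "numeric", residual = "numeric",
    angle = "numeric", unconstrainedAngle = "numeric",
    summaryRNL = "numeric", pair = "character"
  )
)

setValidity("PairDecomposition", function(object) {
  msg <- character()
  if (!is.na(object@angle) && (object@angle < 0 || object@angle > 90))
    msg <- c(msg, "angle must lie in [0, 90] degrees")
  if (length(msg)) msg else TRUE
})
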
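# Single- vs mixed-selectivity classification and conditional probabilities.

#' Classify single- and mixed-selective neurons
#'
#' Per condition, trial windows reaching from \code{baseline_pre} frames
#' before the onset to three frames after it are averaged across trials
#' and z-scored per neuron over that averaged window. A neuron counts as
#' responsive to the condition when its mean z-scored amplitude across the
#' selectivity span (one frame before the onset to three frames after,
#' about 1.8 s) exceeds the mean of the median-filtered pre-onset baseline
#' segment by at least \code{k_sd} of that baseline's standard deviations.
#' Pre-onset frames are the only frames reliably outside every stimulus
#' window when the inter-stimulus interval is comparable to the indicator
#' decay. Labels: \code{nonresponsive} (empty set), \code{single} (one
#' condition), \code{mixed} (two or more).
#'
#' @param ne a \linkS4class{NeuromastExperiment}.
#' @param classes list of identity sets; defaults to all distinct
#'   conditions in the log.
#' @param k_sd amplitude criterion (default 2).
#' @param baseline_window median filter width in frames (default 4).
#' @param baseline_pre pre-onset frames per trial; default 8 frames
#'   (about 3.7 s), shortened when the protocol layout allows less. Short
#'   recent baselines are preferred because frames further back sit closer
#'   to the preceding event's transient.
#' @return data.frame (\code{neuron_id}, \code{classes}, \code{n_classes},
#'   \code{label}) with the logical membership matrix in
#'   \code{attr(, "membership")}.
#' @export
classifySelectivity <- function(ne, classes = NULL, k_sd = 2,
                                baseline_window = 4L, baseline_pre = NULL) {
  log <- stimulusLog(ne)
  fs <- samplingRate(ne)
  if (is.null(classes)) classes <- lapply(unique(log$label), .parseLabel)
  .assert(length(classes) > 0, "no conditions to classify against")
  x <- traces(ne)
  w <- windowPresets()$selectivity
  onset_idx <- .onsetIndex(log$onset_time, fs)
  if (is.null(baseline_pre)) {
    baseline_pre <- min(8L, min(onset_idx) - 1L)
  }
  baseline_pre <- as.integer(baseline_pre)
  .assert(baseline_pre >= 3L,
          "need at least 3 pre-onset frames for the baseline")
  labels <- vapply(classes, .classLabel, character(1),
                   universe = attr(log, "universe"))
  member <- matrix(FALSE, nrow(x), length(classes),
                   dimnames = list(rownames(x), labels))
  span <- baseline_pre:(baseline_pre + 4L)       # frame -1 .. +3
  base_cols <- seq_len(baseline_pre - 1L)
  for (j in seq_along(classes)) {
    tens <- extractTrials(x, classes[[j]], baseline_pre, w[["after"]],
                          log = log, sampling_rate = fs)
    avg <- zscore(trialAverage(tens))
    amp <- rowMeans(avg[, span, drop = FALSE])
    for (i in seq_len(nrow(x))) {
      base <- avg[i, base_cols]
      filt <- medianFilterBaseline(base, baseline_window)
      # median-filtered segment sets the baseline level; the unfiltered
      # samples set the noise scale (filtering would understate it)
      member[i, j] <- amp[i] > mean(filt) + k_sd * sd(base)
    }
  }
  n_cls <- rowSums(member)
  out <- data.frame(
    neuron_id = rownames(x),
    classes = apply(member, 1, function(m) paste(labels[m], collapse = ";")),
    n_classes = n_cls,
    label = ifelse(n_cls == 0, "nonresponsive",
                   ifelse(n_cls == 1, "single", "mixed")),
    stringsAsFactors = FALSE)
  attr(out, "membership") <- member
  out
}

#' Conditional probability of joint selectivity
#'
#' Entry (A, B) is the probability that a neuron responsive to condition A
#' is also responsive to condition B: |A and B| / |A|. The diagonal is 1
#' and rows are undefined (NA) for conditions with no responsive neurons.
#' Rows do not generally sum to 1; this is not a transition matrix.
#'
#' @param membership logical neurons x conditions matrix (e.g.
#'   \code{attr(classifySelectivity(...), "membership")} or
#'   \code{\link{responsiveMatrix}} output), or the data.frame returned by
#'   \code{\link{classifySelectivity}}.
#' @return conditions x conditions numeric matrix P(B | A).
#' @export
conditionalProbabilityMatrix <- function(membership) {
  if (is.data.frame(membership))
    membership <- attr(membership, "membership")
  .assert(is.matrix(membership) && is.logical(membership),
          "membership must be a logical matrix")
  m <- membership * 1
  joint <- crossprod(m)           # |A and B|
  nA <- diag(joint)
  p <- joint / nA                 # rows indexed by A
  p[nA == 0, ] <- NA_real_
  diag(p)[nA > 0] <- 1
  p
}
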
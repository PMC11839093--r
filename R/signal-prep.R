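# Shared deterministic signal transforms: regressors, normalization,
# baselines, peri-stimulus windowing.

#' Peri-stimulus window presets
#'
#' Two distinct windows are used downstream and deliberately kept separate:
#' the selectivity window (one frame before the onset to three frames
#' after) and the binarization window (the four post-onset-inclusive
#' frames, spanning 1.8 s at 2.18 volumes/s).
#' @return named list of \code{c(before, after)} frame counts.
#' @export
windowPresets <- function() {
  list(selectivity = c(before = 1L, after = 3L),
       binarization = c(before = 0L, after = 3L))
}

#' Build a stimulus regressor for one condition
#'
#' A binary impulse train -- 1 at the onset frame of every event whose
#' identity set equals \code{class_set}, 0 elsewhere -- convolved with the
#' peak-normalized double-exponential indicator kernel and truncated to the
#' trace length.
#'
#' @param log stimulus log.
#' @param class_set identity set (character vector) to encode.
#' @param sampling_rate frames per second.
#' @param kernel \code{\link{kernelParams}}.
#' @param n_frames regressor length; defaults to
#'   \code{ceiling(recording_length * sampling_rate)}.
#' @return numeric vector of length \code{n_frames} with attribute
#'   \code{class_set}.
#' @export
makeRegressor <- function(log, class_set, sampling_rate = 2.18,
                          kernel = kernelParams(), n_frames = NULL) {
  ev <- .matchEvents(log, class_set)
  .assert(length(ev) > 0, "no events in the log match class set {",
          paste(class_set, collapse = ", "), "}")
  if (is.null(n_frames)) {
    len <- attr(log, "recording_length")
    .assert(!is.null(len), "log lacks recording_length; supply n_frames")
    n_frames <- as.integer(ceiling(len * sampling_rate))
  }
  impulse <- numeric(n_frames)
  idx <- .onsetIndex(log$onset_time[ev], sampling_rate)
  .assert(all(idx <= n_frames), "event onset beyond the regressor length")
  impulse[idx] <- impulse[idx] + 1
  kv <- calciumKernel(kernel, sampling_rate)
  reg <- convolve(impulse, rev(kv), type = "open")[seq_len(n_frames)]
  reg[reg < 0] <- 0   # clip numerical fuzz from the FFT convolution
  attr(reg, "class_set") <- class_set
  reg
}

#' Min-max normalization to [0, 1]
#'
#' \code{(x - min) / (max - min)} per trace. Constant traces (dead ROIs)
#' are returned as all-zeros and flagged in the \code{"constant"} attribute
#' with a warning, rather than raising; downstream correlation treats
#' flagged traces as non-responsive.
#'
#' @param x numeric vector, or a matrix normalized row-wise.
#' @return object of the same shape with attribute \code{"constant"}
#'   (logical, per trace).
#' @examples
#' minmaxNormalize(c(2, 4, 6))   # 0, 0.5, 1
#' @export
minmaxNormalize <- function(x) {
  if (is.matrix(x)) {
    lo <- apply(x, 1, min)
    hi <- apply(x, 1, max)
    rng <- hi - lo
    constant <- rng <= 0
    rng[constant] <- 1
    out <- (x - lo) / rng
    out[constant, ] <- 0
  } else {
    rng <- max(x) - min(x)
    constant <- rng <= 0
    out <- if (constant) rep(0, length(x)) else (x - min(x)) / rng
  }
  if (any(constant))
    warning(sum(constant), " constant trace(s) returned as all-zeros")
  attr(out, "constant") <- unname(constant)
  out
}

#' Running-median baseline
#'
#' Running median with a (possibly even) window; the window is centered,
#' placing the extra frame after the current one for even widths, and
#' shrinks at the boundaries.
#'
#' @param x numeric vector.
#' @param window window width in frames (default 4).
#' @return numeric vector of the same length.
#' @export
medianFilterBaseline <- function(x, window = 4L) {
  window <- as.integer(window)
  .assert(window >= 1L, "window must be >= 1")
  if (window == 1L) return(x)
  n <- length(x)
  lo <- (window - 1L) %/% 2L
  hi <- window - 1L - lo
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - lo):min(n, i + hi)])
  }, numeric(1))
}

#' Extract peri-stimulus trial windows
#'
#' Cuts one aligned window per event of the requested condition, preserving
#' trial order from the log.
#'
#' @param x a \linkS4class{NeuromastExperiment} or a neurons x frames
#'   matrix (then \code{log} and \code{sampling_rate} are required).
#' @param log stimulus log (taken from \code{x} when omitted).
#' @param class_set identity set selecting the trials.
#' @param frames_before,frames_after window extent around the onset frame.
#' @param sampling_rate frames per second (matrix input only).
#' @return a neurons x trials x window array (\code{TrialTensor}) with
#'   attributes \code{window}, \code{class_set} and \code{onsets}.
#' @export
extractTrials <- function(x, class_set, frames_before, frames_after,
                          log = NULL, sampling_rate = NULL) {
  if (is(x, "NeuromastExperiment")) {
    log <- log %||% stimulusLog(x)
    sampling_rate <- sampling_rate %||% samplingRate(x)
    x <- traces(x)
  }
  .assert(!is.null(log) && !is.null(sampling_rate),
          "log and sampling_rate are required with matrix input")
  frames_before <- as.integer(frames_before)
  frames_after <- as.integer(frames_after)
  .assert(frames_before >= 0 && frames_after >= 0,
          "window extents must be nonnegative")
  ev <- .matchEvents(log, class_set)
  .assert(length(ev) > 0, "class set {", paste(class_set, collapse = ", "),
          "} has no trials in the log")
  idx <- .onsetIndex(log$onset_time[ev], sampling_rate)
  w <- frames_before + frames_after + 1L
  for (k in seq_along(ev)) {
    if (idx[k] - frames_before < 1L || idx[k] + frames_after > ncol(x))
      stop(sprintf(
        "trial window for event %d (t = %.2f s, %s) falls outside the recording",
        ev[k], log$onset_time[ev[k]], log$label[ev[k]]), call. = FALSE)
  }
  out <- array(NA_real_, c(nrow(x), length(ev), w),
               dimnames = list(rownames(x), NULL, NULL))
  for (k in seq_along(ev)) {
    out[, k, ] <- x[, (idx[k] - frames_before):(idx[k] + frames_after)]
  }
  attr(out, "window") <- c(before = frames_before, after = frames_after)
  attr(out, "class_set") <- class_set
  attr(out, "onsets") <- log$onset_time[ev]
  out
}

#' Trial-average a TrialTensor
#'
#' @param tensor array from \code{\link{extractTrials}}.
#' @return neurons x window matrix of across-trial means.
#' @export
trialAverage <- function(tensor) {
  .assert(length(dim(tensor)) == 3, "expected a neurons x trials x frames array")
  out <- apply(tensor, c(1, 3), mean)
  attr(out, "window") <- attr(tensor, "window")
  out
}

#' Z-score a vector or the rows of a matrix
#' @param x numeric vector or matrix (row-wise).
#' @return same shape; constant rows become all zeros.
#' @export
zscore <- function(x) {
  if (is.matrix(x)) {
    mu <- rowMeans(x)
    s <- apply(x, 1, sd)
    s[s <= 0] <- 1
    (x - mu) / s
  } else {
    s <- sd(x)
    if (s <= 0) rep(0, length(x)) else (x - mean(x)) / s
  }
}
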
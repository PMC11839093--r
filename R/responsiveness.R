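# Responsiveness detection: regressor correlation against a shuffled-
# stimulus null distribution.

#' Correlate traces with a stimulus regressor
#'
#' Pearson correlation between every (min-max normalized) trace and the
#' condition regressor; optionally squared. Constant (flagged) traces get
#' the minimum of the statistic's range and are excluded from null fitting
#' by \code{\link{fitNull}}.
#'
#' @param x neurons x frames matrix, min-max normalized (a
#'   \linkS4class{NeuromastExperiment} is normalized internally).
#' @param regressor vector from \code{\link{makeRegressor}}.
#' @param statistic \code{"r"} (default) or \code{"r_squared"}.
#' @return numeric vector, one statistic per neuron.
#' @export
correlateWithRegressor <- function(x, regressor,
                                   statistic = c("r", "r_squared")) {
  statistic <- match.arg(statistic)
  if (is(x, "NeuromastExperiment"))
    x <- suppressWarnings(minmaxNormalize(traces(x)))
  .assert(ncol(x) == length(regressor),
          "trace length (", ncol(x), ") and regressor length (",
          length(regressor), ") differ")
  sc <- .scaleRows(x)
  r <- .rowCor(sc$scaled, sc$constant, regressor)
  out <- if (statistic == "r_squared") r^2 else r
  floor_val <- if (statistic == "r_squared") 0 else -1
  out[sc$constant] <- floor_val
  attr(out, "constant") <- sc$constant
  attr(out, "statistic") <- statistic
  out
}

#' Fit the shuffled-stimulus null distribution for one condition
#'
#' Surrogate stimulus trains are built by drawing, uniformly without
#' replacement, as many onset frames as the condition has real events, over
#' frames that keep the full kernel inside the recording. Each surrogate
#' train is convolved with the kernel and correlated with every neuron;
#' the pooled statistics over all shuffles and neurons are summarized by
#' their sample mean and standard deviation (normal fit).
#'
#' @param x a \linkS4class{NeuromastExperiment} or a neurons x frames
#'   matrix of min-max normalized traces.
#' @param class_set condition whose event count sets the surrogate count.
#' @param log,sampling_rate required with matrix input.
#' @param kernel \code{\link{kernelParams}}.
#' @param n_shuffles number of surrogate trains (default 500).
#' @param statistic \code{"r"} or \code{"r_squared"}.
#' @param seed integer seed or \code{NULL}.
#' @return an object of class \code{"NullModel"}: list with \code{mean},
#'   \code{sd}, \code{n_shuffles}, \code{statistic}.
#' @export
fitNull <- function(x, class_set, log = NULL, sampling_rate = NULL,
                    kernel = kernelParams(), n_shuffles = 500,
                    statistic = c("r", "r_squared"), seed = NULL) {
  statistic <- match.arg(statistic)
  .assert(n_shuffles >= 2, "n_shuffles must be >= 2")
  if (is(x, "NeuromastExperiment")) {
    log <- log %||% stimulusLog(x)
    sampling_rate <- sampling_rate %||% samplingRate(x)
    x <- suppressWarnings(minmaxNormalize(traces(x)))
  }
  .assert(!is.null(log) && !is.null(sampling_rate),
          "log and sampling_rate are required with matrix input")
  n_ev <- length(.matchEvents(log, class_set))
  .assert(n_ev > 0, "class set has no events in the log")
  n_frames <- ncol(x)
  kv <- calciumKernel(kernel, sampling_rate)
  valid <- n_frames - length(kv) + 1L
  .assert(valid >= n_ev,
          "too few valid frames (", valid, ") to place ", n_ev,
          " surrogate events")
  sc <- .scaleRows(x)
  keep <- !sc$constant
  .assert(any(keep), "all traces are constant; cannot fit a null")
  vals <- .withSeed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(s) {
      onsets <- sample.int(valid, n_ev)
      impulse <- numeric(n_frames)
      impulse[onsets] <- 1
      reg <- convolve(impulse, rev(kv), type = "open")[seq_len(n_frames)]
      r <- .rowCor(sc$scaled[keep, , drop = FALSE],
                   rep(FALSE, sum(keep)), reg)
      if (statistic == "r_squared") r^2 else r
    }))
  })
  structure(list(mean = mean(vals), sd = sd(vals),
                 n_shuffles = as.integer(n_shuffles), statistic = statistic),
            class = "NullModel")
}

#' @export
print.NullModel <- function(x, ...) {
  cat(sprintf("NullModel (%s, %d shuffles): mean = %.4f, sd = %.4f\n",
              x$statistic, x$n_shuffles, x$mean, x$sd))
  invisible(x)
}

#' Threshold statistics against a null model
#'
#' A neuron is responsive when its statistic is at least
#' \code{k_sd} null standard deviations above the null mean (boundary
#' inclusive).
#'
#' @param stats per-neuron statistic vector.
#' @param null a \code{"NullModel"}.
#' @param k_sd threshold in null standard deviations (default 2.5).
#' @return data.frame with \code{statistic}, \code{threshold},
#'   \code{responsive}.
#' @export
detectResponsive <- function(stats, null, k_sd = 2.5) {
  .assert(inherits(null, "NullModel"), "null must come from fitNull()")
  .assert(all(is.finite(stats)), "statistics must be finite")
  if (null$sd == 0)
    warning("degenerate null (sd = 0); thresholding at the null mean")
  threshold <- null$mean + k_sd * null$sd
  data.frame(statistic = as.numeric(stats),
             threshold = threshold,
             responsive = as.numeric(stats) >= threshold)
}

#' Detect responsive neurons for every condition of an experiment
#'
#' Convenience wrapper running \code{\link{correlateWithRegressor}},
#' \code{\link{fitNull}} and \code{\link{detectResponsive}} per condition.
#'
#' @param ne a \linkS4class{NeuromastExperiment}.
#' @param classes list of identity sets; defaults to every distinct
#'   condition in the stimulus log.
#' @param statistic \code{"r"} (default) or \code{"r_squared"}.
#' @param n_shuffles,k_sd,kernel see \code{\link{fitNull}} and
#'   \code{\link{detectResponsive}}.
#' @param seed integer seed for the shuffles.
#' @return long data.frame: \code{neuron_id}, \code{class},
#'   \code{statistic}, \code{null_mean}, \code{null_sd}, \code{threshold},
#'   \code{responsive}.
#' @export
detectResponsiveNeurons <- function(ne, classes = NULL,
                                    statistic = c("r", "r_squared"),
                                    n_shuffles = 500, k_sd = 2.5,
                                    kernel = kernelParams(), seed = NULL) {
  statistic <- match.arg(statistic)
  log <- stimulusLog(ne)
  fs <- samplingRate(ne)
  if (is.null(classes))
    classes <- lapply(unique(log$label), .parseLabel)
  x <- suppressWarnings(minmaxNormalize(traces(ne)))
  ids <- rownames(traces(ne))
  seeds <- if (is.null(seed)) vector("list", length(classes)) else
    as.list(seed + seq_along(classes) - 1L)
  out <- lapply(seq_along(classes), function(i) {
    cs <- classes[[i]]
    reg <- makeRegressor(log, cs, fs, kernel, n_frames = ncol(x))
    st <- correlateWithRegressor(x, reg, statistic)
    null <- fitNull(x, cs, log = log, sampling_rate = fs, kernel = kernel,
                    n_shuffles = n_shuffles, statistic = statistic,
                    seed = seeds[[i]])
    det <- detectResponsive(st, null, k_sd)
    data.frame(neuron_id = ids,
               class = .classLabel(cs, attr(log, "universe")),
               statistic = det$statistic,
               null_mean = null$mean, null_sd = null$sd,
               threshold = det$threshold, responsive = det$responsive,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Responsive-set membership matrix from detection results
#'
#' @param result data.frame from \code{\link{detectResponsiveNeurons}}.
#' @return logical neurons x conditions matrix.
#' @export
responsiveMatrix <- function(result) {
  ids <- unique(result$neuron_id)
  cls <- unique(result$class)
  m <- matrix(FALSE, length(ids), length(cls), dimnames = list(ids, cls))
  m[cbind(match(result$neuron_id, ids), match(result$class, cls))] <-
    result$responsive
  m
}
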
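# Trial-averaged neural trajectories in principal-component space.

#' Trial-averaged PC-space trajectories
#'
#' Trial-averaged peri-stimulus windows (default 4 s before and after the
#' onset) for every condition are concatenated along the time axis into a
#' neurons x (conditions * window) matrix, z-scored per neuron and
#' decomposed by SVD. Condition trajectories are the projections of each
#' within-condition time course onto the retained components. The leading
#' component typically carries the stimulus-unspecific global transient and
#' is excluded by default: components 2-4 (1-based) are returned, smoothed
#' with a Gaussian kernel of one frame for visualization.
#'
#' @param ne a \linkS4class{NeuromastExperiment}.
#' @param classes list of identity sets; defaults to all log conditions.
#' @param window_s peri-stimulus half-window in seconds (default 4).
#' @param components 1-based component indices to keep (default 2:4).
#' @param smooth_sigma Gaussian smoothing sigma in frames (default 1; 0
#'   disables).
#' @param neurons optional row subset (indices or logical) restricting the
#'   population.
#' @return list of class \code{"TrajectoryProjection"}: \code{trajectories}
#'   (long data.frame: stimulus, time_s, component, score),
#'   \code{variance_explained} (per component, all components), and
#'   \code{components}.
#' @export
pcaTrajectories <- function(ne, classes = NULL, window_s = 4,
                            components = 2:4, smooth_sigma = 1,
                            neurons = NULL) {
  log <- stimulusLog(ne)
  fs <- samplingRate(ne)
  if (is.null(classes)) classes <- lapply(unique(log$label), .parseLabel)
  labels <- vapply(classes, .classLabel, character(1),
                   universe = attr(log, "universe"))
  x <- traces(ne)
  if (!is.null(neurons)) x <- x[neurons, , drop = FALSE]
  .assert(nrow(x) >= 4, "need at least 4 neurons for the decomposition")
  half <- as.integer(round(window_s * fs))
  avg <- lapply(classes, function(cs) {
    trialAverage(extractTrials(x, cs, half, half, log = log,
                               sampling_rate = fs))
  })
  w <- ncol(avg[[1]])
  concat <- do.call(cbind, avg)
  z <- zscore(concat)
  dec <- svd(z)
  var_frac <- dec$d^2 / sum(dec$d^2)
  .assert(max(components) <= length(dec$d),
          "requested components exceed the decomposition rank")
  kern <- .gaussKernel(smooth_sigma)
  scores <- t(dec$u[, components, drop = FALSE]) %*% z  # comps x (S*w)
  time_s <- (seq_len(w) - half - 1) / fs
  traj <- do.call(rbind, lapply(seq_along(labels), function(s) {
    block <- scores[, (s - 1) * w + seq_len(w), drop = FALSE]
    do.call(rbind, lapply(seq_along(components), function(k) {
      data.frame(stimulus = labels[s], time_s = time_s,
                 component = components[k],
                 score = .smooth1d(block[k, ], kern),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(trajectories = traj,
                 variance_explained = var_frac,
                 components = components,
                 zscored = z, svd = dec),
            class = "TrajectoryProjection")
}

#' @export
print.TrajectoryProjection <- function(x, ...) {
  vf <- x$variance_explained[x$components]
  cat("TrajectoryProjection:", length(unique(x$trajectories$stimulus)),
      "stimuli, components", paste(x$components, collapse = ","),
      sprintf("(%.0f%%, %.0f%%, %.0f%% variance)\n", 100 * vf[1],
              100 * vf[2], 100 * vf[3]))
  invisible(x)
}
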
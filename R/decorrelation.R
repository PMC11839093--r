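# Region-wise pattern decorrelation of condition-mean population vectors.

#' Condition-mean amplitude matrix
#'
#' Per neuron and condition, the mean amplitude over the four
#' post-onset-inclusive frames (the 1.8 s stimulus window) of the
#' trial-averaged trace. The window statistic is the mean as stated for
#' this analysis; the response peak is used elsewhere (binarization).
#'
#' @param ne a \linkS4class{NeuromastExperiment}.
#' @param classes list of identity sets; defaults to all log conditions.
#' @param window frames from the onset (default 4).
#' @param statistic \code{"mean"} (default) or \code{"peak"}.
#' @return neurons x conditions numeric matrix.
#' @export
conditionAmplitudes <- function(ne, classes = NULL, window = 4L,
                                statistic = c("mean", "peak")) {
  statistic <- match.arg(statistic)
  log <- stimulusLog(ne)
  fs <- samplingRate(ne)
  if (is.null(classes)) classes <- lapply(unique(log$label), .parseLabel)
  labels <- vapply(classes, .classLabel, character(1),
                   universe = attr(log, "universe"))
  x <- traces(ne)
  out <- vapply(classes, function(cs) {
    avg <- trialAverage(extractTrials(x, cs, 0L, window - 1L, log = log,
                                      sampling_rate = fs))
    if (statistic == "mean") rowMeans(avg) else apply(avg, 1, max)
  }, numeric(nrow(x)))
  dimnames(out) <- list(rownames(x), labels)
  out
}

#' Region-wise stimulus-pair correlation matrices
#'
#' Within each region, the Pearson correlation between condition-mean
#' population vectors is computed for every pair of stimulus conditions.
#' Low off-diagonal correlations mean the region responds to different
#' conditions with different ensembles (pattern separation); values near 1
#' mean a shared activity profile rescaled across conditions.
#'
#' @param ne a \linkS4class{NeuromastExperiment}.
#' @param classes list of identity sets; defaults to all log conditions.
#' @param neurons optional subset (indices/logical) restricting the
#'   population, e.g. the responsive union.
#' @param min_neurons regions with fewer neurons are marked undefined
#'   (default 3).
#' @param amplitudes optional precomputed \code{\link{conditionAmplitudes}}
#'   matrix.
#' @return list of class \code{"RegionCorrelation"}: \code{matrices}
#'   (named list, \code{NULL} for undefined regions),
#'   \code{decorrelation_index} (mean off-diagonal correlation per
#'   region), \code{n_neurons}.
#' @export
regionCorrelationMatrix <- function(ne, classes = NULL, neurons = NULL,
                                    min_neurons = 3, amplitudes = NULL) {
  A <- amplitudes %||% conditionAmplitudes(ne, classes)
  region <- as.character(rowData(ne)$region)
  if (!is.null(neurons)) {
    A <- A[neurons, , drop = FALSE]
    region <- region[if (is.logical(neurons)) which(neurons) else neurons]
  }
  .assert(ncol(A) >= 2, "need at least two stimulus conditions")
  regions <- unique(region)
  mats <- setNames(vector("list", length(regions)), regions)
  idx <- setNames(rep(NA_real_, length(regions)), regions)
  nn <- setNames(integer(length(regions)), regions)
  for (r in regions) {
    rows <- which(region == r)
    nn[r] <- length(rows)
    if (length(rows) < min_neurons) next
    m <- suppressWarnings(cor(A[rows, , drop = FALSE]))
    diag(m) <- 1
    mats[[r]] <- m
    off <- m[upper.tri(m)]
    idx[r] <- mean(off, na.rm = TRUE)
  }
  structure(list(matrices = mats, decorrelation_index = idx,
                 n_neurons = nn),
            class = "RegionCorrelation")
}

#' Subsampled region correlation matrices
#'
#' Controls for unequal region sizes by repeatedly subsampling a fixed
#' number of neurons per region and averaging the resulting correlation
#' matrices. Regions below the subsample size are excluded by default (or
#' sampled with replacement when \code{replace = TRUE}).
#'
#' @param ne a \linkS4class{NeuromastExperiment}.
#' @param classes list of identity sets; defaults to all log conditions.
#' @param n_subsample neurons drawn per region per iteration (default 200).
#' @param n_iter iterations (default 1000).
#' @param neurons optional subset restricting the population first.
#' @param replace sample with replacement, admitting regions smaller than
#'   \code{n_subsample}.
#' @param seed integer seed.
#' @param amplitudes optional precomputed amplitude matrix.
#' @return list of class \code{"RegionCorrelation"} with iteration-averaged
#'   matrices, \code{decorrelation_index} and \code{n_neurons}.
#' @export
subsampledRegionCorrelation <- function(ne, classes = NULL,
                                        n_subsample = 200, n_iter = 1000,
                                        neurons = NULL, replace = FALSE,
                                        seed = NULL, amplitudes = NULL) {
  A <- amplitudes %||% conditionAmplitudes(ne, classes)
  region <- as.character(rowData(ne)$region)
  if (!is.null(neurons)) {
    A <- A[neurons, , drop = FALSE]
    region <- region[if (is.logical(neurons)) which(neurons) else neurons]
  }
  regions <- unique(region)
  eligible <- vapply(regions, function(r)
    sum(region == r) >= n_subsample || replace, logical(1))
  .assert(any(eligible), "no region meets the subsample size gate")
  if (any(!eligible))
    message("excluding regions below the subsample gate: ",
            paste(regions[!eligible], collapse = ", "))
  regions <- regions[eligible]
  mats <- setNames(vector("list", length(regions)), regions)
  idx <- setNames(rep(NA_real_, length(regions)), regions)
  nn <- setNames(integer(length(regions)), regions)
  .withSeed(seed, {
    for (r in regions) {
      rows <- which(region == r)
      nn[r] <- length(rows)
      acc <- matrix(0, ncol(A), ncol(A))
      for (it in seq_len(n_iter)) {
        sub <- sample(rows, n_subsample, replace = replace)
        m <- suppressWarnings(cor(A[sub, , drop = FALSE]))
        m[is.na(m)] <- 0
        acc <- acc + m
      }
      m <- acc / n_iter
      dimnames(m) <- list(colnames(A), colnames(A))
      diag(m) <- 1
      mats[[r]] <- m
      idx[r] <- mean(m[upper.tri(m)])
    }
  })
  structure(list(matrices = mats, decorrelation_index = idx,
                 n_neurons = nn),
            class = "RegionCorrelation")
}

#' @export
print.RegionCorrelation <- function(x, ...) {
  cat("RegionCorrelation over", length(x$matrices), "regions\n")
  for (r in names(x$decorrelation_index)) {
    cat(sprintf("  %-17s n = %4d  mean off-diagonal r = %s\n", r,
                x$n_neurons[r],
                if (is.na(x$decorrelation_index[r])) "undefined" else
                  sprintf("%.3f", x$decorrelation_index[r])))
  }
  invisible(x)
}

#' Compare decorrelation between two regions across samples
#'
#' Paired test of the decorrelation index (mean off-diagonal correlation)
#' between two regions over a list of per-sample results.
#'
#' @param results list of \code{"RegionCorrelation"} objects (one per
#'   sample or seed).
#' @param region_a,region_b region labels.
#' @param test \code{"wilcoxon"} (paired signed-rank, default) or
#'   \code{"t"} (paired t-test).
#' @param alternative passed to the test; default \code{"less"} tests
#'   whether \code{region_a} is more decorrelated (lower index) than
#'   \code{region_b}.
#' @return htest object.
#' @export
compareDecorrelation <- function(results, region_a, region_b,
                                 test = c("wilcoxon", "t"),
                                 alternative = "less") {
  test <- match.arg(test)
  a <- vapply(results, function(r) r$decorrelation_index[region_a],
              numeric(1))
  b <- vapply(results, function(r) r$decorrelation_index[region_b],
              numeric(1))
  ok <- is.finite(a) & is.finite(b)
  .assert(sum(ok) >= 2, "need at least two samples with both regions defined")
  if (test == "wilcoxon")
    wilcox.test(a[ok], b[ok], paired = TRUE, alternative = alternative)
  else
    t.test(a[ok], b[ok], paired = TRUE, alternative = alternative)
}
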
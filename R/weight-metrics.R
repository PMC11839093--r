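# Sparseness and overlap analyses of decoder weights.

#' Hoyer sparseness of a weight vector
#'
#' \deqn{S(v) = \frac{\sqrt{n} - \|v\|_1 / \|v\|_2}{\sqrt{n} - 1}}
#' computed on magnitudes, so the sign of a weight does not matter. The
#' index is scale-invariant and lies in [0, 1]: exactly 1 when a single
#' entry is nonzero (one neuron carries all the information) and exactly 0
#' when all entries are equal (equal participation).
#'
#' @param v numeric vector, length >= 2, not all zero.
#' @return scalar in [0, 1]; \code{NA} for an all-zero vector.
#' @examples
#' hoyerSparseness(c(0, 0, 3, 0))        # 1
#' hoyerSparseness(rep(0.5, 8))          # 0
#' hoyerSparseness(c(3, 1, 0, 0))        # (2 - 4/sqrt(10)) / 1
#' @export
hoyerSparseness <- function(v) {
  .assert(length(v) >= 2, "sparseness needs a vector of length >= 2")
  v <- abs(v)
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) return(NA_real_)
  n <- length(v)
  (sqrt(n) - sum(v) / l2) / (sqrt(n) - 1)
}

#' Population and lifetime sparseness of a weight matrix
#'
#' Population sparseness scores each class row over the neuron axis;
#' lifetime sparseness scores each neuron column over the class axis,
#' computed only for neurons with at least one nonzero weight (all-zero
#' rows or columns give \code{NA} and are excluded from summaries).
#'
#' @param W classes x neurons weight matrix (e.g.
#'   \code{weightMatrix(trainDecoder(...))}).
#' @return named numeric vector.
#' @export
populationSparseness <- function(W) {
  .assert(is.matrix(W) && nrow(W) >= 1, "W must be a classes x neurons matrix")
  apply(W, 1, hoyerSparseness)
}

#' @rdname populationSparseness
#' @export
lifetimeSparseness <- function(W) {
  .assert(is.matrix(W) && nrow(W) >= 2,
          "lifetime sparseness needs >= 2 classes")
  out <- apply(W, 2, hoyerSparseness)
  out
}

#' Jaccard dissimilarity between class weight-support sets
#'
#' For every pair of classes, takes the index sets of nonzero weights
#' (under the relative zero threshold) and reports
#' \code{1 - |intersection| / |union|}: 1 for disjoint supports, 0 for
#' identical supports.
#'
#' @param W classes x neurons weight matrix.
#' @param zero_tol relative magnitude below which a weight counts as zero.
#' @return symmetric classes x classes matrix with zero diagonal; pairs of
#'   empty supports give \code{NA}.
#' @export
jaccardDissimilarity <- function(W, zero_tol = 1e-8) {
  .assert(is.matrix(W) && nrow(W) >= 2, "need >= 2 classes")
  scale <- max(abs(W))
  nz <- abs(W) > zero_tol * if (scale > 0) scale else 1
  k <- nrow(W)
  out <- matrix(0, k, k, dimnames = list(rownames(W), rownames(W)))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      uni <- sum(nz[a, ] | nz[b, ])
      out[a, b] <- out[b, a] <- if (uni == 0) NA_real_ else
        1 - sum(nz[a, ] & nz[b, ]) / uni
    }
  }
  out
}

#' Locate high-weight neurons anatomically
#'
#' Selects neurons whose weight in any class exceeds that class's mean by
#' more than \code{k_sd} standard deviations, joins them to the ROI table
#' and tallies them per region.
#'
#' @param W classes x neurons weight matrix.
#' @param roi ROI table (data.frame with \code{x_um}, \code{y_um},
#'   \code{z_um}, \code{region}), one row per neuron in weight-column
#'   order.
#' @param k_sd selection threshold (default 3).
#' @return list with \code{table} (selected neurons with coordinates,
#'   region and triggering classes) and \code{region_counts}.
#' @export
highWeightNeurons <- function(W, roi, k_sd = 3) {
  .assert(ncol(W) == nrow(roi), "weight columns and ROI rows must match")
  mu <- rowMeans(W)
  sdv <- apply(W, 1, sd)
  hits <- W > mu + k_sd * sdv     # classes x neurons
  sel <- which(colSums(hits) > 0)
  cls <- vapply(sel, function(j) {
    paste(rownames(W)[hits[, j]], collapse = ";")
  }, character(1))
  tab <- data.frame(
    neuron = sel,
    neuron_id = if (!is.null(colnames(W))) colnames(W)[sel] else
      as.character(sel),
    roi[sel, c("x_um", "y_um", "z_um", "region"), drop = FALSE],
    classes = cls, row.names = NULL, stringsAsFactors = FALSE)
  counts <- table(factor(tab$region, levels = unique(roi$region)))
  list(table = tab, region_counts = counts)
}
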
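# Spatial statistics: 1-D KDE, pairwise KLD between ROI point clouds,
# cluster homogeneity curves.

#' One-dimensional kernel density estimate of ROI positions
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth by default,
#' evaluated on a regular grid.
#'
#' @param coords numeric vector (a projection of ROI coordinates onto one
#'   axis, um).
#' @param bandwidth bandwidth in um, or \code{NULL} for Silverman.
#' @param n grid size.
#' @return data.frame with columns \code{x} and \code{density}; the
#'   trapezoidal integral over the grid is 1 up to grid truncation.
#' @export
kde1d <- function(coords, bandwidth = NULL, n = 512) {
  .assert(length(coords) >= 2, "KDE needs at least 2 points")
  d <- density(coords, bw = bandwidth %||% "nrd0", n = n)
  data.frame(x = d$x, density = d$y)
}

# log KDE density of points `at` under a diagonal-bandwidth Gaussian KDE
# built from `from`; loo drops the matching sample (leave-one-out)
.kdeLogDensity <- function(at, from, h, loo = FALSE) {
  n <- nrow(from)
  lw <- matrix(0, nrow(at), n)
  for (j in seq_len(ncol(at)))
    lw <- lw + outer(at[, j], from[, j],
                     function(a, b) dnorm(a, b, h[j], log = TRUE))
  if (loo) diag(lw) <- -Inf
  m <- apply(lw, 1, max)
  m + log(rowSums(exp(lw - m))) - log(if (loo) n - 1 else n)
}

.silvermanBW <- function(x, min_bw) {
  d <- ncol(x)
  h <- apply(x, 2, sd) * (4 / ((d + 2) * nrow(x)))^(1 / (d + 4))
  if (any(h <= min_bw)) {
    warning("degenerate point cloud; bandwidth regularized")
    h <- pmax(h, min_bw)
  }
  h
}

# one-directional D(P || Q)
.kldOnce <- function(P, Q, estimator, min_bw) {
  if (estimator == "kde") {
    hp <- .silvermanBW(P, min_bw)
    hq <- .silvermanBW(Q, min_bw)
    mean(.kdeLogDensity(P, P, hp, loo = TRUE) - .kdeLogDensity(P, Q, hq))
  } else {
    nn1 <- function(A, B, self = FALSE) {
      vapply(seq_len(nrow(A)), function(i) {
        dd <- sqrt(colSums((t(B) - A[i, ])^2))
        if (self) dd[i] <- Inf
        max(min(dd), min_bw)
      }, numeric(1))
    }
    d <- ncol(P); n <- nrow(P); m <- nrow(Q)
    r <- nn1(P, P, self = TRUE)
    s <- nn1(P, Q)
    d / n * sum(log(s / r)) + log(m / (n - 1))
  }
}

#' Pairwise symmetrized Kullback-Leibler divergence between point clouds
#'
#' For every pair of identity-labeled 3-D ROI point sets, estimates
#' D(P||Q) and D(Q||P) and reports their mean, so the result is a
#' symmetric matrix with zero diagonal. The default estimator is a
#' Gaussian-KDE plug-in with diagonal Silverman bandwidths and
#' leave-one-out own-density; a 1-nearest-neighbor estimator is available
#' as an alternative. Sets with fewer than \code{min_points} members are
#' dropped (small classes carry too few examples for a stable estimate).
#'
#' @param coord_sets named list of n x 3 coordinate matrices (um).
#' @param min_points minimum set size (default 10).
#' @param estimator \code{"kde"} (default) or \code{"knn"}.
#' @param min_bw bandwidth/distance floor (um) guarding rank-deficient
#'   clouds.
#' @return symmetric matrix of symmetrized divergences (nats); dropped
#'   classes are absent.
#' @export
pairwiseKLD <- function(coord_sets, min_points = 10,
                        estimator = c("kde", "knn"), min_bw = 1e-3) {
  estimator <- match.arg(estimator)
  coord_sets <- lapply(coord_sets, function(m) as.matrix(m)[, 1:3, drop = FALSE])
  sizes <- vapply(coord_sets, nrow, integer(1))
  keep <- sizes >= min_points
  if (any(!keep))
    message("dropping classes with < ", min_points, " points: ",
            paste(names(coord_sets)[!keep], collapse = ", "))
  coord_sets <- coord_sets[keep]
  .assert(length(coord_sets) >= 2, "need at least two sets of sufficient size")
  k <- length(coord_sets)
  out <- matrix(0, k, k, dimnames = list(names(coord_sets), names(coord_sets)))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      v <- mean(c(
        .kldOnce(coord_sets[[a]], coord_sets[[b]], estimator, min_bw),
        .kldOnce(coord_sets[[b]], coord_sets[[a]], estimator, min_bw)))
      out[a, b] <- out[b, a] <- v
    }
  }
  out
}

#' Cluster homogeneity: same-identity probability versus distance
#'
#' For every labeled ROI, its nearest labeled neighbors (up to
#' \code{max_neighbors}) are binned by Euclidean distance; per identity and
#' bin, the raw probability is the fraction of neighbor pairs whose
#' neighbor shares the query's identity, and the normalized probability
#' divides by the identity's overall base rate among labeled ROIs. Under
#' uniformly shuffled labels the normalized curve is about 1 at every
#' radius; spatial same-identity clustering pushes it well above 1 at
#' short range.
#'
#' @param roi data.frame with \code{x_um}, \code{y_um}, \code{z_um}.
#' @param labels character vector, one identity per ROI; \code{NA} marks
#'   unlabeled ROIs (excluded).
#' @param bin_width distance bin width, um (default 5).
#' @param max_radius largest distance considered, um (default 100).
#' @param max_neighbors neighbor cap per query ROI (default 2000; exact
#'   search).
#' @return data.frame: \code{class}, \code{bin_lo}, \code{bin_hi},
#'   \code{raw}, \code{normalized}, \code{n_pairs}; empty bins have
#'   \code{NA} probabilities.
#' @export
clusterHomogeneity <- function(roi, labels, bin_width = 5, max_radius = 100,
                               max_neighbors = 2000) {
  keep <- which(!is.na(labels))
  .assert(length(keep) >= 2, "need at least two labeled neurons")
  xyz <- as.matrix(roi[keep, c("x_um", "y_um", "z_um")])
  lab <- as.character(labels[keep])
  n <- nrow(xyz)
  base_rate <- table(lab) / n
  edges <- seq(0, max_radius, by = bin_width)
  nb <- length(edges) - 1L
  classes <- names(base_rate)
  same <- matrix(0, length(classes), nb, dimnames = list(classes, NULL))
  tot <- matrix(0, length(classes), nb, dimnames = list(classes, NULL))
  txyz <- t(xyz)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((txyz - xyz[i, ])^2))
    d[i] <- Inf
    if (n - 1L > max_neighbors) {
      cut_d <- sort(d, partial = max_neighbors)[max_neighbors]
      sel <- which(d <= cut_d)
    } else sel <- which(is.finite(d))
    bin <- findInterval(d[sel], edges, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb
    if (!any(ok)) next
    bin <- bin[ok]; sel <- sel[ok]
    cls <- lab[i]
    hit <- lab[sel] == cls
    tt <- tabulate(bin, nb)
    ss <- tabulate(bin[hit], nb)
    tot[cls, ] <- tot[cls, ] + tt
    same[cls, ] <- same[cls, ] + ss
  }
  raw <- same / tot
  raw[tot == 0] <- NA_real_
  out <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(class = cl,
               bin_lo = edges[-length(edges)], bin_hi = edges[-1],
               raw = raw[cl, ],
               normalized = raw[cl, ] / as.numeric(base_rate[cl]),
               n_pairs = tot[cl, ],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  single <- names(base_rate)[base_rate * n < 2]
  if (length(single))
    out[out$class %in% single, c("raw", "normalized")] <- NA_real_
  out
}
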
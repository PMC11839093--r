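# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed
#'
#' When \code{seed} is \code{NULL} the expression runs on the current RNG
#' stream; otherwise the RNG state is saved, seeded, and restored afterwards.
#' @noRd
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' @noRd
.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

# canonical "+"-joined label for a set of neuromast identities, ordered by
# their position in the universe (body axis order)
.classLabel <- function(classes, universe) {
  classes <- unique(as.character(classes))
  bad <- setdiff(classes, universe)
  .assert(length(bad) == 0,
          "unknown neuromast identities: ", paste(bad, collapse = ", "))
  paste(classes[order(match(classes, universe))], collapse = "+")
}

# inverse of .classLabel
.parseLabel <- function(label) strsplit(label, "+", fixed = TRUE)[[1]]

# onset frame (1-based index) for an onset time in seconds; frame 0 starts
# at t = 0, onset frame = floor(t * fs)
.onsetIndex <- function(onset_time, sampling_rate) {
  as.integer(floor(onset_time * sampling_rate)) + 1L
}

# row-wise mean/sd scaling used by the correlation machinery; constant rows
# are reported, not scaled
.scaleRows <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- sqrt(rowSums(xc^2))
  constant <- unname(ss <= .Machine$double.eps * ncol(x) * pmax(1, abs(mu)))
  ss[constant] <- 1
  list(scaled = xc / ss, constant = constant)
}

# Pearson correlation of every row of a pre-scaled matrix with a vector
.rowCor <- function(scaled, constant, v) {
  vc <- v - mean(v)
  nv <- sqrt(sum(vc^2))
  .assert(nv > 0, "regressor is constant")
  r <- as.numeric(scaled %*% (vc / nv))
  r[constant] <- NA_real_
  r
}

# discrete Gaussian smoothing kernel (sigma in samples), normalized
.gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

# smooth a vector with a normalized kernel, reflecting at the edges
.smooth1d <- function(x, kernel) {
  if (length(kernel) == 1L) return(x)
  half <- (length(kernel) - 1L) / 2L
  padded <- c(rev(x[seq_len(half)]), x, rev(x)[seq_len(half)])
  as.numeric(stats::filter(padded, kernel, sides = 2))[half + seq_along(x)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
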
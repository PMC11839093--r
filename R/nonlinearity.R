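# Vector-based nonlinear-summation analysis: bounded decomposition of the
# paired response into the plane of the individual responses.

#' Population response vector for one condition
#'
#' Each trace is min-max normalized over the whole recording (guarding
#' against photobleaching and habituation scale differences), trial
#' windows of the condition are averaged, and the per-neuron maximum over
#' the four post-onset-inclusive frames (1.8 s) is taken, yielding one
#' scalar per neuron in [0, 1].
#'
#' @param ne a \linkS4class{NeuromastExperiment}.
#' @param condition identity set of the condition (e.g. \code{c("AP3",
#'   "AP4")} for a pair, \code{"AP3"} for a single).
#' @param window response window in frames (default 4).
#' @return named numeric vector (one entry per neuron) with attribute
#'   \code{condition}.
#' @export
populationResponseVector <- function(ne, condition, window = 4L) {
  x <- suppressWarnings(minmaxNormalize(traces(ne)))
  rownames(x) <- rownames(traces(ne))
  tens <- extractTrials(x, condition, frames_before = 0L,
                        frames_after = window - 1L,
                        log = stimulusLog(ne),
                        sampling_rate = samplingRate(ne))
  avg <- trialAverage(tens)
  out <- apply(avg, 1, max)
  attr(out, "condition") <- .classLabel(condition, neuromastUniverse(ne))
  out
}

# exact bounded 2-D least squares over a box: enumerate the unconstrained
# optimum, the four clamped edges (1-D problems), and the four corners;
# the problem is convex so the best feasible candidate is the optimum
.boundedLSQ <- function(RA, RB, RAB, lower, upper) {
  gaa <- sum(RA^2)
  gbb <- sum(RB^2)
  gab <- sum(RA * RB)
  ca <- sum(RA * RAB)
  cb <- sum(RB * RAB)
  clamp <- function(v) pmin(upper, pmax(lower, v))
  cand <- list()
  det <- gaa * gbb - gab^2
  if (det > 1e-12 * max(gaa * gbb, 1)) {
    cand <- c(cand, list(c((gbb * ca - gab * cb) / det,
                           (gaa * cb - gab * ca) / det)))
  }
  solve1 <- function(gxx, rhs) if (gxx > 0) rhs / gxx else 0
  for (a in c(lower, upper))
    cand <- c(cand, list(c(a, clamp(solve1(gbb, cb - a * gab)))))
  for (b in c(lower, upper))
    cand <- c(cand, list(c(clamp(solve1(gaa, ca - b * gab)), b)))
  for (a in c(lower, upper)) for (b in c(lower, upper))
    cand <- c(cand, list(c(a, b)))
  obj <- vapply(cand, function(p) {
    p <- clamp(p)
    sum((RAB - p[1] * RA - p[2] * RB)^2)
  }, numeric(1))
  clamp(cand[[which.min(obj)]])
}

#' Decompose a paired response into the plane of its components
#'
#' Finds bounded coefficients minimizing
#' \eqn{\|R(A,B) - \alpha R(A,0) - \beta R(0,B)\|_2} over the box (default
#' \eqn{[-1, 1]^2}); the residual is the per-neuron nonlinear component
#' \eqn{R_{NL}(A,B)} and the reconstruction identity
#' \eqn{R(A,B) = \alpha R(A,0) + \beta R(0,B) + R_{NL}} holds exactly.
#' The angle between the paired response and the individual-response plane
#' is \code{asin(||residual|| / ||R(A,B)||)} in degrees: 0 for an exactly
#' linear combination, 90 when the paired response is orthogonal to both
#' components. The convex box problem is solved exactly by active-set
#' enumeration. The unconstrained-projection angle is retained as a
#' diagnostic.
#'
#' @param RA,RB,RAB population response vectors (shared neuron ordering)
#'   for conditions (A,0), (0,B) and (A,B).
#' @param bounds length-2 numeric, the coefficient box (default
#'   \code{c(-1, 1)}).
#' @param pair optional label for the pair.
#' @return a \linkS4class{PairDecomposition}.
#' @examples
#' d <- decomposePair(c(1, 0), c(0, 1), c(0.5, 0.5))
#' coef(d)        # alpha = beta = 0.5
#' planeAngle(d)  # 0
#' @export
decomposePair <- function(RA, RB, RAB, bounds = c(-1, 1), pair = "") {
  .assert(length(RA) == length(RB) && length(RB) == length(RAB),
          "response vectors must share the neuron ordering")
  .assert(sum(RA^2) > 0 || sum(RB^2) > 0,
          "individual responses are both zero")
  RA <- as.numeric(RA)
  RB <- as.numeric(RB)
  RAB <- as.numeric(RAB)
  ab <- .boundedLSQ(RA, RB, RAB, bounds[1], bounds[2])
  residual <- RAB - ab[1] * RA - ab[2] * RB
  nab <- sqrt(sum(RAB^2))
  angle <- if (nab == 0) {
    warning("||R(A,B)|| = 0; angle undefined")
    NA_real_
  } else {
    asin(min(1, sqrt(sum(residual^2)) / nab)) * 180 / pi
  }
  # unconstrained projection residual for the diagnostic angle
  G <- rbind(c(sum(RA^2), sum(RA * RB)), c(sum(RA * RB), sum(RB^2)))
  rhs <- c(sum(RA * RAB), sum(RB * RAB))
  proj <- tryCatch(solve(G, rhs), error = function(e) ab)
  res_u <- RAB - proj[1] * RA - proj[2] * RB
  angle_u <- if (nab == 0) NA_real_ else
    asin(min(1, sqrt(sum(res_u^2)) / nab)) * 180 / pi
  new("PairDecomposition", alpha = ab[1], beta = ab[2],
      residual = residual, angle = angle, unconstrainedAngle = angle_u,
      summaryRNL = mean(residual), pair = as.character(pair))
}

#' Summarize nonlinear summation across pairs or samples
#'
#' Pools decompositions: mean plane angle and mean residual with SEMs,
#' plus per-decomposition supra- and sub-linear neuron sets, thresholded
#' on z-scored residuals by default (the residual distribution's own scale;
#' set \code{scale = "raw"} to threshold the raw residual units).
#'
#' @param decompositions list of \linkS4class{PairDecomposition}.
#' @param threshold residual threshold for supra/sub classification
#'   (default 2).
#' @param scale \code{"z"} (default) or \code{"raw"}.
#' @param responses optional named list of population response vectors
#'   (names are condition labels); when given, mean response amplitudes of
#'   the supra and sub sets are reported per condition.
#' @return list with \code{mean_angle}, \code{sem_angle},
#'   \code{mean_RNL}, \code{sem_RNL}, \code{supra}, \code{sub} (lists of
#'   neuron indices) and optionally \code{amplitudes}.
#' @export
nonlinearitySummary <- function(decompositions, threshold = 2,
                                scale = c("z", "raw"), responses = NULL) {
  scale <- match.arg(scale)
  .assert(length(decompositions) >= 1, "need at least one decomposition")
  angles <- vapply(decompositions, planeAngle, numeric(1))
  rnl <- vapply(decompositions, function(d) d@summaryRNL, numeric(1))
  sets <- lapply(decompositions, function(d) {
    r <- nonlinearResidual(d)
    rs <- if (scale == "z") zscore(r) else r
    list(supra = which(rs > threshold), sub = which(rs < -threshold))
  })
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  out <- list(
    mean_angle = mean(angles), sem_angle = sem(angles),
    mean_RNL = mean(rnl), sem_RNL = sem(rnl),
    supra = lapply(sets, `[[`, "supra"),
    sub = lapply(sets, `[[`, "sub"))
  if (!is.null(responses)) {
    amp <- do.call(rbind, lapply(names(responses), function(cond) {
      v <- responses[[cond]]
      do.call(rbind, lapply(seq_along(sets), function(i) {
        data.frame(
          pair = decompositions[[i]]@pair, condition = cond,
          set = c("supra", "sub"),
          mean_amplitude = c(
            if (length(sets[[i]]$supra)) mean(v[sets[[i]]$supra]) else NA_real_,
            if (length(sets[[i]]$sub)) mean(v[sets[[i]]$sub]) else NA_real_),
          stringsAsFactors = FALSE)
      }))
    }))
    out$amplitudes <- amp
  }
  out
}

#' Null controls for the nonlinearity angle
#'
#' \code{"scrambled"} permutes the neuron order of each paired response
#' before decomposing it against its own components, destroying the
#' population structure while preserving the value distribution.
#' \code{"noncorrespondent"} decomposes each paired response against the
#' individual responses of the \emph{other} pairs. Both null families
#' should produce larger angles than the matched true pairs when the
#' paired responses genuinely live near their components' plane.
#'
#' @param responses named list of population response vectors.
#' @param pairs data.frame with columns \code{a}, \code{b}, \code{ab}
#'   naming, for each pair, the two single conditions and the paired
#'   condition in \code{responses}.
#' @param mode \code{"scrambled"} or \code{"noncorrespondent"}.
#' @param n_perm permutations per pair in scrambled mode (default 20).
#' @param seed integer seed.
#' @param bounds coefficient box.
#' @return data.frame with columns \code{pair}, \code{mode}, \code{angle}.
#' @export
nullControls <- function(responses, pairs,
                         mode = c("scrambled", "noncorrespondent"),
                         n_perm = 20, seed = NULL, bounds = c(-1, 1)) {
  mode <- match.arg(mode)
  .assert(all(c("a", "b", "ab") %in% names(pairs)),
          "pairs needs columns a, b, ab")
  .assert(all(unlist(pairs) %in% names(responses)),
          "pairs reference conditions missing from responses")
  if (mode == "noncorrespondent")
    .assert(nrow(pairs) >= 2,
            "non-correspondent pairing needs at least two pairs")
  .withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
      RAB <- responses[[pairs$ab[i]]]
      if (mode == "scrambled") {
        for (p in seq_len(n_perm)) {
          d <- decomposePair(responses[[pairs$a[i]]], responses[[pairs$b[i]]],
                             sample(RAB), bounds = bounds,
                             pair = pairs$ab[i])
          rows[[length(rows) + 1L]] <-
            data.frame(pair = pairs$ab[i], mode = mode,
                       angle = planeAngle(d), stringsAsFactors = FALSE)
        }
      } else {
        for (j in setdiff(seq_len(nrow(pairs)), i)) {
          d <- decomposePair(responses[[pairs$a[j]]], responses[[pairs$b[j]]],
                             RAB, bounds = bounds, pair = pairs$ab[i])
          rows[[length(rows) + 1L]] <-
            data.frame(pair = pairs$ab[i], mode = mode,
                       angle = planeAngle(d), stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
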
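# Trial binarization and linear population decoding.

#' One-shot binarization of trial responses
#'
#' For every neuron, trial and condition the entry is 1 when the peak
#' activity within the four post-onset-inclusive frames (1.8 s at 2.18
#' volumes/s) is at least \code{k_sd} standard deviations above the
#' per-trial pre-onset baseline mean, else 0.
#'
#' @param ne a \linkS4class{NeuromastExperiment}.
#' @param classes list of identity sets; defaults to all conditions in the
#'   log. Conditions must have equal trial counts (balanced protocol).
#' @param window response window length in frames from the onset (default 4).
#' @param k_sd threshold in baseline standard deviations (default 2).
#' @param baseline_frames pre-onset frames forming the per-trial baseline
#'   (default 4); trials without that many pre-onset frames are rejected.
#' @return binary neurons x trials x conditions array
#'   (\code{BinaryResponseTensor}) with condition labels as the third
#'   dimnames.
#' @export
binarizeResponses <- function(ne, classes = NULL, window = 4L, k_sd = 2,
                              baseline_frames = 4L) {
  log <- stimulusLog(ne)
  fs <- samplingRate(ne)
  if (is.null(classes)) classes <- lapply(unique(log$label), .parseLabel)
  labels <- vapply(classes, .classLabel, character(1),
                   universe = attr(log, "universe"))
  x <- traces(ne)
  slices <- lapply(classes, function(cs) {
    tens <- extractTrials(x, cs, frames_before = baseline_frames,
                          frames_after = window - 1L,
                          log = log, sampling_rate = fs)
    nb <- baseline_frames
    base <- tens[, , seq_len(nb), drop = FALSE]
    resp <- tens[, , nb + seq_len(window), drop = FALSE]
    mu <- apply(base, c(1, 2), mean)
    sdv <- apply(base, c(1, 2), sd)
    peak <- apply(resp, c(1, 2), max)
    (peak >= mu + k_sd * sdv) * 1
  })
  n_trials <- vapply(slices, ncol, integer(1))
  .assert(length(unique(n_trials)) == 1,
          "conditions have unequal trial counts: ",
          paste(sprintf("%s=%d", labels, n_trials), collapse = ", "))
  out <- array(0, c(nrow(x), n_trials[1], length(classes)),
               dimnames = list(rownames(x), NULL, labels))
  for (s in seq_along(slices)) out[, , s] <- slices[[s]]
  out
}

# flatten an N x T x S tensor to samples x neurons + labels
.tensorToXY <- function(tensor) {
  dims <- dim(tensor)
  labels <- dimnames(tensor)[[3]] %||% as.character(seq_len(dims[3]))
  X <- do.call(rbind, lapply(seq_len(dims[3]), function(s) t(tensor[, , s])))
  y <- rep(labels, each = dims[2])
  list(X = X, y = y, levels = labels)
}

# one-vs-rest linear decoder at a fixed regularization value
.fitOVR <- function(X, y, levels, cost, penalty) {
  W <- matrix(0, length(levels), ncol(X),
              dimnames = list(levels, colnames(X)))
  b <- setNames(numeric(length(levels)), levels)
  for (s in seq_along(levels)) {
    memb <- factor(ifelse(y == levels[s], "pos", "neg"),
                   levels = c("pos", "neg"))
    if (penalty == "l2") {
      m <- e1071::svm(X, memb, kernel = "linear", cost = cost,
                      scale = FALSE)
      w <- as.numeric(t(m$coefs) %*% m$SV)
      off <- -m$rho
      if (levels(memb)[m$labels[1]] != "pos") {
        w <- -w
        off <- -off
      }
    } else {
      lambda <- 1 / (cost * nrow(X))
      m <- glmnet::glmnet(X, memb, family = "binomial", alpha = 1,
                          lambda = lambda, standardize = FALSE)
      cf <- as.numeric(stats::coef(m))
      # glmnet models P(second level); second level here is "neg"
      w <- -cf[-1]
      off <- -cf[1]
    }
    W[s, ] <- w
    b[s] <- off
  }
  list(W = W, b = b)
}

.predictOVR <- function(fit, X, levels) {
  scores <- X %*% t(fit$W) + matrix(fit$b, nrow(X), length(fit$b),
                                    byrow = TRUE)
  levels[max.col(scores, ties.method = "first")]
}

# stratified assignment of samples to k groups (per-class shuffled cycling)
.stratifiedGroups <- function(y, k) {
  g <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    g[idx] <- (sample(seq_along(idx)) %% k) + 1L
  }
  g
}

#' Train a multiclass linear population decoder
#'
#' Implements the decoding protocol: a stratified random 80/20
#' train/test split of the binarized population vectors; ten-fold
#' cross-validation on the training split with the SVM regularization
#' value iterated over \code{c_grid}; the cost with the highest mean
#' held-out validation accuracy is selected; fold weights at that cost are
#' averaged into the final classes x neurons weight matrix; accuracy and
#' the confusion matrix are reported on the untouched test split.
#' Multiclass scheme is one-vs-rest with a linear kernel; prediction ties
#' go to the lowest class index.
#'
#' @param tensor binary neurons x trials x conditions array from
#'   \code{\link{binarizeResponses}}.
#' @param test_fraction held-out test fraction (default 0.2).
#' @param n_folds cross-validation folds on the training split (default 10).
#' @param c_grid candidate regularization values; default 10 values
#'   logarithmically spaced in [0.1, 10].
#' @param penalty \code{"l2"} (linear-kernel SVM, default) or \code{"l1"}
#'   (L1-regularized logistic one-vs-rest, for genuinely sparse weights).
#' @param min_neurons optional gate: refuse to decode with fewer neurons
#'   (e.g. 100 for single-neuromast runs, 200 for combinations).
#' @param holdout optional tensor used as the test set instead of an
#'   internal split (then all of \code{tensor} is used for training); used
#'   by \code{\link{compositionDecode}}.
#' @param seed integer seed for split and folds.
#' @return a \linkS4class{DecoderResult}.
#' @export
trainDecoder <- function(tensor, test_fraction = 0.2, n_folds = 10,
                         c_grid = NULL, penalty = c("l2", "l1"),
                         min_neurons = NULL, holdout = NULL, seed = NULL) {
  penalty <- match.arg(penalty)
  .assert(length(dim(tensor)) == 3 && dim(tensor)[3] >= 2,
          "need a neurons x trials x conditions tensor with >= 2 conditions")
  if (!is.null(min_neurons))
    .assert(dim(tensor)[1] > min_neurons,
            "population gate: ", dim(tensor)[1], " neurons <= ", min_neurons)
  if (is.null(c_grid))
    c_grid <- 10^seq(log10(0.1), log10(10), length.out = 10)
  xy <- .tensorToXY(tensor)
  zero_tol <- 1e-8
  .withSeed(seed, {
    if (is.null(holdout)) {
      test_grp <- .stratifiedGroups(xy$y, round(1 / test_fraction))
      is_test <- test_grp == 1L
      .assert(all(table(xy$y[!is_test]) >= n_folds),
              "a class has fewer training trials than folds")
      Xtr <- xy$X[!is_test, , drop = FALSE]
      ytr <- xy$y[!is_test]
      Xte <- xy$X[is_test, , drop = FALSE]
      yte <- xy$y[is_test]
    } else {
      .assert(identical(dim(holdout)[1], dim(tensor)[1]),
              "holdout tensor must share the neuron axis")
      ho <- .tensorToXY(holdout)
      .assert(identical(ho$levels, xy$levels),
              "holdout tensor must share the condition labels")
      Xtr <- xy$X
      ytr <- xy$y
      Xte <- ho$X
      yte <- ho$y
      .assert(all(table(ytr) >= n_folds),
              "a class has fewer training trials than folds")
    }
    folds <- .stratifiedGroups(ytr, n_folds)
    cv <- vapply(c_grid, function(cost) {
      mean(vapply(seq_len(n_folds), function(f) {
        fit <- .fitOVR(Xtr[folds != f, , drop = FALSE], ytr[folds != f],
                       xy$levels, cost, penalty)
        mean(.predictOVR(fit, Xtr[folds == f, , drop = FALSE],
                         xy$levels) == ytr[folds == f])
      }, numeric(1)))
    }, numeric(1))
    best <- c_grid[which.max(cv)]   # ties resolve to the smaller cost
    fold_fits <- lapply(seq_len(n_folds), function(f) {
      .fitOVR(Xtr[folds != f, , drop = FALSE], ytr[folds != f],
              xy$levels, best, penalty)
    })
    W <- Reduce(`+`, lapply(fold_fits, `[[`, "W")) / n_folds
    b <- Reduce(`+`, lapply(fold_fits, `[[`, "b")) / n_folds
    W[abs(W) <= zero_tol * max(abs(W))] <- 0
    pred <- .predictOVR(list(W = W, b = b), Xte, xy$levels)
    counts <- table(factor(yte, levels = xy$levels),
                    factor(pred, levels = xy$levels))
    counts <- matrix(as.integer(counts), nrow(counts),
                     dimnames = dimnames(counts))
    rs <- rowSums(counts)
    conf <- counts / ifelse(rs == 0, 1, rs)
    new("DecoderResult",
        weights = W, intercepts = as.numeric(b), cost = best,
        cvAccuracy = data.frame(cost = c_grid, cv_accuracy = cv),
        accuracy = mean(pred == yte),
        classAccuracy = setNames(diag(conf), xy$levels),
        confusion = conf, confusionCounts = counts,
        classLevels = xy$levels, zeroTol = zero_tol)
  })
}

#' Combine binarized single-condition responses with a boolean operator
#'
#' Trials are paired by trial index; when the two conditions have unequal
#' trial counts the pairing is completed by seeded random draws from the
#' smaller set.
#'
#' @param a,b binary neurons x trials matrices for the two conditions
#'   (identical neuron ordering).
#' @param operator \code{"AND"}, \code{"OR"} or \code{"XOR"}.
#' @param seed integer seed for the completion draws.
#' @return binary neurons x trials matrix of composed vectors.
#' @examples
#' booleanCompose(matrix(c(1, 0)), matrix(c(0, 1)), "OR")
#' @export
booleanCompose <- function(a, b, operator = c("AND", "OR", "XOR"),
                           seed = NULL) {
  operator <- match.arg(operator)
  a <- as.matrix(a)
  b <- as.matrix(b)
  .assert(nrow(a) == nrow(b), "neuron axes differ in length")
  if (!is.null(rownames(a)) && !is.null(rownames(b)))
    .assert(identical(rownames(a), rownames(b)),
            "neuron ordering differs between the two tensors")
  n_out <- max(ncol(a), ncol(b))
  .withSeed(seed, {
    ia <- c(seq_len(min(ncol(a), n_out)),
            if (ncol(a) < n_out)
              sample.int(ncol(a), n_out - ncol(a), replace = TRUE))
    ib <- c(seq_len(min(ncol(b), n_out)),
            if (ncol(b) < n_out)
              sample.int(ncol(b), n_out - ncol(b), replace = TRUE))
    A <- a[, ia, drop = FALSE]
    B <- b[, ib, drop = FALSE]
    out <- switch(operator,
                  AND = A * B,
                  OR = pmax(A, B),
                  XOR = (A + B == 1) * 1)
    rownames(out) <- rownames(a)
    out
  })
}

#' Composition decoding: predict paired stimuli from composed single
#' responses
#'
#' The control decoder is trained and tested on real pair trials. The
#' composed decoder is trained on boolean combinations of single-condition
#' trials and tested on all real pair trials. A drop of composed accuracy
#' below control indicates that paired stimuli recruit ensembles not
#' predictable from the single-condition responses (emergent pair coding).
#'
#' @param single_tensors named list of binary neurons x trials matrices,
#'   one per single condition (names are condition labels).
#' @param pair_tensor binary neurons x trials x pairs array; pair labels
#'   like \code{"AP3+AP4"} name the third axis.
#' @param operator boolean operator for the composition.
#' @param universe identity labels used to parse pair labels; defaults to
#'   the identities appearing in \code{names(single_tensors)}.
#' @param seed integer seed.
#' @param ... forwarded to \code{\link{trainDecoder}}.
#' @return list with elements \code{operator}, \code{control},
#'   \code{composed} (both \linkS4class{DecoderResult}) and
#'   \code{accuracy} (per-pair and overall comparison).
#' @export
compositionDecode <- function(single_tensors, pair_tensor,
                              operator = c("AND", "OR", "XOR"),
                              universe = NULL, seed = NULL, ...) {
  operator <- match.arg(operator)
  pair_labels <- dimnames(pair_tensor)[[3]]
  .assert(!is.null(pair_labels), "pair tensor must carry condition labels")
  universe <- universe %||% names(single_tensors)
  composed <- lapply(pair_labels, function(pl) {
    members <- .parseLabel(pl)
    .assert(length(members) == 2, "pair label '", pl, "' is not a pair")
    .assert(all(members %in% names(single_tensors)),
            "single tensors missing for pair ", pl)
    booleanCompose(single_tensors[[members[1]]], single_tensors[[members[2]]],
                   operator, seed = seed)
  })
  n_trials <- vapply(composed, ncol, integer(1))
  .assert(length(unique(n_trials)) == 1, "composed trial counts differ")
  comp_tensor <- array(0, c(nrow(composed[[1]]), n_trials[1],
                            length(pair_labels)),
                       dimnames = list(rownames(composed[[1]]), NULL,
                                       pair_labels))
  for (s in seq_along(composed)) comp_tensor[, , s] <- composed[[s]]
  control <- trainDecoder(pair_tensor, seed = seed, ...)
  composed_fit <- trainDecoder(comp_tensor, holdout = pair_tensor,
                               seed = seed, ...)
  list(operator = operator, control = control, composed = composed_fit,
       accuracy = data.frame(
         pair = c(pair_labels, "overall"),
         control = c(control@classAccuracy, control@accuracy),
         composed = c(composed_fit@classAccuracy, composed_fit@accuracy),
         row.names = NULL))
}

#' Firing probability and recruitment statistics across stimulus
#' complexities
#'
#' For each condition group (e.g. single, paired, triplet stimulation) the
#' firing probability is the mean binary response over responsive neurons
#' and trials, where a neuron counts as responsive when it fires on at
#' least one trial of the group; recruitment is the responsive-set size.
#' Pairwise comparisons of per-neuron firing rates use Welch's two-sample
#' t-test.
#'
#' @param tensors named list (one entry per condition group) of binary
#'   neurons x trials matrices or neurons x trials x conditions arrays.
#' @return list with \code{probability}, \code{count} (named vectors) and
#'   \code{tests} (data.frame of pairwise Welch tests).
#' @export
firingStatistics <- function(tensors) {
  .assert(length(tensors) >= 2, "need at least two condition groups")
  .assert(!is.null(names(tensors)), "condition groups must be named")
  flat <- lapply(tensors, function(t3) {
    if (length(dim(t3)) == 3)
      t3 <- matrix(t3, nrow = dim(t3)[1])
    as.matrix(t3)
  })
  rates <- lapply(flat, function(m) {
    resp <- rowSums(m) > 0
    list(rate = rowMeans(m)[resp], count = sum(resp))
  })
  prob <- vapply(rates, function(r)
    if (r$count == 0) NA_real_ else mean(r$rate), numeric(1))
  count <- vapply(rates, `[[`, integer(1), "count")
  combos <- utils::combn(names(tensors), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(combos, function(p) {
    a <- rates[[p[1]]]$rate
    b <- rates[[p[2]]]$rate
    pv <- if (length(a) >= 2 && length(b) >= 2)
      t.test(a, b)$p.value else NA_real_
    data.frame(group_a = p[1], group_b = p[2], p_value = pv,
               stringsAsFactors = FALSE)
  }))
  list(probability = prob, count = count, tests = tests)
}
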
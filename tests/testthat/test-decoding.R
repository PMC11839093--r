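test_that("binarization matches the peak-over-baseline rule", {
  # planted strong transient -> 1 on (almost) every trial
  cfg <- experimentConfig(combinations = list("AP3", "AP4"), n_trials = 15,
                          n_neurons = 60, p_mix = 0, frac_responsive = 0.5,
                          amplitude = 3, noise_sd = 0.3, reliability = 1)
  ne <- simulateExperiment(cfg, seed = 12)
  tens <- binarizeResponses(ne)
  gt <- groundTruth(ne)
  for (cl in c("AP3", "AP4")) {
    tuned <- gt$tuning[, cl] > 0
    expect_gt(mean(tens[tuned, , cl]), 0.98)
  }
  expect_equal(sort(unique(as.vector(tens))), c(0, 1))
})

test_that("flat trials fire at the max-of-window false-positive rate", {
  # order-statistic oracle computed independently from normal draws with
  # the same 4-frame estimated baseline
  set.seed(31)
  n_mc <- 40000
  mc <- replicate(n_mc, {
    base <- rnorm(4)
    max(rnorm(4)) >= mean(base) + 2 * sd(base)
  })
  oracle <- mean(mc)
  cfg <- experimentConfig(combinations = list("AP3"), n_trials = 20,
                          n_neurons = 300, frac_responsive = 0)
  ne <- simulateExperiment(cfg, seed = 13)
  tens <- binarizeResponses(ne)
  rate <- mean(tens)
  expect_lt(abs(rate - oracle), 0.02)
})

test_that("binarized firing rates track planted reliability", {
  for (p in c(0.5, 0.9)) {
    cfg <- experimentConfig(combinations = list("AP3"), n_trials = 25,
                            n_neurons = 80, p_mix = 0, frac_responsive = 1,
                            amplitude = 3, noise_sd = 0.2, reliability = p)
    ne <- simulateExperiment(cfg, seed = 14)
    tens <- binarizeResponses(ne)
    rate <- mean(tens[, , 1])
    # the planted rate, allowing for the flat-trial false-positive floor
    # on the (1 - p) silent trials
    expect_gt(rate, p - 0.06)
    expect_lt(rate, p + (1 - p) * 0.35)
  }
})

test_that("a separable one-hot code decodes perfectly", {
  tens <- oneHotTensor()
  d <- trainDecoder(tens, seed = 1)
  expect_equal(accuracy(d), 1)
  expect_equal(unname(diag(confusionMatrix(d))), rep(1, 4))
  expect_true(all(confusionMatrix(d)[upper.tri(diag(4))] == 0))
  # confusion accounting identities
  counts <- confusionMatrix(d, normalized = FALSE)
  expect_equal(accuracy(d), sum(diag(counts)) / sum(counts))
  expect_equal(unname(rowSums(confusionMatrix(d))), rep(1, 4))
})

test_that("decoders are seed-deterministic", {
  set.seed(20)
  tens <- oneHotTensor(80, 30, 4)
  flip <- array(runif(length(tens)) < 0.15, dim(tens))
  tens <- abs(tens - flip)
  a <- trainDecoder(tens, seed = 5)
  b <- trainDecoder(tens, seed = 5)
  expect_identical(weightMatrix(a), weightMatrix(b))
  expect_identical(accuracy(a), accuracy(b))
})

test_that("shuffled labels decode at chance", {
  set.seed(21)
  tens <- oneHotTensor(80, 40, 4)
  # destroy the label structure: reassign all samples to random classes
  X <- matrix(aperm(tens, c(2, 3, 1)), ncol = dim(tens)[1])
  X <- X[sample(nrow(X)), ]
  shuffled <- array(t(X), dim = dim(tens), dimnames = dimnames(tens))
  d <- trainDecoder(shuffled, seed = 2)
  n_test <- sum(confusionMatrix(d, normalized = FALSE))
  tol <- 3 * sqrt(0.25 * 0.75 / n_test)
  expect_lt(abs(accuracy(d) - 0.25), tol + 1e-9)
})

test_that("boolean composition reproduces the operator truth tables", {
  a <- matrix(c(1, 0, 1, 1, 0, 0), 3)
  b <- matrix(c(0, 1, 1, 1, 1, 0), 3)
  expect_equal(unname(booleanCompose(a, b, "OR")),
               matrix(c(1, 1, 1, 1, 1, 0), 3))
  expect_equal(unname(booleanCompose(a, b, "AND")),
               matrix(c(0, 0, 1, 1, 0, 0), 3))
  expect_equal(unname(booleanCompose(a, b, "XOR")),
               matrix(c(1, 1, 0, 0, 1, 0), 3))
  # unequal trial counts: pairing completed reproducibly
  c1 <- booleanCompose(a, b[, 1, drop = FALSE], "OR", seed = 4)
  c2 <- booleanCompose(a, b[, 1, drop = FALSE], "OR", seed = 4)
  expect_identical(c1, c2)
  expect_equal(ncol(c1), 2)
  ra <- a
  rownames(ra) <- c("x", "y", "z")
  rb <- b
  rownames(rb) <- c("x", "z", "y")
  expect_error(booleanCompose(ra, rb, "OR"), "ordering")
})

test_that("composed decoders match controls when pairs are exact unions", {
  set.seed(33)
  N <- 120
  T_ <- 30
  ens <- list(AP3 = 1:25, AP4 = 26:50, AP5 = 51:75)
  make_single <- function(e, p = 0.9) {
    m <- matrix(rbinom(N * T_, 1, 0.03), N, T_)
    m[e, ] <- rbinom(length(e) * T_, 1, p)
    rownames(m) <- sprintf("n%03d", 1:N)
    m
  }
  singles <- lapply(ens, make_single)
  pf <- pairFrame()
  pair_t <- array(0, c(N, T_, 3),
                  dimnames = list(rownames(singles[[1]]), NULL, pf$ab))
  for (i in 1:3)
    pair_t[, , i] <- booleanCompose(make_single(ens[[pf$a[i]]]),
                                    make_single(ens[[pf$b[i]]]), "OR")
  cd <- compositionDecode(singles, pair_t, "OR", seed = 1)
  expect_gt(cd$composed@accuracy, cd$control@accuracy - 0.1)
  expect_gt(cd$composed@accuracy, 0.9)
})

test_that("emergent pair-only ensembles degrade composed decoding", {
  pf <- pairFrame()
  N <- 120
  T_ <- 24
  ens <- list(AP3 = 1:25, AP4 = 26:50, AP5 = 51:75)
  emerg <- list(76:90, 91:105, 106:120)
  deltas <- vapply(1:10, function(seed) {
    set.seed(100 + seed)
    make_single <- function(e, p = 0.9) {
      m <- matrix(rbinom(N * T_, 1, 0.03), N, T_)
      m[e, ] <- rbinom(length(e) * T_, 1, p)
      rownames(m) <- sprintf("n%03d", 1:N)
      m
    }
    singles <- lapply(ens, make_single)
    pair_t <- array(0, c(N, T_, 3),
                    dimnames = list(rownames(singles[[1]]), NULL, pf$ab))
    for (i in 1:3) {
      # real pairs: constituents nearly silent, a pair-specific ensemble fires
      m <- matrix(rbinom(N * T_, 1, 0.03), N, T_)
      m[c(ens[[pf$a[i]]], ens[[pf$b[i]]]), ] <-
        rbinom(50 * T_, 1, 0.15)
      m[emerg[[i]], ] <- rbinom(15 * T_, 1, 0.9)
      pair_t[, , i] <- m
    }
    cd <- compositionDecode(singles, pair_t, "OR", seed = seed)
    cd$control@accuracy - cd$composed@accuracy
  }, numeric(1))
  pv <- suppressWarnings(wilcox.test(deltas, alternative = "greater")$p.value)
  expect_lt(pv, 0.05)
})

test_that("AND of disjoint ensembles collapses to chance", {
  set.seed(44)
  N <- 90
  T_ <- 24
  ens <- list(AP3 = 1:30, AP4 = 31:60, AP5 = 61:90)
  make_single <- function(e) {
    m <- matrix(0, N, T_)
    m[e, ] <- 1
    rownames(m) <- sprintf("n%03d", 1:N)
    m
  }
  singles <- lapply(ens, make_single)
  pf <- pairFrame()
  pair_t <- array(rbinom(N * T_ * 3, 1, 0.5), c(N, T_, 3),
                  dimnames = list(rownames(singles[[1]]), NULL, pf$ab))
  cd <- compositionDecode(singles, pair_t, "AND", seed = 2)
  # all-zero composed vectors carry no information
  expect_lt(cd$composed@accuracy, 1 / 3 + 3 * sqrt(2 / 9 / (T_ * 3)))
})

test_that("firing statistics recover planted rates and their contrast", {
  set.seed(55)
  lo <- matrix(rbinom(200 * 20, 1, 0.5), 200)
  hi <- matrix(rbinom(200 * 20, 1, 0.8), 200)
  fs <- firingStatistics(list(single = lo, pair = hi))
  expect_lt(abs(fs$probability["single"] - 0.5), 0.03)
  expect_lt(abs(fs$probability["pair"] - 0.8), 0.03)
  expect_lt(fs$tests$p_value, 0.01)
  expect_equal(unname(fs$count), c(200, 200))
  empty <- matrix(0, 200, 20)
  fs2 <- firingStatistics(list(a = lo, b = empty))
  expect_true(is.na(fs2$probability["b"]))
  expect_equal(unname(fs2$count["b"]), 0L)
  expect_error(firingStatistics(list(a = lo)), "at least two")
})
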
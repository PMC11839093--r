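test_that("selectivity labels recover the planted tuning structure", {
  cfg <- experimentConfig(combinations = list("AP3", "AP4", "AP5"),
                          n_trials = 15, n_neurons = 150, p_mix = 0.25,
                          isi = 8, region_props = c(MON_ipsi = 1),
                          frac_responsive = 0.5)
  ne <- simulateExperiment(cfg, seed = 7)
  gt <- groundTruth(ne)
  sel <- classifySelectivity(ne)
  m <- attr(sel, "membership")
  tuned <- gt$tuning[, colnames(m)] > 0
  expect_gt(mean(m == tuned), 0.95)
  # planted single-selective neurons carry exactly their class
  singles <- which(rowSums(tuned) == 1)
  expect_true(all(sel$label[singles] %in% c("single", "mixed")))
  expect_gt(mean(sel$label[singles] == "single"), 0.9)
  # planted two-class neurons come out mixed with those classes
  mixed <- which(rowSums(tuned) == 2)
  if (length(mixed) >= 3) {
    agree <- vapply(mixed, function(i) all(m[i, ] == tuned[i, ]), logical(1))
    expect_gt(mean(agree), 0.8)
  }
  # flat neurons are nonresponsive
  flat <- which(rowSums(tuned) == 0)
  expect_gt(mean(sel$label[flat] == "nonresponsive"), 0.9)
})

test_that("conditional probabilities follow the counting definition", {
  # hand-built membership: |A| = 10, |A and B| = 4
  m <- matrix(FALSE, 20, 2, dimnames = list(NULL, c("A", "B")))
  m[1:10, "A"] <- TRUE
  m[7:16, "B"] <- TRUE
  p <- conditionalProbabilityMatrix(m)
  expect_equal(p["A", "B"], 0.4)
  expect_equal(p["B", "A"], 0.4)
  expect_equal(diag(p), c(A = 1, B = 1))
  # class with only single-selective members: zero off-diagonal row
  m2 <- matrix(FALSE, 10, 2, dimnames = list(NULL, c("A", "B")))
  m2[1:5, "A"] <- TRUE
  m2[6:8, "B"] <- TRUE
  p2 <- conditionalProbabilityMatrix(m2)
  expect_equal(p2["A", "B"], 0)
  # empty class: undefined row, not zero
  m3 <- m2
  m3[, "B"] <- FALSE
  p3 <- conditionalProbabilityMatrix(m3)
  expect_true(all(is.na(p3["B", ])))
  expect_false(anyNA(p3["A", ]))
})

test_that("conditional-probability rows are not forced to sum to one", {
  set.seed(11)
  m <- matrix(runif(300) < 0.4, 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  p <- conditionalProbabilityMatrix(m)
  expect_true(any(abs(rowSums(p) - 1) > 0.2))
})

test_that("mixed selectivity decays with distance along the body axis", {
  # planted overlap ~ exp(-d / lambda) must surface as conditional
  # probabilities that fall with rank distance (the heatmap's off-diagonal
  # gradient)
  combos <- as.list(c("AP2", "AP3", "AP4", "AP5", "AP6"))
  vals <- list()
  for (seed in 1:3) {
    cfg <- experimentConfig(combinations = combos, n_trials = 10,
                            n_neurons = 250, p_mix = 0.6, mixing_lambda = 1.5,
                            isi = 8, region_props = c(MON_ipsi = 1),
                            frac_responsive = 0.8)
    ne <- simulateExperiment(cfg, seed = seed)
    p <- conditionalProbabilityMatrix(classifySelectivity(ne))
    cls <- colnames(p)
    rk <- match(cls, cfg$universe)
    for (a in seq_along(cls)) for (b in seq_along(cls)) {
      if (a != b && is.finite(p[a, b]))
        vals[[length(vals) + 1L]] <- c(d = abs(rk[a] - rk[b]), p = p[a, b])
    }
  }
  vals <- do.call(rbind, vals)
  ct <- suppressWarnings(
    cor.test(vals[, "d"], vals[, "p"], method = "spearman",
             alternative = "less"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("1-D KDE is normalized and locates cluster structure", {
  set.seed(5)
  x <- c(rnorm(400, -50, 4), rnorm(400, 50, 4))
  d <- kde1d(x)
  expect_equal(sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2),
               1, tolerance = 1e-3)
  # bimodal: both cluster centers carry local maxima
  peak_lo <- d$x[which.max(d$density * (d$x < 0))]
  peak_hi <- d$x[which.max(d$density * (d$x > 0))]
  expect_lt(abs(peak_lo + 50), 5)
  expect_lt(abs(peak_hi - 50), 5)
  # large-sample peak of a N(0, 10^2) sample sits near 0
  set.seed(6)
  g <- kde1d(rnorm(1000, 0, 10))
  expect_lt(abs(g$x[which.max(g$density)]), 2)
  expect_error(kde1d(1), "at least 2")
})

test_that("pairwise KLD is a symmetric nonnegative matrix with zero diagonal", {
  set.seed(7)
  sets <- list(a = matrix(rnorm(300, 0, 10), ncol = 3),
               b = matrix(rnorm(300, 0, 10), ncol = 3) + 8,
               c = matrix(rnorm(300, 0, 10), ncol = 3))
  k <- pairwiseKLD(sets)
  expect_true(isSymmetric(k))
  expect_equal(diag(k), c(a = 0, b = 0, c = 0))
  expect_true(all(k >= 0))
  # near-identical distributions score near zero, separated ones higher
  expect_lt(k["a", "c"], 0.15)
  expect_gt(k["a", "b"], k["a", "c"])
  expect_message(pairwiseKLD(c(sets, list(d = sets$a[1:3, ]))), "dropping")
})

test_that("homogeneity curves separate planted clusters from shuffled labels", {
  cfg <- experimentConfig(combinations = as.list(c("AP2", "AP3", "AP4", "AP5")),
                          n_trials = 2, n_neurons = 400, p_mix = 0,
                          region_props = c(MON_ipsi = 1), frac_responsive = 1,
                          spatial = spatialParams(class_spacing = 100,
                                                  cluster_sd = 5))
  ne <- simulateExperiment(cfg, seed = 2)
  lab <- groundTruth(ne)$preferred
  hom <- clusterHomogeneity(roiTable(ne), lab)
  near <- subset(hom, bin_hi <= 10 & n_pairs > 0)
  expect_gt(mean(near$normalized, na.rm = TRUE), 2)
  # permutation oracle: shuffled labels flatten the curve to ~1
  set.seed(3)
  homp <- clusterHomogeneity(roiTable(ne), sample(lab))
  # neighbor pairs within a bin are correlated (shared queries), so only
  # well-populated bins are held to a per-bin band; the weighted mean is
  # tight
  dense <- subset(homp, n_pairs >= 1000)
  expect_lt(max(abs(dense$normalized - 1)), 0.35)
  expect_lt(abs(weighted.mean(dense$normalized, dense$n_pairs) - 1), 0.05)
  # a single-member class has no defined curve
  lab2 <- lab
  lab2[lab2 == "AP2"] <- NA
  lab2[which(is.na(lab2))[1]] <- "AP2"
  hom2 <- clusterHomogeneity(roiTable(ne), lab2)
  expect_true(all(is.na(subset(hom2, class == "AP2")$normalized)))
})
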
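test_that("PC trajectories separate orthogonal ensembles at the onset", {
  # isi 10 keeps the +/- 4 s windows clear of neighboring transients
  cfg <- experimentConfig(combinations = list("AP3", "AP4"), n_trials = 10,
                          n_neurons = 60, p_mix = 0, frac_responsive = 1,
                          noise_sd = 0.1, reliability = 1, isi = 10,
                          region_props = c(MON_ipsi = 1))
  ne <- simulateExperiment(cfg, seed = 25)
  tp <- pcaTrajectories(ne, window_s = 4)
  expect_s3_class(tp, "TrajectoryProjection")
  # variance fractions are an SVD spectrum: sorted, nonnegative, sum 1
  vf <- tp$variance_explained
  expect_true(all(diff(vf) <= 1e-12))
  expect_true(all(vf >= 0))
  expect_equal(sum(vf), 1, tolerance = 1e-9)
  # the two stimuli diverge maximally right after the stimulus
  tr <- tp$trajectories
  sep <- sapply(split(tr, tr$time_s), function(b) {
    a <- b$score[b$stimulus == unique(tr$stimulus)[1]]
    c2 <- b$score[b$stimulus == unique(tr$stimulus)[2]]
    sqrt(sum((a - c2)^2))
  })
  t_at_max <- as.numeric(names(sep))[which.max(sep)]
  expect_lt(abs(t_at_max), 1.5)          # within ~3 frames of the onset
  edge_sep <- sep[c(1, length(sep))]
  expect_true(all(edge_sep < max(sep) / 2))
})

test_that("identical condition responses give coincident trajectories", {
  # one condition duplicated under two labels: scores must coincide
  cfg <- experimentConfig(combinations = list("AP3"), n_trials = 12,
                          n_neurons = 30, noise_sd = 0.05, reliability = 1,
                          p_mix = 0, frac_responsive = 1)
  ne <- simulateExperiment(cfg, seed = 26)
  tp <- pcaTrajectories(ne, classes = list("AP3", "AP3"), window_s = 3)
  tr <- tp$trajectories
  for (k in tp$components) {
    s1 <- tr$score[tr$component == k][seq_len(sum(tr$component == k) / 2)]
    s2 <- tr$score[tr$component == k][-seq_len(sum(tr$component == k) / 2)]
    expect_equal(s1, s2, tolerance = 1e-9)
  }
})

test_that("the SVD reconstruction reproduces the z-scored matrix", {
  cfg <- experimentConfig(combinations = list("AP3", "AP4"), n_trials = 6,
                          n_neurons = 25, noise_sd = 0.2)
  ne <- simulateExperiment(cfg, seed = 27)
  tp <- pcaTrajectories(ne, window_s = 3)
  rec <- tp$svd$u %*% diag(tp$svd$d) %*% t(tp$svd$v)
  expect_equal(rec, unname(tp$zscored), tolerance = 1e-9)
})

test_that("region correlation matrices contrast coding styles", {
  cfg <- experimentConfig(
    combinations = as.list(c("AP2", "AP3", "AP4", "AP5")),
    n_trials = 10, n_neurons = 500, p_mix = 0.1, frac_responsive = 0.8,
    region_props = c(MON_ipsi = 0.5, superior_medulla = 0.5))
  ne <- simulateExperiment(cfg, seed = 28)
  rc <- regionCorrelationMatrix(ne)
  for (m in rc$matrices[!vapply(rc$matrices, is.null, logical(1))]) {
    expect_true(isSymmetric(m))
    expect_equal(unname(diag(m)), rep(1, 4))
    expect_true(all(abs(m) <= 1 + 1e-12))
  }
  # condition-specific ensembles decorrelate; shared gain does not
  expect_lt(rc$decorrelation_index["MON_ipsi"], 0.4)
  expect_gt(rc$decorrelation_index["superior_medulla"], 0.7)
  # undersized regions are undefined, not fabricated
  rc2 <- regionCorrelationMatrix(ne, min_neurons = 10^6)
  expect_true(all(is.na(rc2$decorrelation_index)))
})

test_that("subsampling is unbiased, seeded, and gated by region size", {
  cfg <- experimentConfig(
    combinations = as.list(c("AP2", "AP3", "AP4", "AP5")),
    n_trials = 10, n_neurons = 500, p_mix = 0.1, frac_responsive = 0.8,
    region_props = c(MON_ipsi = 0.5, superior_medulla = 0.5))
  ne <- simulateExperiment(cfg, seed = 28)
  full <- regionCorrelationMatrix(ne)
  sub <- suppressMessages(
    subsampledRegionCorrelation(ne, n_subsample = 150, n_iter = 300,
                                seed = 29))
  for (r in names(sub$matrices)) {
    expect_lt(max(abs(sub$matrices[[r]] - full$matrices[[r]])), 0.02)
  }
  sub2 <- suppressMessages(
    subsampledRegionCorrelation(ne, n_subsample = 150, n_iter = 300,
                                seed = 29))
  expect_identical(sub$matrices, sub2$matrices)
  expect_error(subsampledRegionCorrelation(ne, n_subsample = 10^6),
               "size gate")
})

test_that("across-sample decorrelation comparison uses paired tests", {
  results <- lapply(1:6, function(seed) {
    cfg <- experimentConfig(
      combinations = as.list(c("AP3", "AP4", "AP5")),
      n_trials = 8, n_neurons = 200, frac_responsive = 0.8, p_mix = 0.1,
      region_props = c(MON_ipsi = 0.5, superior_medulla = 0.5))
    regionCorrelationMatrix(simulateExperiment(cfg, seed = seed))
  })
  ht <- compareDecorrelation(results, "MON_ipsi", "superior_medulla")
  expect_lt(ht$p.value, 0.05)
})
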
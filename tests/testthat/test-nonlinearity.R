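test_that("population response vectors are normalized per-neuron maxima", {
  # isi beyond the kernel support: transients never superpose, so every
  # tuned trial peak equals the global trace max exactly
  cfg <- experimentConfig(combinations = list("AP3"), n_trials = 6,
                          n_neurons = 40, noise_sd = 0, reliability = 1,
                          p_mix = 0, frac_responsive = 0.5, amplitude_cv = 0,
                          isi = 20)
  ne <- simulateExperiment(cfg, seed = 15)
  gt <- groundTruth(ne)
  r3 <- suppressWarnings(populationResponseVector(ne, "AP3"))
  tuned <- gt$tuning[, "AP3"] > 0
  # noiseless tuned neuron: its transient is the global trace max -> 1
  expect_true(all(r3[tuned] > 0.999))
  # noiseless silent neuron: constant trace -> flagged zero
  silent <- rowSums(gt$tuning) == 0
  expect_true(all(r3[silent] == 0))
  expect_true(all(r3 >= 0 & r3 <= 1))
})

test_that("bounded decomposition solves its closed-form cases", {
  d1 <- decomposePair(c(1, 0), c(0, 1), c(0.5, 0.5))
  expect_equal(unname(coef(d1)), c(0.5, 0.5))
  expect_equal(planeAngle(d1), 0)
  expect_equal(nonlinearResidual(d1), c(0, 0))

  d2 <- decomposePair(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(unname(coef(d2)), c(0, 0))
  expect_equal(planeAngle(d2), 90)

  # clipped optimum, hand-solved: alpha pinned at the +1 bound
  d3 <- decomposePair(c(1, 0), c(0, 1), c(1.5, 0))
  expect_equal(unname(coef(d3)), c(1, 0))
  expect_equal(nonlinearResidual(d3), c(0.5, 0))
  expect_equal(d3@summaryRNL, 0.25)
  expect_equal(planeAngle(d3), asin(0.5 / 1.5) * 180 / pi, tolerance = 1e-10)
})

test_that("the reconstruction identity holds exactly for random problems", {
  set.seed(16)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    RA <- abs(rnorm(n))
    RB <- abs(rnorm(n))
    RAB <- abs(rnorm(n))
    d <- decomposePair(RA, RB, RAB)
    expect_equal(RAB, coef(d)[1] * RA + coef(d)[2] * RB +
                   nonlinearResidual(d), tolerance = 1e-12)
    expect_gte(planeAngle(d), 0)
    expect_lte(planeAngle(d), 90)
    expect_true(all(abs(coef(d)) <= 1 + 1e-12))
  }
})

test_that("interior optima leave residuals orthogonal to the plane", {
  set.seed(17)
  for (i in 1:15) {
    RA <- rnorm(30)
    RB <- rnorm(30)
    RAB <- 0.3 * RA + 0.4 * RB + rnorm(30, 0, 0.05)
    d <- decomposePair(RA, RB, RAB)
    r <- nonlinearResidual(d)
    expect_lt(abs(sum(r * RA)), 1e-8 * sqrt(sum(r^2) * sum(RA^2)) + 1e-12)
    expect_lt(abs(sum(r * RB)), 1e-8 * sqrt(sum(r^2) * sum(RB^2)) + 1e-12)
  }
})

test_that("the angle is invariant to joint positive rescaling", {
  set.seed(18)
  RA <- abs(rnorm(20))
  RB <- abs(rnorm(20))
  RAB <- abs(rnorm(20))
  a1 <- planeAngle(decomposePair(RA, RB, RAB))
  a2 <- planeAngle(decomposePair(3 * RA, 3 * RB, 3 * RAB))
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("planted coefficients are recovered at high SNR", {
  set.seed(19)
  for (i in 1:10) {
    n <- 60
    RA <- abs(rnorm(n))
    RB <- abs(rnorm(n))
    ab <- runif(2, -1, 1)
    signal <- ab[1] * RA + ab[2] * RB
    noise_sd <- sd(signal) / 10                       # SNR 10
    RAB <- signal + rnorm(n, 0, noise_sd)
    d <- decomposePair(RA, RB, RAB)
    expect_lt(max(abs(coef(d) - ab)), 0.05)
  }
})

test_that("summary statistics and supra/sub sets behave on exact cases", {
  d <- decomposePair(c(1, 0), c(0, 1), c(0.5, 0.5))
  s <- nonlinearitySummary(list(d, d))
  expect_equal(s$mean_angle, 0)
  expect_equal(s$mean_RNL, 0)
  expect_length(s$supra[[1]], 0)
  expect_length(s$sub[[1]], 0)
  # amplitude comparisons attach per-condition means for the classed sets
  dd <- decomposePair(c(1, 0, 0, 0.2), c(0, 1, 0, 0.2), c(1, 1, 3, -2))
  s2 <- nonlinearitySummary(list(dd), threshold = 1,
                            responses = list(A = c(1, 0, 0, 0.2)))
  expect_true(is.data.frame(s2$amplitudes))
  expect_length(s2$supra[[1]], 1)
  expect_length(s2$sub[[1]], 1)
})

test_that("planted interaction gains leave signed residual footprints", {
  # supra-linear plant: the jointly tuned subpopulation carries positive
  # residuals; sub-linear gain flips the sign on that subpopulation
  pf <- pairFrame()
  for (gain in c(2, 0.5)) {
    ne <- simulateExperiment(nonlinConfig(gain = gain, p_mix = 0.3,
                                          noise_sd = 0.02), seed = 22)
    pd <- pairDecompositions(ne)
    tk <- groundTruth(ne)$tuning[pd$keep, ] > 0
    subres <- unlist(lapply(1:3, function(i) {
      both <- tk[, pf$a[i]] & tk[, pf$b[i]]
      nonlinearResidual(pd$decs[[i]])[both]
    }))
    expect_gt(length(subres), 5)
    if (gain > 1) expect_gt(mean(subres), 0.2) else
      expect_lt(mean(subres), -0.2)
  }
})

test_that("null controls produce larger angles than matched true pairs", {
  ne <- simulateExperiment(nonlinConfig(), seed = 23)
  pd <- pairDecompositions(ne)
  true_angles <- vapply(pd$decs, planeAngle, numeric(1))
  sc <- nullControls(pd$responses, pairFrame(), "scrambled", n_perm = 8,
                     seed = 24)
  expect_gt(min(sc$angle), max(true_angles))
  nc <- nullControls(pd$responses, pairFrame(), "noncorrespondent",
                     seed = 24)
  expect_gt(mean(nc$angle), mean(true_angles))
  # seeded scrambles are reproducible
  sc2 <- nullControls(pd$responses, pairFrame(), "scrambled", n_perm = 8,
                      seed = 24)
  expect_identical(sc, sc2)
  expect_error(nullControls(pd$responses, pairFrame()[1, ],
                            "noncorrespondent"), "at least two")
})
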
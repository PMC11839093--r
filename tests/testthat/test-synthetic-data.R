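test_that("protocol layout is deterministic without randomization", {
  log <- buildStimulusProtocol(c("AP3", "AP4", "AP5"),
                               list("AP3", "AP4", "AP5"),
                               n_trials = 2, isi = 4, randomize = FALSE)
  expect_equal(log$onset_time, seq(0, 20, by = 4))
  expect_equal(log$label, rep(c("AP3", "AP4", "AP5"), 2))
  expect_equal(log$duration, rep(0.05, 6))
})

test_that("randomized protocols permute within blocks and respect seeds", {
  uni <- c("AP3", "AP4", "AP5")
  combos <- list("AP3", "AP4", "AP5")
  a <- buildStimulusProtocol(uni, combos, 6, 4, randomize = TRUE, seed = 1)
  b <- buildStimulusProtocol(uni, combos, 6, 4, randomize = TRUE, seed = 2)
  expect_equal(sort(a$label), sort(b$label))      # same multiset
  expect_false(identical(a$label, b$label))       # different order
  # each trial block holds each condition exactly once
  blocks <- matrix(a$label, nrow = 3)
  expect_true(all(apply(blocks, 2, function(x) setequal(x, uni))))
  expect_identical(a, buildStimulusProtocol(uni, combos, 6, 4,
                                            randomize = TRUE, seed = 1))
})

test_that("balanced pair protocols count every combination exactly", {
  uni <- c("AP2", "AP3", "AP4", "AP5")
  combos <- utils::combn(uni, 2, simplify = FALSE)
  log <- buildStimulusProtocol(uni, combos, n_trials = 10, isi = 4, seed = 3)
  expect_equal(nrow(log), 60)
  tally <- stimulusCounts(log)                    # brute-force tally
  expect_length(tally, 6)
  expect_true(all(tally == 10))
})

test_that("degenerate protocol requests are rejected with clear messages", {
  expect_error(buildStimulusProtocol(c("AP3"), list(), 5, 4), "empty")
  expect_error(buildStimulusProtocol(c("AP3"), list("AP3"), 0, 4),
               "positive integer")
  expect_error(buildStimulusProtocol(c("AP3"), list("AP3"), 5, 0.1),
               "at least one frame")
  expect_error(buildStimulusProtocol(c("AP3"), list("AP4"), 5, 4), "unknown")
})

test_that("ROI sampling honors cluster geometry and seeds", {
  gt <- list(region = rep("MON_ipsi", 40),
             preferred = rep(c("AP3", "AP5"), each = 20))
  uni <- c("AP3", "AP4", "AP5")
  sp0 <- spatialParams(class_spacing = 100, cluster_sd = 0, terminal_sd = 0)
  roi0 <- sampleRoiCoordinates(gt, sp0, uni, seed = 1)
  # degenerate SD: all same-class neurons collapse onto the class center
  expect_equal(var(roi0$x_um[1:20]), 0)
  expect_equal(unique(roi0$x_um[1:20]) - unique(roi0$x_um[21:40]), -200)

  sp <- spatialParams(class_spacing = 100, cluster_sd = 5)
  roi <- sampleRoiCoordinates(gt, sp, uni, seed = 2)
  expect_identical(roi, sampleRoiCoordinates(gt, sp, uni, seed = 2))
  # 100 um between centers, 5 um SD: nearest neighbor shares the class
  xyz <- as.matrix(roi[, 1:3])
  nn_same <- vapply(seq_len(40), function(i) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    d[i] <- Inf
    gt$preferred[which.min(d)] == gt$preferred[i]
  }, logical(1))
  expect_true(mean(nn_same) == 1)

  gt_bad <- list(region = c("MON_ipsi", "nowhere"), preferred = c("AP3", NA))
  expect_error(sampleRoiCoordinates(gt_bad, sp, uni),
               "missing cluster parameters")
})

test_that("trace rendering reproduces the forward model exactly", {
  uni <- c("A", "B")
  log <- buildStimulusProtocol(uni, list("A"), 1, 4, randomize = FALSE,
                               pre_time = 2)
  kp <- kernelParams()
  gt <- list(tuning = matrix(c(1, 0), 1, 2, dimnames = list(NULL, uni)),
             reliability = 1, noise_sd = 0, pair_gain = numeric(0))
  x <- renderTraces(gt, log, kp, sampling_rate = 2.18, seed = 1)
  kv <- calciumKernel(kp, 2.18)
  onset <- floor(2 * 2.18) + 1
  expect_equal(max(x), max(kv), tolerance = 1e-12)
  expect_equal(x[1, onset + seq_along(kv) - 1], kv)
  expect_true(all(x[1, seq_len(onset - 1)] == 0))

  # reliability 0: nothing but noise (here zero noise)
  gt0 <- modifyList(gt, list(reliability = 0))
  expect_true(all(renderTraces(gt0, log, kp, 2.18, seed = 1) == 0))
})

test_that("pair interaction gain multiplies the summed amplitude", {
  uni <- c("A", "B")
  log <- buildStimulusProtocol(uni, list(c("A", "B")), 1, 4,
                               randomize = FALSE, pre_time = 2)
  kp <- kernelParams()
  gt <- list(tuning = matrix(c(1, 1), 1, 2, dimnames = list(NULL, uni)),
             reliability = 1, noise_sd = 0,
             pair_gain = c("A+B" = 2))
  x <- renderTraces(gt, log, kp, 2.18, seed = 1)
  # brute-force: 2 x (a_A + a_B) x peak-normalized kernel
  expect_equal(max(x), 2 * (1 + 1) * max(calciumKernel(kp, 2.18)),
               tolerance = 1e-12)
})

test_that("generated experiments are seed-deterministic and balanced", {
  cfg <- experimentConfig(combinations = list("AP3", "AP4"), n_trials = 4,
                          n_neurons = 30)
  a <- simulateExperiment(cfg, seed = 9)
  b <- simulateExperiment(cfg, seed = 9)
  expect_identical(traces(a), traces(b))
  expect_identical(roiTable(a), roiTable(b))
  expect_identical(stimulusLog(a), stimulusLog(b))
  expect_equal(nrow(stimulusLog(a)), 4 * 2)
  c2 <- simulateExperiment(cfg, seed = 10)
  expect_false(identical(traces(a), traces(c2)))
})

test_that("a survey-style protocol yields n_trials x n_neuromasts events", {
  cfg <- experimentConfig(
    combinations = as.list(c("DV1", "DV2", "AP2", "AP3", "AP4", "AP5",
                             "AP6", "Ter")),
    n_trials = 20, isi = 60, n_neurons = 10)
  ne <- simulateExperiment(cfg, seed = 1)
  expect_equal(nrow(stimulusLog(ne)), 8 * 20)
  expect_true(all(stimulusCounts(stimulusLog(ne)) == 20))
})

test_that("noiseless tuned traces correlate perfectly with their regressor", {
  cfg <- experimentConfig(combinations = list("AP3", "AP4"), n_trials = 6,
                          n_neurons = 20, noise_sd = 0, reliability = 1,
                          p_mix = 0, frac_responsive = 1, amplitude_cv = 0,
                          region_props = c(MON_ipsi = 1))
  ne <- simulateExperiment(cfg, seed = 4)
  gt <- groundTruth(ne)
  reg <- makeRegressor(stimulusLog(ne), "AP3", samplingRate(ne))
  tuned <- which(gt$tuning[, "AP3"] > 0)
  for (i in head(tuned, 3))
    expect_equal(cor(traces(ne)[i, ], reg), 1, tolerance = 1e-9)
})
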
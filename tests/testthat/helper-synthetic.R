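# Shared fixtures, all generated in code.

# singles + all pairs of AP3..AP5 (the single/pair/triplet-style session
# used by the nonlinearity analyses, without the triplet unless asked)
fig6Combinations <- function(triplet = FALSE) {
  out <- c(list("AP3", "AP4", "AP5"),
           list(c("AP3", "AP4"), c("AP3", "AP5"), c("AP4", "AP5")))
  if (triplet) out <- c(out, list(c("AP3", "AP4", "AP5")))
  out
}

pairFrame <- function() {
  data.frame(a = c("AP3", "AP3", "AP4"), b = c("AP4", "AP5", "AP5"),
             ab = c("AP3+AP4", "AP3+AP5", "AP4+AP5"),
             stringsAsFactors = FALSE)
}

# high-SNR session for nonlinearity recovery; gain = NULL plants no
# interaction (linear summation)
nonlinConfig <- function(gain = NULL, p_mix = 0.35, noise_sd = 0.05) {
  pg <- if (is.null(gain)) numeric(0) else
    setNames(rep(gain, 3), pairFrame()$ab)
  experimentConfig(combinations = fig6Combinations(),
                   n_trials = 12, n_neurons = 150, p_mix = p_mix, isi = 8,
                   reliability = 1, noise_sd = noise_sd, pair_gain = pg,
                   region_props = c(MON_ipsi = 1), frac_responsive = 0.7)
}

# population response vectors for every condition of an experiment
responseVectors <- function(ne) {
  labels <- unique(stimulusLog(ne)$label)
  setNames(lapply(labels, function(l) {
    populationResponseVector(ne, strsplit(l, "+", fixed = TRUE)[[1]])
  }), labels)
}

# decompositions for the three AP3..AP5 pairs restricted to the planted
# responsive union
pairDecompositions <- function(ne) {
  keep <- rowSums(groundTruth(ne)$tuning) > 0
  resp <- responseVectors(ne[keep, ])
  pf <- pairFrame()
  list(decs = lapply(seq_len(3), function(i) {
    decomposePair(resp[[pf$a[i]]], resp[[pf$b[i]]], resp[[pf$ab[i]]],
                  pair = pf$ab[i])
  }), responses = resp, keep = keep)
}

# binary tensor with one disjoint always-firing ensemble per class
oneHotTensor <- function(n_neurons = 120, n_trials = 40, n_classes = 4) {
  stopifnot(n_neurons %% n_classes == 0)
  size <- n_neurons %/% n_classes
  tens <- array(0, c(n_neurons, n_trials, n_classes),
                dimnames = list(sprintf("n%03d", seq_len(n_neurons)), NULL,
                                paste0("C", seq_len(n_classes))))
  for (s in seq_len(n_classes))
    tens[(s - 1) * size + seq_len(size), , s] <- 1
  tens
}
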
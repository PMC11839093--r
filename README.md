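# neuromastCoding

Population-coding analysis for optogenetic lateral-line stimulation
experiments in larval zebrafish.

The posterior lateral line (pLL) is a chain of mechanosensory organs —
neuromasts — along the fish's tail, innervated by the pLL ganglion and
relayed to the medial octavolateralis nucleus (MON) in the hindbrain.
Stimulating single neuromasts, pairs or triplets optogenetically while
imaging whole-brain calcium activity yields neuron × time fluorescence
matrices, a stimulus log, and registered ROI coordinates. This package
implements the downstream population analyses for such experiments, plus a
synthetic-experiment generator with planted ground truth so that every
stage is testable without data downloads:

* **Responsiveness** — per-condition stimulus regressors (binary onset
  trains convolved with a peak-normalized double-exponential indicator
  kernel, τ_decay ≤ 3 s), Pearson correlation of min-max normalized traces,
  and a 500-shuffle surrogate-stimulus null; a neuron is responsive when its
  statistic is ≥ 2.5 null SDs above the null mean.
* **Selectivity & topography** — single- vs mixed-selectivity labels from a
  2-SD amplitude criterion, conditional-probability matrices
  P(B|A) = |A∩B|/|A|, 1-D KDE of ROI positions, pairwise symmetrized
  Kullback–Leibler divergence between per-identity point clouds, and
  cluster-homogeneity curves (same-identity neighbor probability,
  normalized by base rate).
* **Decoding** — one-shot binarization (peak within 4 frames ≥ baseline
  mean + 2 SD), multiclass linear SVM (one-vs-rest, stratified 80/20 split,
  10-fold CV over costs in [0.1, 10], fold-averaged weights), confusion
  matrices, boolean AND/OR/XOR composition decoding, and firing/recruitment
  statistics.
* **Weight metrics** — Hoyer sparseness
  S(v) = (√n − ‖v‖₁/‖v‖₂)/(√n − 1) over neurons (population) and over
  classes (lifetime), Jaccard dissimilarity of nonzero-weight index sets,
  and anatomical localization of weights > 3 SD above the class mean.
* **Nonlinear summation** — exact bounded least squares
  R(A,B) = α·R(A,0) + β·R(0,B) + R_NL(A,B) with α, β ∈ [−1, 1]; the angle
  asin(‖R_NL‖/‖R(A,B)‖) measures departure from the component plane
  (0° linear, 90° orthogonal), with scrambled and non-correspondent null
  controls.
* **Geometry & decorrelation** — trial-averaged PC-space trajectories
  (components 2–4, the leading stimulus-unspecific component excluded) and
  region-wise Pearson correlation matrices of condition-mean population
  vectors with a 200-neuron × 1000-iteration subsampling control.

The central container, `NeuromastExperiment`, extends Bioconductor's
`SummarizedExperiment` (assay `"traces"`, ROI table in `rowData`, stimulus
log and sampling rate in dedicated slots, planted ground truth retained for
synthetic data).

## Worked example

Simulate a single/pair session, detect responsive neurons, decode stimulus
identity, and quantify weight sparseness and nonlinear summation:

```r
library(neuromastCoding)

prs <- list(c("AP3", "AP4"), c("AP3", "AP5"), c("AP4", "AP5"))
cfg <- experimentConfig(
  combinations = c(list("AP3", "AP4", "AP5"), prs),
  n_trials = 13, n_neurons = 150, isi = 8,
  reliability = 0.9, noise_sd = 0.2, p_mix = 0.3)
ne <- simulateExperiment(cfg, seed = 4)
ne
#> NeuromastExperiment: 150 neurons x 1398 frames @ 2.18 Hz
#>   stimulus log: 78 events, 6 distinct conditions (641.0 s recording)
#>   regions: cerebellum=6, MON_contra=2, MON_ipsi=89, OT=4, other=19,
#>            pLLg=6, superior_medulla=15, TS=9
#>   ground truth: present

res  <- detectResponsiveNeurons(ne, n_shuffles = 500, seed = 11)
keep <- rowSums(responsiveMatrix(res)) > 0
sum(keep)
#> [1] 93

tens <- binarizeResponses(ne)
dec  <- trainDecoder(tens[keep, , ], seed = 3)
dec
#> DecoderResult: 6 classes x 93 neurons
#>   cost C = 0.1, test accuracy = 1.000
#>   per-class: AP5=1.00, AP4+AP5=1.00, AP3+AP5=1.00, AP3+AP4=1.00,
#>              AP4=1.00, AP3=1.00

mean(populationSparseness(weightMatrix(dec)))
#> [1] 0.2456249

d <- decomposePair(populationResponseVector(ne[keep, ], "AP3"),
                   populationResponseVector(ne[keep, ], "AP4"),
                   populationResponseVector(ne[keep, ], c("AP3", "AP4")),
                   pair = "AP3+AP4")
d
#> PairDecomposition (AP3+AP4)
#>   alpha = 0.748, beta = 0.783, angle = 7.65 deg, mean R_NL = -0.0058
```

The accuracy of 1.0 reflects the planted code: disjoint, reliable ensembles
are linearly separable. The population sparseness near 0.25 says each
condition's weights are spread over its whole planted ensemble rather than
a single neuron; the decomposition angle of ~8° with α + β near 1.5 says
the paired response lies close to the plane of the single-neuromast
responses — this configuration plants no interaction gain, and the residual
mean near zero agrees.

A full run of every stage, with CSV/JSON artifacts and a run report:

```r
report <- runPipeline(pipelineConfig(experiment = cfg), out_dir = "run1",
                      seed = 4)
```

The methods vignette
(`vignettes/population-coding-methods.Rmd`) documents the models, the
tunable parameters with their defaults and units, the synthetic generator's
assumptions, and the package's numerical choices.

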
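---
title: "Population coding analysis of optogenetic lateral-line stimulation: models and methods"
author: "neuromastCoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population coding analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromastCoding)
```

# The problem

The posterior lateral line of a larval zebrafish is a chain of mechanosensory
organs (neuromasts) along the tail. Stimulating single neuromasts — or pairs
and triplets — while recording whole-brain calcium activity produces, after
segmentation and registration (both upstream of this package), three aligned
objects: a neurons × frames fluorescence matrix sampled at about 2.18
volumes/s, a stimulus log (onset time plus the set of stimulated neuromast
identities per event), and an ROI table (3-D coordinates in registered-atlas
space and a brain-region label per neuron). The scientific questions this
package addresses are how neuromast identity is represented in that activity:
which neurons respond to which organs, whether responses are topographically
organized, how well a linear decoder can read out stimulus identity from
single trials, how sparse and non-overlapping the decoder's weights are,
whether paired stimulation sums linearly, and how strongly different regions
decorrelate the stimulus patterns.

All of these stages are exercised end-to-end on a synthetic generator whose
ground truth is retained, so every recovery claim in the test suite is checked
against planted structure rather than against opinion.

# The data container

`NeuromastExperiment` extends `SummarizedExperiment`: the assay `"traces"`
holds the fluorescence matrix, `rowData` the ROI table, and dedicated slots
carry the stimulus log, the sampling rate and (for synthetic data) the ground
truth. The class validity ties the three together — events must be sorted and
end inside the recording, and the frame count must equal
`ceiling(recording_length * sampling_rate)`. Subsetting rows (`ne[keep, ]`)
restricts the population while keeping the log intact, which is how analyses
are run on responsive subsets.

# The synthetic generator

`simulateExperiment()` draws a complete experiment from an
`experimentConfig()`. Its defaults are the conditions of a typical decoding
session: trunk neuromasts stimulated in randomized order, 20 trials per
condition, 4 s inter-stimulus interval (selectivity-style surveys use 6–10 s
or 60 s cycles; the ISI is a protocol field, not a constant), 2.18 volumes/s,
a few hundred neurons concentrated in the ipsilateral MON, transient
amplitude 2 (arbitrary ΔF/F units) with 20% log-normal spread, trial-to-trial
reliability 0.8, and i.i.d. Gaussian noise with SD 0.3.

Design choices worth stating explicitly:

* **Events are single impulses.** A 50 ms stimulus is sub-frame at 2.18
  volumes/s, so the within-event pulse micro-structure is metadata only. The
  onset frame is `floor(onset_time * sampling_rate)` (0-based), used
  identically by the generator and every analysis.
* **Indicator kernel.** Transients are a peak-normalized double exponential
  with `tau_rise` 0.1 s and `tau_decay` 3 s (the slow nuclear indicator
  regime); the kernel support is truncated at five decay constants.
* **Mixed selectivity decays with distance.** A neuron preferring neuromast
  A is also tuned to B with probability `p_mix * exp(-d / mixing_lambda)`
  where `d` is the rank distance along the body axis. This is the structure
  the conditional-probability analysis is designed to recover.
* **Interactions are multiplicative.** When two or more tuned identities are
  co-stimulated the summed amplitude is multiplied by the planted pair gain
  (triplets: product of constituent pair gains); gain 1 is linear summation,
  2 supra-linear, 0.5 sub-linear.
* **Region coding styles.** MON-like regions code selectively
  (condition-specific ensembles); relay-like regions (TS, OT, superior
  medulla, pLL ganglion by default) share one tuning profile scaled by a
  per-neuron gain. This is the minimal structure that lets the
  decorrelation analysis order regions.
* **Noise.** i.i.d. Gaussian per frame; optional linear drift (a
  photobleaching proxy) and an optional AR(1) coefficient. No autocorrelated
  noise by default.
* **Space.** Isotropic Gaussian clusters: region centers plus, within the
  ipsilateral MON, per-identity subclusters spaced along the body axis
  (default 20 µm spacing, 6 µm SD; terminal-like identities 20 µm SD) —
  same-identity fields at the 10–20 µm scale.

What the generator does *not* emulate: spike-train statistics, indicator
nonlinearity beyond the kernel, motion or segmentation artifacts, and any
anatomy beyond Gaussian clusters. Tests passing on this generator show the
*pipeline* recovers planted structure under its stated assumptions; they are
not evidence about biology.

# Responsiveness

A condition's regressor is the binary onset impulse train convolved with the
indicator kernel. Traces are min-max normalized and Pearson-correlated with
the regressor; significance comes from a null built by placing the same
number of surrogate onsets uniformly without replacement over frames that
keep the kernel inside the recording, repeated 500 times, correlating every
surrogate train with all neurons and fitting a normal to the pooled values.
A neuron is responsive when its statistic is at least 2.5 null SDs above the
null mean (boundary inclusive).

The statistic is Pearson's *r* on both the observed and the null side by
default, with `r_squared` available. With *r*, the flagged fraction on pure
noise matches the normal tail (`1 - pnorm(2.5)` ≈ 0.62%), which the
calibration test checks on 10,000 null neurons; squaring makes the null
distribution a scaled chi-square whose normal fit cuts a different (~3%)
tail, so the two modes are not interchangeable and the package treats *r*
as the calibrated default. Constant (dead) traces are pinned to the
statistic's floor and excluded from null fitting. No multiple-testing
correction is applied across classes; this is a documented limitation of
the procedure.

# Selectivity and topography

Selectivity uses an amplitude criterion: per condition, trial windows from
8 frames before the onset to 3 after are averaged across trials and z-scored;
the mean over the span (one frame before to three after, ≈1.8 s) must exceed
the mean of the median-filtered (4-frame window, shrinking at edges)
pre-onset baseline by 2 baseline SDs. Two numerical choices matter here.
First, the baseline is the *recent* pre-onset segment: with a 3 s indicator
decay, frames further back sit close to the preceding event's transient and
would inflate both the baseline level and its variance. Second, the baseline
SD is taken from the unfiltered baseline samples; the median-filtered curve
sets the level but understates the noise scale. Labels follow the set size:
`single` (one condition), `mixed` (two or more), `nonresponsive`.

The conditional-probability matrix is a counting estimate,
P(B|A) = \|A∩B\|/\|A\|, with unit diagonal and `NA` rows for empty classes;
its rows are deliberately not normalized. Topography statistics: a 1-D
Gaussian KDE (Silverman bandwidth) of coordinate projections; a pairwise
symmetrized Kullback–Leibler divergence between per-identity 3-D point
clouds (Gaussian-KDE plug-in estimator with diagonal Silverman bandwidths
and leave-one-out own-density; a 1-NN estimator is available — the plug-in
was the more accurate of the two on Gaussian benchmarks at n = 1000, within
a few percent of the \|Δµ\|²/2σ² closed form); and a cluster-homogeneity
curve, the probability that a neighbor within a distance bin shares the
query's identity, normalized by the identity's base rate (5 µm bins to
100 µm by default, exact neighbor search, up to 2000 neighbors per query).
Classes with fewer than 10 points are dropped from the KLD matrix.

# Decoding

Trial responses are binarized: 1 when the peak in the four
post-onset-inclusive frames (1.8 s) is at least 2 SDs above the per-trial
mean of the 4 pre-onset baseline frames. The resulting neurons × trials ×
conditions tensor feeds a multiclass linear SVM (one-vs-rest, which is what
yields the classes × neurons weight matrix the sparseness analysis needs):
stratified 80/20 split, 10-fold cross-validation on the training split over
10 log-spaced costs in [0.1, 10], fold weights averaged at the selected
cost, accuracy and a row-normalized confusion matrix reported on the
untouched test split. Prediction ties resolve to the lowest class index;
cost ties to the smaller cost. The SVM is L2-penalized (libsvm via e1071);
weights below 1e-8 of the maximum magnitude are treated as exact zeros for
support-set analyses, and an L1-regularized logistic one-vs-rest mode is
available when genuinely sparse solutions are wanted.

Boolean composition (AND/OR/XOR of single-condition binarized vectors,
trials paired by index with seeded random completion when counts differ)
asks whether paired-stimulus responses are predictable from their
components: the composed decoder is trained on composed vectors and tested
on real pair trials, against a control trained on the pair trials
themselves. Firing statistics (probability over responsive neurons × trials,
responsive-set sizes, Welch t-tests between condition groups) quantify
recruitment as stimulus complexity grows.

# Nonlinear summation

For conditions A, B and their pair (A,B), per-neuron response vectors are
the maxima over the four post-onset frames of the trial-averaged, min-max
normalized traces. The paired response is decomposed as
R(A,B) = α·R(A,0) + β·R(0,B) + R_NL(A,B) with α, β restricted to [-1, 1];
the convex box problem is solved exactly by enumerating the unconstrained
optimum, the clamped edges and the corners, so there are no iterative
tolerances and the reconstruction identity holds to machine precision. The
angle between R(A,B) and the component plane is
asin(‖R_NL‖/‖R(A,B)‖) in degrees — 0 for an in-plane (linear) response,
90 for an orthogonal one; the unconstrained-projection angle is kept as a
diagnostic. Null controls decompose scrambled (neuron-permuted) paired
responses, or pair responses against the *other* pairs' components.

Two caveats the tests made explicit. First, min-max normalization leaves a
noise floor (the baseline maps to roughly 3σ/range, not to 0), so even
planted-linear data produce a few degrees of angle; the linear-recovery test
therefore runs at high SNR. Second, the *mean* residual is a population
summary whose sign reflects the planted interaction only when the jointly
tuned subpopulation is sizeable: the bounded fit redistributes residual mass
between that subpopulation and the single-tuned majority, and for sub-linear
gains the compromise coefficients can leave the mean slightly positive even
though the jointly tuned neurons themselves carry strongly negative
residuals. The per-neuron residual footprint (positive ≈ +0.4 under gain 2,
negative ≈ -0.5 under gain 0.5 on the planted subpopulation) is the robust
recovery signature and is what the module tests assert; supra/sub neuron
sets are thresholded on z-scored residuals by default because the raw
residual scale depends on normalization (threshold units are configurable).

# Trajectories and decorrelation

Trial-averaged peri-stimulus windows (4 s before and after the onset) are
concatenated across conditions, z-scored per neuron and decomposed by SVD.
The leading component carries the stimulus-unspecific transient and is
excluded; components 2–4 (1-based) are reported with their variance
fractions, smoothed with a 1-frame Gaussian for visualization.

Pattern decorrelation: per region, the Pearson correlation between
condition-mean population vectors (mean amplitude over the four post-onset
frames of the trial-averaged trace — the mean, not the peak, is used here;
the peak is used in binarization, and the choice is configurable) for every
pair of conditions. Regions with fewer than 3 neurons are undefined. The
subsampling control redraws 200 neurons per region 1000 times and averages
the matrices; regions below the gate are excluded by default (or sampled
with replacement on request). The decorrelation index is the mean
off-diagonal correlation, and across-sample region comparisons use a paired
Wilcoxon signed-rank test by default (Welch t available).

# Orchestration

`runPipeline()` chains simulate → responsiveness → selectivity/topography →
decoding → weight metrics → nonlinearity (when a pair condition and both of
its singles are present; otherwise the stage is skipped with a reason) →
trajectories/decorrelation, writing labeled CSVs, a resolved-config YAML
with a config hash, and a machine-readable JSON run report. All randomness
is derived from the master seed; a rerun with the same config and seed
produces byte-identical CSVs. The on-disk bundle format is a plain CSV trio
(traces, stimulus log, ROI table) plus a YAML sidecar, with the ground
truth as an optional subdirectory — `readBundle()` validates the invariants
and names the first violation.

# Problem sizes and limitations

The test suite and the worked examples run at deliberately modest sizes —
hundreds of neurons, 10–20 trials per condition, a handful of conditions —
chosen so that every recovery statement can be checked against planted
ground truth in seconds while remaining in the regime the analyses assume
(more trials than folds, more neurons than conditions). The calibration
test uses 10,000 null neurons because a 0.6% tail rate needs that many for
a stable estimate.

Known limitations: responsiveness detection by regressor correlation
penalizes neurons that respond to nearly every condition (their correlation
with any single regressor is diluted), which is why recovery tests that
need the jointly tuned subpopulation select it from ground truth rather
than through detection; selectivity requires protocols with pre-onset
baselines clear of the preceding transient (6–10 s gaps; at a 4 s ISI with
a 3 s decay no window is truly clean); and the headline numbers from real
imaging data depend on biological effect sizes the generator does not claim
to reproduce — the package's quantitative guarantees are the analytic
limiting values and the planted-structure recoveries exercised in
`tests/testthat/test-acceptance.R`.
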
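#' Spatial layout parameters for synthetic ROI tables
#'
#' Neurons are placed in isotropic Gaussian clusters. Every region has a
#' center and an overall spread; within the ipsilateral MON, neurons that
#' prefer the same neuromast are additionally grouped into per-identity
#' subclusters spaced along a body-axis direction, emulating the 10-20 um
#' same-identity fields seen in registered data. Terminal-like identities
#' can be given a larger spread than trunk identities.
#'
#' @param region_centers named list or 3-column matrix of region centers in
#'   um (registered-atlas space); defaults cover the standard region
#'   vocabulary.
#' @param region_sd within-region spread (um) outside identity subclusters.
#' @param class_spacing distance between neighboring identity subcluster
#'   centers in the MON (um).
#' @param cluster_sd subcluster spread for trunk identities (um).
#' @param terminal_sd subcluster spread for terminal-like identities (um).
#' @param class_axis unit direction along which identity subclusters are laid
#'   out.
#' @return an object of class \code{"SpatialParams"}.
#' @export
spatialParams <- function(region_centers = NULL, region_sd = 30,
                          class_spacing = 20, cluster_sd = 6,
                          terminal_sd = 20, class_axis = c(1, 0, 0)) {
  if (is.null(region_centers)) {
    region_centers <- rbind(
      MON_ipsi = c(0, 0, 0),
      MON_contra = c(0, 120, 0),
      cerebellum = c(-120, 0, 40),
      TS = c(-200, 60, 60),
      OT = c(-260, 0, 80),
      superior_medulla = c(60, 80, -20),
      pLLg = c(200, 0, -40),
      other = c(0, -150, 0)
    )
  }
  region_centers <- as.matrix(region_centers)
  .assert(ncol(region_centers) == 3, "region centers must be 3-D")
  .assert(region_sd >= 0 && cluster_sd >= 0 && terminal_sd >= 0 &&
            class_spacing >= 0, "spatial scales must be nonnegative")
  class_axis <- class_axis / sqrt(sum(class_axis^2))
  structure(list(region_centers = region_centers, region_sd = region_sd,
                 class_spacing = class_spacing, cluster_sd = cluster_sd,
                 terminal_sd = terminal_sd, class_axis = class_axis),
            class = "SpatialParams")
}

#' Configuration of a synthetic stimulation experiment
#'
#' Defaults describe a typical decoding session: four trunk neuromasts
#' stimulated singly in randomized order, 20 trials per condition at a 4 s
#' inter-stimulus interval, imaging at 2.18 volumes/s, a few hundred
#' segmented neurons concentrated in the ipsilateral MON, trial-to-trial
#' response reliability of 0.8 and additive Gaussian noise. Mixed
#' selectivity is planted with a probability that decays exponentially with
#' the distance between neuromasts along the body axis
#' (\code{p_mix * exp(-d / mixing_lambda)}, \code{d} in body-axis rank
#' units). Pairwise interaction gains plant supra- (\code{> 1}) or
#' sub-linear (\code{< 1}) summation for jointly stimulated tuned pairs.
#' Regions can code selectively (condition-specific ensembles, the MON-like
#' default) or with a shared gain profile in which every neuron follows the
#' same condition tuning up to a scalar (relay-like regions downstream of
#' the MON).
#'
#' @param universe ordered identity labels, head to tail.
#' @param combinations list of stimulated identity sets.
#' @param n_trials,isi,randomize,pre_time,post_time protocol layout; see
#'   \code{\link{buildStimulusProtocol}}.
#' @param sampling_rate volumes per second.
#' @param n_neurons number of segmented neurons.
#' @param region_props named proportions over region labels.
#' @param frac_responsive fraction of neurons tuned to at least one
#'   stimulated identity.
#' @param tuned_classes identities available as preferred classes; defaults
#'   to all identities appearing in \code{combinations}.
#' @param p_mix,mixing_lambda mixed-selectivity probability scale and decay
#'   length (body-axis rank units).
#' @param amplitude,amplitude_cv mean transient amplitude (a.u. Delta F/F)
#'   and log-normal coefficient of variation across neurons.
#' @param reliability probability that a preferred stimulus elicits a
#'   transient on a given trial.
#' @param noise_sd per-frame Gaussian noise standard deviation.
#' @param drift total linear baseline drift over the recording (a.u.;
#'   photobleaching proxy), 0 to disable.
#' @param ar_coef optional AR(1) coefficient for temporally correlated
#'   noise; 0 (default) gives i.i.d. noise.
#' @param pair_gain named numeric of multiplicative interaction gains,
#'   names are pair labels such as \code{"AP3+AP4"}; unlisted pairs get 1
#'   (linear). Triplet gains default to the product of constituent pair
#'   gains.
#' @param region_coding named character, \code{"selective"} or
#'   \code{"shared"} per region; unlisted regions are selective.
#' @param shared_gain_range uniform range of per-neuron gains in shared
#'   regions.
#' @param kernel \code{\link{kernelParams}}.
#' @param spatial \code{\link{spatialParams}}.
#' @param terminal_classes identities treated as terminal-like for spatial
#'   spread.
#' @return an object of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(
    universe = c("AP1", "DV1", "DV2", "DV3", "AP2", "AP3", "AP4", "AP5",
                 "AP6", "Ter"),
    combinations = list("AP2", "AP3", "AP4", "AP5"),
    n_trials = 20, isi = 4, randomize = TRUE, pre_time = 10, post_time = 15,
    sampling_rate = 2.18,
    n_neurons = 400,
    region_props = c(MON_ipsi = 0.55, MON_contra = 0.02, cerebellum = 0.05,
                     TS = 0.05, OT = 0.05, superior_medulla = 0.08,
                     pLLg = 0.05, other = 0.15),
    frac_responsive = 0.6, tuned_classes = NULL,
    p_mix = 0.3, mixing_lambda = 1.5,
    amplitude = 2, amplitude_cv = 0.2,
    reliability = 0.8, noise_sd = 0.3, drift = 0, ar_coef = 0,
    pair_gain = numeric(0),
    region_coding = c(TS = "shared", OT = "shared",
                      superior_medulla = "shared", pLLg = "shared"),
    shared_gain_range = c(0.5, 1.5),
    kernel = kernelParams(), spatial = spatialParams(),
    terminal_classes = c("AP6", "Ter")) {
  cfg <- as.list(environment())
  .assert(length(cfg$combinations) > 0, "config field 'combinations': empty")
  all_classes <- unique(unlist(cfg$combinations))
  bad <- setdiff(all_classes, cfg$universe)
  .assert(length(bad) == 0, "config field 'combinations': identities outside universe: ",
          paste(bad, collapse = ", "))
  if (is.null(cfg$tuned_classes)) cfg$tuned_classes <- all_classes
  .assert(all(cfg$tuned_classes %in% cfg$universe),
          "config field 'tuned_classes': outside universe")
  .assert(cfg$n_neurons >= 1, "config field 'n_neurons': must be >= 1")
  .assert(all(names(cfg$region_props) %in% .REGIONS),
          "config field 'region_props': unknown region label")
  .assert(all(cfg$region_props >= 0) && sum(cfg$region_props) > 0,
          "config field 'region_props': must be nonnegative, not all zero")
  .assert(cfg$frac_responsive >= 0 && cfg$frac_responsive <= 1,
          "config field 'frac_responsive': must lie in [0, 1]")
  .assert(cfg$reliability >= 0 && cfg$reliability <= 1,
          "config field 'reliability': must lie in [0, 1]")
  .assert(cfg$amplitude >= 0, "config field 'amplitude': must be >= 0")
  .assert(cfg$noise_sd >= 0, "config field 'noise_sd': must be >= 0")
  .assert(all(cfg$pair_gain > 0), "config field 'pair_gain': must be > 0")
  .assert(all(cfg$region_coding %in% c("selective", "shared")),
          "config field 'region_coding': values must be 'selective' or 'shared'")
  .assert(abs(cfg$ar_coef) < 1, "config field 'ar_coef': |ar| must be < 1")
  .assert(inherits(cfg$kernel, "KernelParams"),
          "config field 'kernel': must be kernelParams()")
  .assert(inherits(cfg$spatial, "SpatialParams"),
          "config field 'spatial': must be spatialParams()")
  structure(cfg, class = "ExperimentConfig")
}

# Plant tuning, reliability and noise parameters for every neuron.
# Consumes RNG; callers fix the seed.
.assignTuning <- function(cfg) {
  n <- cfg$n_neurons
  universe <- cfg$universe
  props <- cfg$region_props / sum(cfg$region_props)
  region <- sample(names(props), n, replace = TRUE, prob = props)
  coding <- setNames(rep("selective", length(props)), names(props))
  coding[names(cfg$region_coding)] <- cfg$region_coding
  responsive <- runif(n) < cfg$frac_responsive
  amp <- cfg$amplitude * exp(rnorm(n, 0, cfg$amplitude_cv))
  tuning <- matrix(0, n, length(universe), dimnames = list(NULL, universe))
  preferred <- rep(NA_character_, n)
  ranks <- match(cfg$tuned_classes, universe)
  pref_draw <- sample(cfg$tuned_classes, n, replace = TRUE)
  mix_draw <- matrix(runif(n * length(cfg$tuned_classes)), n)
  gain_draw <- runif(n, cfg$shared_gain_range[1], cfg$shared_gain_range[2])
  for (i in seq_len(n)) {
    if (!responsive[i]) next
    if (coding[region[i]] == "shared") {
      tuning[i, cfg$tuned_classes] <- gain_draw[i] * cfg$amplitude
      next
    }
    preferred[i] <- pref_draw[i]
    tuning[i, preferred[i]] <- amp[i]
    d <- abs(ranks - match(preferred[i], universe))
    extra <- cfg$tuned_classes[d > 0 &
                                 mix_draw[i, ] < cfg$p_mix * exp(-d / cfg$mixing_lambda)]
    tuning[i, extra] <- amp[i]
  }
  list(tuning = tuning,
       reliability = rep(cfg$reliability, n),
       noise_sd = rep(cfg$noise_sd, n),
       preferred = preferred,
       region = region,
       pair_gain = cfg$pair_gain)
}

#' Sample ROI coordinates for planted ground truth
#'
#' @param ground_truth list with elements \code{region} and \code{preferred}
#'   (per neuron), as produced inside \code{\link{simulateExperiment}}.
#' @param spatial \code{\link{spatialParams}}.
#' @param universe ordered identity labels (for subcluster placement).
#' @param terminal_classes identities given the terminal spread.
#' @param seed integer seed or \code{NULL}.
#' @return data.frame with columns \code{x_um}, \code{y_um}, \code{z_um},
#'   \code{region}.
#' @export
sampleRoiCoordinates <- function(ground_truth, spatial = spatialParams(),
                                 universe, terminal_classes = c("AP6", "Ter"),
                                 seed = NULL) {
  region <- ground_truth$region
  preferred <- ground_truth$preferred
  .assert(!is.null(region) && length(region) == length(preferred),
          "ground truth must assign a region to every neuron")
  missing <- setdiff(unique(region), rownames(spatial$region_centers))
  .assert(length(missing) == 0,
          "missing cluster parameters for region(s): ",
          paste(missing, collapse = ", "))
  n <- length(region)
  .withSeed(seed, {
    centers <- spatial$region_centers[region, , drop = FALSE]
    sds <- rep(spatial$region_sd, n)
    sub <- region == "MON_ipsi" & !is.na(preferred)
    if (any(sub)) {
      rk <- match(preferred[sub], universe)
      .assert(!anyNA(rk), "preferred identity outside universe")
      offset <- (rk - (length(universe) + 1) / 2) * spatial$class_spacing
      centers[sub, ] <- centers[sub, , drop = FALSE] +
        outer(offset, spatial$class_axis)
      sds[sub] <- ifelse(preferred[sub] %in% terminal_classes,
                         spatial$terminal_sd, spatial$cluster_sd)
    }
    xyz <- centers + matrix(rnorm(3 * n, 0, rep(sds, 3)), n, 3)
    data.frame(x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
               region = region, stringsAsFactors = FALSE)
  })
}

#' Render fluorescence traces from planted ground truth
#'
#' Forward model: for every stimulus event and neuron, with probability
#' equal to the neuron's reliability, a calcium transient is added at the
#' event's onset frame. The transient is the peak-normalized double
#' exponential kernel scaled by the summed amplitudes of the neuron's tuned
#' identities present in the event; when two or more tuned identities are
#' co-stimulated the amplitude is multiplied by the planted interaction
#' gain (product of constituent pair gains). Gaussian noise (optionally
#' AR(1)) and an optional linear drift are added.
#'
#' @param ground_truth list with \code{tuning}, \code{reliability},
#'   \code{noise_sd}, \code{pair_gain}.
#' @param log stimulus log.
#' @param kernel \code{\link{kernelParams}}.
#' @param sampling_rate frames per second.
#' @param drift total linear drift over the recording (a.u.).
#' @param ar_coef AR(1) noise coefficient; 0 for i.i.d. noise.
#' @param seed integer seed or \code{NULL}.
#' @return neurons x frames numeric matrix.
#' @export
renderTraces <- function(ground_truth, log, kernel = kernelParams(),
                         sampling_rate = 2.18, drift = 0, ar_coef = 0,
                         seed = NULL) {
  tuning <- ground_truth$tuning
  n <- nrow(tuning)
  universe <- attr(log, "universe")
  len <- attr(log, "recording_length")
  .assert(!is.null(len), "stimulus log lacks a recording_length")
  .assert(all(log$onset_time + log$duration <= len),
          "stimulus events extend past the end of the recording")
  n_frames <- as.integer(ceiling(len * sampling_rate))
  kv <- calciumKernel(kernel, sampling_rate)
  onset_idx <- .onsetIndex(log$onset_time, sampling_rate)
  .assert(all(onset_idx <= n_frames), "event onset beyond the trace matrix")
  pg <- ground_truth$pair_gain %||% numeric(0)
  rel <- ground_truth$reliability
  nsd <- ground_truth$noise_sd
  .withSeed(seed, {
    fire_draw <- matrix(runif(nrow(log) * n), nrow(log), n)
    x <- matrix(0, n, n_frames)
    for (e in seq_len(nrow(log))) {
      cls <- .parseLabel(log$label[e])
      sub <- tuning[, cls, drop = FALSE]
      amp <- rowSums(sub)
      ntuned <- rowSums(sub > 0)
      multi <- which(ntuned >= 2)
      if (length(pg) && length(multi)) {
        for (i in multi) {
          active <- cls[sub[i, ] > 0]
          prs <- utils::combn(active, 2, simplify = FALSE)
          g <- vapply(prs, function(p) {
            v <- pg[.classLabel(p, universe)]
            if (is.na(v)) 1 else v
          }, numeric(1))
          amp[i] <- amp[i] * prod(g)
        }
      } else if (length(multi)) {
        # no planted interactions: linear summation
      }
      w <- amp * (fire_draw[e, ] < rel)
      nz <- which(w > 0)
      if (!length(nz)) next
      cols <- onset_idx[e]:min(n_frames, onset_idx[e] + length(kv) - 1L)
      x[nz, cols] <- x[nz, cols] +
        outer(w[nz], kv[seq_along(cols)])
    }
    noise <- matrix(rnorm(n * n_frames), n, n_frames) * nsd
    if (ar_coef != 0) {
      noise <- t(apply(noise, 1, function(row) {
        as.numeric(stats::filter(row, ar_coef, method = "recursive"))
      })) * sqrt(1 - ar_coef^2)
    }
    x <- x + noise
    if (drift != 0)
      x <- x + matrix(drift * seq(0, 1, length.out = n_frames),
                      n, n_frames, byrow = TRUE)
    x
  })
}

#' Generate a complete synthetic experiment
#'
#' Produces a mutually consistent bundle -- traces, stimulus log, ROI table
#' and planted ground truth -- wrapped in a
#' \linkS4class{NeuromastExperiment}. Identical \code{(config, seed)} pairs
#' give bit-identical results.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param seed integer seed.
#' @return a \linkS4class{NeuromastExperiment} whose \code{groundTruth()}
#'   holds the planted parameters.
#' @examples
#' ne <- simulateExperiment(experimentConfig(n_neurons = 50, n_trials = 3),
#'                          seed = 1)
#' ne
#' @export
simulateExperiment <- function(config = experimentConfig(), seed = 1) {
  .assert(inherits(config, "ExperimentConfig"),
          "config must be created with experimentConfig()")
  .withSeed(seed, {
    log <- buildStimulusProtocol(config$universe, config$combinations,
                                 n_trials = config$n_trials, isi = config$isi,
                                 randomize = config$randomize,
                                 sampling_rate = config$sampling_rate,
                                 pre_time = config$pre_time,
                                 post_time = config$post_time)
    gt <- .assignTuning(config)
    roi <- sampleRoiCoordinates(gt, config$spatial, config$universe,
                                config$terminal_classes)
    x <- renderTraces(gt, log, config$kernel, config$sampling_rate,
                      drift = config$drift, ar_coef = config$ar_coef)
    ne <- NeuromastExperiment(x, config$sampling_rate, log,
                              roi, groundTruth = gt)
    metadata(ne)$config <- config
    ne
  })
}
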
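#' Build a balanced optogenetic stimulation protocol
#'
#' Lays out \code{n_trials} trial blocks; within each block every requested
#' identity combination occurs exactly once, separated by a fixed
#' inter-stimulus interval. With \code{randomize = TRUE} the order within
#' each block is shuffled independently (the multiset of conditions per
#' block is preserved), mirroring randomized stimulus order in decoding
#' experiments. Stimuli are 50 ms light exposures; at ~2.18 volumes/s a
#' stimulus is sub-frame, so each event is treated as a single impulse and
#' the duration is kept as metadata.
#'
#' @param universe ordered character vector of neuromast identity labels
#'   (head-to-tail body axis order), e.g.
#'   \code{c("AP1","DV1","DV2","DV3","AP2",...)}.
#' @param combinations list of identity sets (character vectors), each a
#'   subset of \code{universe}.
#' @param n_trials trials per combination.
#' @param isi inter-stimulus interval between consecutive onsets, seconds.
#' @param randomize shuffle condition order within each trial block.
#' @param seed integer seed for the shuffle (ignored when
#'   \code{randomize = FALSE}).
#' @param duration stimulus duration in seconds (default 0.05).
#' @param sampling_rate used only to check that \code{isi} spans at least
#'   one frame.
#' @param pre_time silence before the first event, seconds (default 0;
#'   simulated experiments use 10 s so that pre-onset baselines exist).
#' @param post_time silence appended after the last event, seconds; default
#'   15 s, enough for one kernel decay.
#' @return the stimulus log: a \code{data.frame} with columns
#'   \code{onset_time}, \code{label}, \code{duration} and attributes
#'   \code{universe} and \code{recording_length}.
#' @examples
#' log <- buildStimulusProtocol(c("AP3", "AP4", "AP5"),
#'                              list("AP3", "AP4", "AP5"),
#'                              n_trials = 2, isi = 4, randomize = FALSE)
#' log$onset_time   # 0, 4, 8, ... 20
#' @export
buildStimulusProtocol <- function(universe, combinations, n_trials, isi,
                                  randomize = TRUE, seed = NULL,
                                  duration = 0.05, sampling_rate = 2.18,
                                  pre_time = 0, post_time = 15) {
  .assert(length(universe) >= 1 && !anyDuplicated(universe),
          "universe must be a non-empty set of unique identity labels")
  .assert(is.list(combinations) && length(combinations) > 0,
          "combinations must be a non-empty list of identity sets")
  .assert(length(n_trials) == 1 && n_trials >= 1 && n_trials == round(n_trials),
          "n_trials must be a positive integer")
  .assert(isi >= 1 / sampling_rate,
          sprintf("isi (%.3f s) must span at least one frame (%.3f s)",
                  isi, 1 / sampling_rate))
  labels <- vapply(combinations, .classLabel, character(1), universe = universe)
  .assert(!anyDuplicated(labels), "duplicate combinations in protocol")
  n_comb <- length(labels)
  order_mat <- .withSeed(seed, {
    vapply(seq_len(n_trials), function(i) {
      if (randomize) sample.int(n_comb) else seq_len(n_comb)
    }, integer(n_comb))
  })
  order_mat <- matrix(order_mat, nrow = n_comb)
  seq_labels <- labels[as.vector(order_mat)]
  onsets <- pre_time + (seq_along(seq_labels) - 1) * isi
  log <- data.frame(onset_time = onsets, label = seq_labels,
                    duration = duration, stringsAsFactors = FALSE)
  attr(log, "universe") <- as.character(universe)
  attr(log, "recording_length") <- max(onsets) + post_time
  log
}

#' Tabulate stimulus conditions in a log
#'
#' @param log a stimulus log.
#' @return named integer vector of event counts per condition label.
#' @export
stimulusCounts <- function(log) {
  tab <- table(log$label)
  setNames(as.integer(tab), names(tab))
}

# events whose class set equals class_set (set equality, order-free)
.matchEvents <- function(log, class_set) {
  target <- .classLabel(class_set, attr(log, "universe"))
  which(log$label == target)
}
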
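# On-disk bundle format: plain CSV files plus a YAML sidecar.
#
#   traces.csv        neuron_id + one column per frame (f00001, ...)
#   stimulus_log.csv  onset_time, label, duration
#   roi.csv           neuron_id, x_um, y_um, z_um, region
#   meta.yaml         sampling_rate, universe, recording_length, shapes
#   ground_truth/     tuning.csv, params.csv, pair_gain.csv (synthetic only)

#' Write an experiment bundle to a directory
#'
#' @param ne a \linkS4class{NeuromastExperiment}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(ne, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- traces(ne)
  tr <- data.frame(neuron_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(tr) <- c("neuron_id", sprintf("f%05d", seq_len(ncol(x))))
  write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  log <- stimulusLog(ne)
  write.csv(log[, c("onset_time", "label", "duration")],
            file.path(dir, "stimulus_log.csv"), row.names = FALSE)
  roi <- roiTable(ne)
  write.csv(data.frame(neuron_id = rownames(x),
                       roi[, c("x_um", "y_um", "z_um", "region")],
                       stringsAsFactors = FALSE),
            file.path(dir, "roi.csv"), row.names = FALSE)
  meta <- list(format_version = 1L,
               sampling_rate = samplingRate(ne),
               universe = as.list(neuromastUniverse(ne)),
               recording_length = recordingLength(ne),
               n_neurons = nrow(x), n_frames = ncol(x))
  writeLines(yaml::as.yaml(meta), file.path(dir, "meta.yaml"))
  gt <- groundTruth(ne)
  if (length(gt)) {
    gdir <- file.path(dir, "ground_truth")
    dir.create(gdir, showWarnings = FALSE)
    write.csv(data.frame(neuron_id = rownames(x), gt$tuning,
                         check.names = FALSE),
              file.path(gdir, "tuning.csv"), row.names = FALSE)
    write.csv(data.frame(neuron_id = rownames(x),
                         reliability = gt$reliability,
                         noise_sd = gt$noise_sd,
                         preferred = ifelse(is.na(gt$preferred), "",
                                            gt$preferred),
                         region = gt$region, stringsAsFactors = FALSE),
              file.path(gdir, "params.csv"), row.names = FALSE)
    pg <- gt$pair_gain %||% numeric(0)
    write.csv(data.frame(pair = names(pg), gain = as.numeric(pg),
                         stringsAsFactors = FALSE),
              file.path(gdir, "pair_gain.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read an experiment bundle from a directory
#'
#' Loads and cross-validates the CSV/YAML bundle written by
#' \code{\link{writeBundle}} (or assembled by hand for real data; the
#' ground-truth directory is optional). The first violated invariant is
#' reported by name.
#'
#' @param dir bundle directory.
#' @return a \linkS4class{NeuromastExperiment}.
#' @export
readBundle <- function(dir) {
  need <- c("traces.csv", "stimulus_log.csv", "roi.csv", "meta.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  .assert(length(missing) == 0,
          "bundle is missing file(s): ", paste(missing, collapse = ", "))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  tr <- read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  x <- as.matrix(tr[, -1, drop = FALSE])
  dimnames(x) <- list(tr$neuron_id, NULL)
  .assert(nrow(x) == meta$n_neurons && ncol(x) == meta$n_frames,
          sprintf("trace matrix shape mismatch: file is %d x %d, meta.yaml says %d x %d",
                  nrow(x), ncol(x), meta$n_neurons, meta$n_frames))
  log <- read.csv(file.path(dir, "stimulus_log.csv"),
                  stringsAsFactors = FALSE)
  attr(log, "universe") <- unlist(meta$universe)
  attr(log, "recording_length") <- meta$recording_length
  roi <- read.csv(file.path(dir, "roi.csv"), stringsAsFactors = FALSE)
  .assert(identical(roi$neuron_id, rownames(x)),
          "roi.csv neuron ordering differs from traces.csv")
  gt <- list()
  gdir <- file.path(dir, "ground_truth")
  if (dir.exists(gdir)) {
    tun <- read.csv(file.path(gdir, "tuning.csv"), check.names = FALSE)
    par <- read.csv(file.path(gdir, "params.csv"), stringsAsFactors = FALSE)
    pg <- read.csv(file.path(gdir, "pair_gain.csv"),
                   stringsAsFactors = FALSE)
    gt <- list(tuning = {
      m <- as.matrix(tun[, -1, drop = FALSE])
      rownames(m) <- NULL
      m
    },
    reliability = par$reliability,
    noise_sd = par$noise_sd,
    preferred = ifelse(par$preferred == "", NA_character_, par$preferred),
    region = par$region,
    pair_gain = setNames(pg$gain, pg$pair))
  }
  NeuromastExperiment(x, meta$sampling_rate, log,
                      roi[, c("x_um", "y_um", "z_um", "region")],
                      groundTruth = gt)
}
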
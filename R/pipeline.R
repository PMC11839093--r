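# End-to-end orchestration of the analysis stages.

# provenance stamp: order-sensitive checksum of the serialized config
.configHash <- function(cfg) {
  b <- as.integer(serialize(cfg, NULL, version = 2))
  sprintf("%08x",
          sum((b + 1) * (seq_along(b) %% 9973)) %% .Machine$integer.max)
}

# strip classes / matrices so the resolved config survives a YAML round trip
.configToList <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 1, as.list, simplify = FALSE)
    return(out)
  }
  if (is.list(x)) return(lapply(unclass(x), .configToList))
  if (is.function(x)) return(NULL)
  x
}

#' Pipeline configuration
#'
#' Bundles the stage parameters with their defaults. Unknown keys are
#' rejected (arguments are matched exactly).
#'
#' @param experiment an \code{\link{experimentConfig}} describing the
#'   synthetic experiment to simulate (ignored when \code{ne} is passed to
#'   \code{\link{runPipeline}}).
#' @param n_shuffles,k_sd_responsive,statistic responsiveness stage.
#' @param k_sd_selectivity selectivity amplitude criterion.
#' @param k_sd_binarize binarization threshold.
#' @param test_fraction,n_folds decoder protocol.
#' @param min_neurons decoder population gate (\code{NULL} disables).
#' @param homogeneity_bin,homogeneity_radius cluster homogeneity binning
#'   (um).
#' @param kld_min_points minimum class size for the KLD matrix.
#' @param window_s PCA peri-stimulus half window (seconds).
#' @param n_subsample,n_iter decorrelation subsampling control.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(experiment = experimentConfig(),
                           n_shuffles = 500, k_sd_responsive = 2.5,
                           statistic = "r",
                           k_sd_selectivity = 2, k_sd_binarize = 2,
                           test_fraction = 0.2, n_folds = 10,
                           min_neurons = NULL,
                           homogeneity_bin = 5, homogeneity_radius = 100,
                           kld_min_points = 10,
                           window_s = 4, n_subsample = 200, n_iter = 1000) {
  cfg <- as.list(environment())
  .assert(inherits(cfg$experiment, "ExperimentConfig"),
          "experiment must be an experimentConfig()")
  structure(cfg, class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) an experiment and chains the stages:
#' responsiveness detection, selectivity and topography, decoding, weight
#' metrics, nonlinear summation (when a pair condition and both of its
#' single conditions are present), and PC trajectories plus region
#' decorrelation. All artifacts are written as labeled CSV/JSON files
#' stamped with the resolved-config hash; a stage failure halts the run
#' with a stage-scoped error while earlier outputs are retained.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param out_dir output directory.
#' @param seed integer master seed; stage seeds are derived from it.
#' @param ne optional pre-built \linkS4class{NeuromastExperiment} (real
#'   data); when omitted the experiment is simulated from
#'   \code{config$experiment}.
#' @return the run report (list of class \code{"RunReport"}), invisibly
#'   written to \code{report.json}.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir, seed = 1,
                        ne = NULL) {
  .assert(inherits(config, "PipelineConfig"),
          "config must come from pipelineConfig()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  hash <- .configHash(config)
  writeLines(yaml::as.yaml(list(config = .configToList(config),
                                seed = seed, config_hash = hash)),
             file.path(out_dir, "config.yaml"))
  stages <- list()
  note <- function(name, status, metrics = list(), reason = NULL) {
    stages[[name]] <<- c(list(status = status),
                         if (!is.null(reason)) list(reason = reason),
                         if (length(metrics)) list(metrics = metrics))
  }
  wcsv <- function(obj, name) {
    f <- file.path(out_dir, name)
    write.csv(obj, f, row.names = !is.null(rownames(obj)) &&
                !is.data.frame(obj))
    f
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note(name, "failed", reason = conditionMessage(e))
      report <- structure(list(stages = stages, seed = seed,
                               config_hash = hash,
                               wall_time_s = proc.time()[["elapsed"]] - t0),
                          class = "RunReport")
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  if (is.null(ne)) {
    ne <- run_stage("simulate", simulateExperiment(config$experiment, seed))
    note("simulate", "ok", list(n_neurons = nrow(ne), n_frames = ncol(ne),
                                n_events = nrow(stimulusLog(ne))))
  } else {
    note("simulate", "skipped", reason = "experiment supplied by caller")
  }
  log <- stimulusLog(ne)
  universe <- neuromastUniverse(ne)
  conditions <- lapply(unique(log$label), .parseLabel)
  singles <- conditions[lengths(conditions) == 1]

  # -- responsiveness ------------------------------------------------------
  resp <- run_stage("responsiveness", {
    r <- detectResponsiveNeurons(ne, conditions,
                                 statistic = config$statistic,
                                 n_shuffles = config$n_shuffles,
                                 k_sd = config$k_sd_responsive,
                                 seed = seed + 100L)
    wcsv(r, "responsiveness.csv")
    r
  })
  rmat <- responsiveMatrix(resp)
  resp_any <- rowSums(rmat) > 0
  region <- as.character(rowData(ne)$region)
  note("responsiveness", "ok",
       list(n_responsive = sum(resp_any),
            per_region = as.list(table(region[resp_any]))))

  # -- selectivity & topography -------------------------------------------
  sel <- run_stage("selectivity", {
    s <- classifySelectivity(ne, singles, k_sd = config$k_sd_selectivity)
    wcsv(s, "selectivity.csv")
    cp <- conditionalProbabilityMatrix(s)
    write.csv(cp, file.path(out_dir, "conditional_probability.csv"))
    s
  })
  note("selectivity", "ok",
       list(single = sum(sel$label == "single"),
            mixed = sum(sel$label == "mixed")))
  run_stage("topography", {
    member <- attr(sel, "membership")
    single_pref <- ifelse(sel$label == "single", sel$classes, NA_character_)
    hom <- clusterHomogeneity(roiTable(ne), single_pref,
                              bin_width = config$homogeneity_bin,
                              max_radius = config$homogeneity_radius)
    wcsv(hom, "homogeneity.csv")
    sets <- split(seq_len(nrow(ne)), single_pref)
    sets <- lapply(sets, function(i)
      as.matrix(roiTable(ne)[i, c("x_um", "y_um", "z_um")]))
    sizes <- vapply(sets, nrow, integer(1))
    if (sum(sizes >= config$kld_min_points) >= 2) {
      kld <- suppressMessages(pairwiseKLD(sets, config$kld_min_points))
      write.csv(kld, file.path(out_dir, "kld.csv"))
      note("topography", "ok", list(n_classes_kld = nrow(kld)))
    } else {
      note("topography", "ok",
           list(n_classes_kld = 0),
           reason = "too few sufficiently large classes for the KLD matrix")
    }
  })

  # -- decoding ------------------------------------------------------------
  decoder <- NULL
  if (sum(resp_any) >= 2) {
    decoder <- run_stage("decoding", {
      tensor <- binarizeResponses(ne, conditions,
                                  k_sd = config$k_sd_binarize)
      d <- trainDecoder(tensor[resp_any, , , drop = FALSE],
                        test_fraction = config$test_fraction,
                        n_folds = config$n_folds,
                        min_neurons = config$min_neurons,
                        seed = seed + 200L)
      write.csv(confusionMatrix(d), file.path(out_dir, "confusion.csv"))
      write.csv(t(weightMatrix(d)), file.path(out_dir, "weights.csv"))
      d
    })
    note("decoding", "ok", list(accuracy = accuracy(decoder),
                                cost = decoder@cost))
  } else {
    note("decoding", "skipped", reason = "fewer than 2 responsive neurons")
  }

  # -- weight metrics ------------------------------------------------------
  if (!is.null(decoder)) {
    run_stage("weights", {
      W <- weightMatrix(decoder)
      ps <- populationSparseness(W)
      ls <- lifetimeSparseness(W)
      wcsv(data.frame(class = names(ps), population_sparseness = ps,
                      row.names = NULL), "population_sparseness.csv")
      wcsv(data.frame(neuron = seq_along(ls), lifetime_sparseness = ls),
           "lifetime_sparseness.csv")
      jac <- jaccardDissimilarity(W)
      write.csv(jac, file.path(out_dir, "jaccard.csv"))
      hw <- highWeightNeurons(W, roiTable(ne)[resp_any, , drop = FALSE])
      wcsv(hw$table, "high_weight_neurons.csv")
      note("weights", "ok",
           list(mean_population_sparseness = mean(ps, na.rm = TRUE),
                mean_jaccard = mean(jac[upper.tri(jac)], na.rm = TRUE),
                n_high_weight = nrow(hw$table)))
    })
  } else {
    note("weights", "skipped", reason = "no decoder")
  }

  # -- nonlinear summation -------------------------------------------------
  labels <- vapply(conditions, .classLabel, character(1),
                   universe = universe)
  pair_idx <- which(lengths(conditions) == 2)
  pairs_ok <- Filter(function(i) {
    all(conditions[[i]] %in% unlist(singles))
  }, pair_idx)
  if (length(pairs_ok)) {
    run_stage("nonlinearity", {
      responses <- setNames(lapply(conditions, function(cs)
        populationResponseVector(ne, cs)), labels)
      pairs <- data.frame(
        a = vapply(pairs_ok, function(i) conditions[[i]][1], character(1)),
        b = vapply(pairs_ok, function(i) conditions[[i]][2], character(1)),
        ab = labels[pairs_ok], stringsAsFactors = FALSE)
      decs <- lapply(seq_len(nrow(pairs)), function(i) {
        decomposePair(responses[[pairs$a[i]]], responses[[pairs$b[i]]],
                      responses[[pairs$ab[i]]], pair = pairs$ab[i])
      })
      tab <- data.frame(
        pair = pairs$ab,
        alpha = vapply(decs, function(d) d@alpha, numeric(1)),
        beta = vapply(decs, function(d) d@beta, numeric(1)),
        angle_deg = vapply(decs, planeAngle, numeric(1)),
        mean_RNL = vapply(decs, function(d) d@summaryRNL, numeric(1)))
      wcsv(tab, "nonlinearity.csv")
      resid <- do.call(cbind, lapply(decs, nonlinearResidual))
      colnames(resid) <- pairs$ab
      wcsv(data.frame(neuron_id = rownames(traces(ne)), resid,
                      check.names = FALSE), "nonlinearity_residuals.csv")
      nulls <- nullControls(responses, pairs, "scrambled", n_perm = 10,
                            seed = seed + 300L)
      wcsv(nulls, "nonlinearity_null.csv")
      summ <- nonlinearitySummary(decs)
      note("nonlinearity", "ok",
           list(mean_angle = summ$mean_angle, mean_RNL = summ$mean_RNL,
                null_mean_angle = mean(nulls$angle)))
    })
  } else {
    note("nonlinearity", "skipped",
         reason = "no pair condition with both single conditions present")
  }

  # -- geometry & decorrelation -------------------------------------------
  run_stage("geometry", {
    first_onset <- min(log$onset_time)
    half_s <- min(config$window_s,
                  floor(first_onset * samplingRate(ne)) / samplingRate(ne))
    tp <- pcaTrajectories(ne, conditions, window_s = half_s,
                          neurons = which(resp_any))
    wcsv(tp$trajectories, "trajectories.csv")
    jsonlite::write_json(
      list(variance_explained = tp$variance_explained),
      file.path(out_dir, "variance_explained.json"), digits = NA)
    note("geometry", "ok",
         list(var_2_4 = sum(tp$variance_explained[2:4])))
  })
  run_stage("decorrelation", {
    rc <- regionCorrelationMatrix(ne, conditions, neurons = which(resp_any))
    for (r in names(rc$matrices)) {
      if (!is.null(rc$matrices[[r]]))
        write.csv(rc$matrices[[r]],
                  file.path(out_dir, paste0("correlation_", r, ".csv")))
    }
    wcsv(data.frame(region = names(rc$decorrelation_index),
                    decorrelation_index = rc$decorrelation_index,
                    n_neurons = rc$n_neurons, row.names = NULL),
         "decorrelation_index.csv")
    note("decorrelation", "ok",
         list(indices = as.list(rc$decorrelation_index[
           is.finite(rc$decorrelation_index)])))
  })

  report <- structure(list(stages = stages, seed = seed, config_hash = hash,
                           wall_time_s = proc.time()[["elapsed"]] - t0),
                      class = "RunReport")
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed", x$seed, ", config", x$config_hash, ")\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-15s %s%s\n", s, st$status,
                if (!is.null(st$reason)) paste0(" (", st$reason, ")") else ""))
  }
  cat(sprintf("  wall time: %.1f s\n", x$wall_time_s))
  invisible(x)
}
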
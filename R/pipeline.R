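#' Default pipeline configuration
#'
#' Nested list with one section per stage; every value is a documented
#' default of the corresponding function. Round-trips losslessly through
#' YAML ([read_config()] / [write_config()]).
#'
#' @return Named list with sections `simulate`, `preprocess`,
#'   `connectivity`, `stats`, `model`, plus global `seed`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_subjects = 88L,
      discovery_n = 70L,
      responder_fraction = 37 / 70,
      responder_coupling = 0.8,
      nonresponder_coupling = 0.4,
      coupling_band = "high_beta",
      phase_lag = pi / 4,
      mixing_coefficient = 0.1,
      noise_sd = 1,
      duration_s = 60,
      fs = 500L,
      n_channels = 19L
    ),
    preprocess = list(
      target_fs = 500,
      epoch_length_s = 2,
      amplitude_threshold_uv = 200,
      flatline_eps = 0.1,
      montage = "longitudinal"
    ),
    connectivity = list(
      trim = 0.1,
      hilbert_scope = "epoch",
      filter_order = 4L
    ),
    stats = list(
      alpha = 0.05,
      method = "mann_whitney"
    ),
    model = list(
      selector = "f_score",
      outer_k = 10L,
      inner_k = 5L,
      C_grid = c(0.01, 0.1, 1, 10, 100),
      n_features_grid = c(5L, 10L, 15L, 20L, 30L, 43L),
      min_select_frac = 0.5
    )
  )
}

#' Validate a pipeline configuration
#'
#' Merges the supplied (possibly partial) configuration over the defaults
#' and rejects unknown keys at both levels.
#'
#' @param config nested list (as from [read_config()]).
#' @return The merged, validated configuration.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in names(config)) {
    if (is.list(defaults[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
      if (length(bad) > 0) {
        stop("unknown key(s) in config section '", sec, "': ",
             paste(bad, collapse = ", "))
      }
    }
  }
  out <- utils::modifyList(defaults, config)
  stopifnot(out$simulate$discovery_n < out$simulate$n_subjects,
            out$stats$alpha > 0, out$stats$alpha < 1)
  out
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns the validated configuration;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

# FNV-1a hash of a string, hex; stamps every artifact with its provenance
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' simulate -> extract -> compare -> train -> predict on synthetic data:
#' generates the cohort, writes per-subject EDF files and the manifest,
#' reads the EDFs back and extracts the synchronization features, splits
#' the cohort into a discovery and a validation set (seeded random split),
#' runs the clinical and synchronization group comparisons on the
#' discovery set, trains the nested-CV SVM on the three feature modes, and
#' predicts the validation cohort with the final refit model. All outputs
#' are delimited text or JSON stamped with the configuration hash and
#' seed.
#'
#' @param config pipeline configuration (see [default_config()]); partial
#'   lists are merged over the defaults.
#' @param out_dir output directory.
#' @param modes feature modes to train (default all three).
#' @return Invisibly, a list with the in-memory results (feature table,
#'   comparisons, model reports, validation accuracy) and `paths` of the
#'   written artifacts.
#' @export
run_pipeline <- function(config = list(), out_dir,
                         modes = c("integrated", "clinical", "sync")) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  write_config(cfg, file.path(out_dir, "config.yaml"))
  sim <- cfg$simulate

  cohort <- pipeline_stage("simulate", {
    spec <- cohort_spec(
      n_subjects = sim$n_subjects,
      responder_fraction = sim$responder_fraction,
      responder_coupling = coupling_spec(
        sim$coupling_band, sim$responder_coupling, sim$phase_lag,
        sim$mixing_coefficient, sim$noise_sd),
      nonresponder_coupling = coupling_spec(
        sim$coupling_band, sim$nonresponder_coupling, sim$phase_lag,
        sim$mixing_coefficient, sim$noise_sd),
      duration_s = sim$duration_s, fs = sim$fs,
      n_channels = sim$n_channels, seed = cfg$seed)
    generate_cohort(spec)
  })
  manifest_path <- pipeline_stage("simulate", write_cohort(cohort, out_dir))
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)

  montage <- if (identical(cfg$preprocess$montage, "longitudinal") &&
                 sim$n_channels == 19L) default_montage() else NULL
  pp_cfg <- c(cfg$preprocess[c("target_fs", "epoch_length_s",
                               "amplitude_threshold_uv", "flatline_eps")],
              cfg$connectivity)

  features <- pipeline_stage("extract", {
    edf_paths <- file.path(dirname(manifest_path), manifest$edf_path)
    rows <- lapply(edf_paths, function(p) {
      rec <- read_edf(p)
      f <- extract_sync_features(rec, montage = montage, config = pp_cfg)
      cbind(data.frame(subject_id = rec$subject_id,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(f)))
    })
    out <- do.call(rbind, rows)
    utils::write.table(out, file.path(out_dir, "features.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      c(list(config_hash = hash, seed = cfg$seed), pp_cfg),
      file.path(out_dir, "features_config.json"), auto_unbox = TRUE)
    out
  })

  # seeded random discovery/validation split
  set.seed(cfg$seed)
  discovery_idx <- sort(sample(nrow(manifest), sim$discovery_n))
  manifest$cohort_role <- "validation"
  manifest$cohort_role[discovery_idx] <- "discovery"
  utils::write.table(manifest, manifest_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  disc <- manifest$cohort_role == "discovery"
  labels <- label_responder(manifest$baseline_freq,
                            manifest$followup_freq)$responder

  comparisons <- pipeline_stage("compare", {
    sync_cmp <- compare_sync_by_group(
      features[disc, , drop = FALSE], labels[disc],
      alpha = cfg$stats$alpha, method = cfg$stats$method)
    clin_cmp <- compare_clinical_by_group(
      manifest[disc, , drop = FALSE], labels[disc],
      alpha = cfg$stats$alpha)
    utils::write.table(sync_cmp, file.path(out_dir, "sync_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(clin_cmp,
                       file.path(out_dir, "clinical_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(sync = sync_cmp, clinical = clin_cmp)
  })

  md <- cfg$model
  reports <- pipeline_stage("train", {
    reps <- lapply(modes, function(mode) {
      mat <- assemble_matrix(manifest[disc, , drop = FALSE],
                             features[disc, , drop = FALSE],
                             labels[disc], mode = mode)
      rep <- nested_cv(mat$X, mat$y, selector = md$selector,
                       outer_k = md$outer_k, inner_k = md$inner_k,
                       C_grid = md$C_grid,
                       n_features_grid = md$n_features_grid,
                       seed = cfg$seed,
                       min_select_frac = md$min_select_frac)
      utils::write.csv(rep$roc,
                       file.path(out_dir, paste0("roc_", mode, ".csv")),
                       row.names = FALSE)
      rep
    })
    names(reps) <- modes
    jsonlite::write_json(
      list(config_hash = hash, seed = cfg$seed,
           performance = lapply(reps, function(r) {
             list(accuracy = r$accuracy, precision = r$precision,
                  auc = r$auc,
                  confusion = as.data.frame(r$confusion),
                  coefficients = r$coefficient_summary)
           })),
      file.path(out_dir, "model_report.json"), auto_unbox = TRUE,
      digits = 10)
    reps
  })

  validation <- pipeline_stage("predict", {
    mode <- modes[1]
    tr <- assemble_matrix(manifest[disc, , drop = FALSE],
                          features[disc, , drop = FALSE],
                          labels[disc], mode = mode)
    ext <- assemble_matrix(manifest[!disc, , drop = FALSE],
                           features[!disc, , drop = FALSE],
                           labels[!disc], mode = mode)
    fin <- fit_final_and_predict(tr$X, tr$y, ext$X, ext$y,
                                 selector = md$selector,
                                 inner_k = md$inner_k, C_grid = md$C_grid,
                                 n_features_grid = md$n_features_grid,
                                 seed = cfg$seed)
    out <- data.frame(subject_id = manifest$subject_id[!disc],
                      score = fin$scores,
                      predicted = ifelse(fin$predictions, "R50", "NR50"),
                      truth = ifelse(ext$y, "R50", "NR50"),
                      stringsAsFactors = FALSE)
    utils::write.csv(out, file.path(out_dir, "validation_predictions.csv"),
                     row.names = FALSE)
    list(predictions = out, accuracy = fin$accuracy, bundle = fin$bundle)
  })

  summary <- list(
    config_hash = hash, seed = cfg$seed,
    n_discovery = sum(disc), n_validation = sum(!disc),
    discovery_responders = sum(labels[disc]),
    performance = lapply(reports, function(r) {
      list(accuracy = r$accuracy, precision = r$precision, auc = r$auc)
    }),
    validation_accuracy = validation$accuracy)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(list(cohort = cohort, features = features,
                 comparisons = comparisons, reports = reports,
                 validation = validation, summary = summary,
                 paths = list(
                   manifest = manifest_path,
                   features = file.path(out_dir, "features.tsv"),
                   summary = file.path(out_dir, "summary.json"))))
}
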
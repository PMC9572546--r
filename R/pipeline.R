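#' Default pipeline configuration
#'
#' The defaults encode the screening protocol's reference settings: 1 uM
#' activity threshold and 4:1 stratified split for curation; zero-variance /
#' zero-MI / 0.8-correlation descriptor pruning; 10-fold CV; dual 0.8
#' confidence threshold, rule-based drug-likeness, −10.6 kcal/mol reference
#' affinity and 0.8 total-score selection for screening. Synthetic inputs
#' default to the study-scale dataset (1138 active / 285 inactive, 208
#' descriptors) and a 4112-compound annotated library.
#'
#' @return Nested named list; serialize with [yaml::write_yaml()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "qsarvs_run",
    stages = list(simulate = TRUE, curate = TRUE, descriptors = TRUE,
                  select = TRUE, train = TRUE, evaluate = TRUE,
                  predict = TRUE, filter = TRUE, consensus = TRUE,
                  ic50 = TRUE),
    inputs = list(compounds = NULL, descriptors = NULL, library = NULL,
                  plate = NULL),
    curation = list(activity_threshold_um = 1.0),
    split = list(ratio = c(4L, 1L), stratify = TRUE),
    selection = list(variance_eps = 0, mi_epsilon = 1e-6, cor_threshold = 0.8),
    training = list(tune = FALSE, budget = 50L, folds = 10L,
                    hyperparameters = default_hyperparameters()),
    evaluation = list(folds = 10L, threshold = 0.5),
    screening = list(confidence_threshold = 0.8,
                     reference_energy_kcal = -10.6,
                     s_total_threshold = 0.8,
                     lipinski_max_violations = 0L,
                     druglikeness = TRUE),
    synthetic = list(
      qsar = list(n_active = 1138L, n_inactive = 285L, n_features = 208L,
                  n_constant = 12L, n_duplicated = 20L, n_independent = 40L,
                  effect_size = 0.6, label_noise = 0.05),
      library = list(n = 4112L, fraction_dual_high = 343 / 4112,
                     admet_pass_fraction = 22 / 343),
      dose_response = list(ic50_um = 10, hill = 1, top = 100, bottom = 0,
                           ratio_noise_sd = 0.02)
    )
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified settings fall back to [default_pipeline_config()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  cfg
}

pipeline_log <- function(outdir, stage, fmt, ...) {
  line <- sprintf("[%s] %-11s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...))
  cat(line, "\n", file = file.path(outdir, "run.log"), append = TRUE, sep = "")
  message(line)
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(compound_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the virtual-screening pipeline end to end
#'
#' Executes the enabled stages in their fixed order — simulate, curate,
#' descriptors, select, train, evaluate, predict, filter, consensus, ic50 —
#' writing each stage's artifact into the output directory before the next
#' stage begins, together with a structured log of per-stage record counts
#' (the screening funnel) and a run manifest (package version, seeds, config
#' hash). A stage failure aborts with the stage name; partial outputs remain
#' on disk for inspection. Identical configuration and seed reproduce
#' identical outputs.
#'
#' @param config Configuration list (see [default_pipeline_config()]), or a
#'   path to a YAML file.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- load_pipeline_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- list(
    package = as.character(utils::packageVersion("qsarvs")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    started = format(Sys.time())
  )
  yaml::write_yaml(manifest, file.path(outdir, "run_manifest.yaml"))

  run_stage <- function(stage, fun) {
    if (!isTRUE(cfg$stages[[stage]])) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs in %s)",
                   stage, conditionMessage(e), outdir), call. = FALSE)
    })
  }
  path <- function(...) file.path(outdir, ...)
  seed <- as.integer(cfg$seed)

  run_stage("simulate", function() {
    q <- do.call(synth_qsar_dataset, c(cfg$synthetic$qsar, list(seed = seed)))
    write_compounds(q$records, path("compounds.csv"), "csv")
    write_matrix_csv(q$descriptors, path("descriptors_raw.csv"))
    yaml::write_yaml(list(feature_roles = q$manifest$feature_roles$role,
                          descriptor = q$manifest$feature_roles$descriptor),
                     path("qsar_manifest.yaml"))
    lib <- do.call(synth_screening_library,
                   c(cfg$synthetic$library, list(seed = seed + 1L)))
    utils::write.csv(lib$records, path("library.csv"), row.names = FALSE)
    utils::write.csv(lib$manifest, path("library_manifest.csv"), row.names = FALSE)
    dr <- do.call(synth_dose_response,
                  c(cfg$synthetic$dose_response, list(seed = seed + 2L)))
    utils::write.csv(dr, path("plate.csv"), row.names = FALSE)
    pipeline_log(outdir, "simulate", "%d compounds, %d library entries",
                 nrow(q$records), nrow(lib$records))
  })

  run_stage("curate", function() {
    src <- cfg$inputs$compounds %||% path("compounds.csv")
    records <- read_compounds(src, "csv")
    curated <- curate_dataset(records, cfg$curation$activity_threshold_um)
    rep <- attr(curated, "report")
    write_compounds(curated, path("curated.csv"), "csv")
    split <- split_dataset(curated, ratio = cfg$split$ratio, seed = seed,
                           stratify = cfg$split$stratify)
    utils::write.csv(data.frame(
      compound_id = c(split$train_ids, split$test_ids),
      role = rep(c("train", "test"),
                 c(length(split$train_ids), length(split$test_ids)))),
      path("split.csv"), row.names = FALSE)
    pipeline_log(outdir, "curate", "%d -> %d records (%d active / %d inactive), split %d/%d",
                 rep$n_input, rep$n_output, rep$n_active, rep$n_inactive,
                 length(split$train_ids), length(split$test_ids))
  })

  run_stage("descriptors", function() {
    curated <- read_compounds(path("curated.csv"), "csv")
    desc_src <- cfg$inputs$descriptors %||% path("descriptors_raw.csv")
    raw <- if (file.exists(desc_src)) {
      compute_descriptors(curated, file_descriptor_provider(desc_src))
    } else {
      compute_descriptors(curated)
    }
    split <- utils::read.csv(path("split.csv"), stringsAsFactors = FALSE)
    train_ids <- split$compound_id[split$role == "train"]
    std <- fit_standardizer(raw[rownames(raw) %in% train_ids, , drop = FALSE])
    standardized <- apply_standardizer(std, raw)
    write_matrix_csv(standardized, path("standardized.csv"))
    utils::write.csv(data.frame(descriptor = std$descriptor_names,
                                center = std$center, scale = std$scale),
                     path("standardizer.csv"), row.names = FALSE)
    cs <- fit_chemspace(standardized[rownames(standardized) %in% train_ids, ,
                                     drop = FALSE], n_components = 2)
    ad <- applicability_domain(cs, standardized)
    utils::write.csv(ad$flags, path("chemspace.csv"), row.names = FALSE)
    pipeline_log(outdir, "descriptors", "%d x %d matrix standardized; AD overlap %.3f",
                 nrow(standardized), ncol(standardized), ad$overlap_fraction)
  })

  run_stage("select", function() {
    standardized <- read_matrix_csv(path("standardized.csv"))
    curated <- read_compounds(path("curated.csv"), "csv")
    split <- utils::read.csv(path("split.csv"), stringsAsFactors = FALSE)
    train_ids <- split$compound_id[split$role == "train"]
    tr <- rownames(standardized) %in% train_ids
    labels <- curated$label[match(rownames(standardized), curated$compound_id)]
    sel <- select_features(standardized[tr, , drop = FALSE], labels[tr],
                           seed = seed,
                           variance_eps = cfg$selection$variance_eps,
                           mi_epsilon = cfg$selection$mi_epsilon,
                           cor_threshold = cfg$selection$cor_threshold)
    write_selection_report(sel$report, path("selection_report.csv"))
    selected_all <- apply_selection(sel$report, standardized)
    write_matrix_csv(selected_all, path("selected.csv"))
    pipeline_log(outdir, "select", "%d -> %d descriptors", ncol(standardized),
                 ncol(selected_all))
  })

  run_stage("train", function() {
    selected <- read_matrix_csv(path("selected.csv"))
    curated <- read_compounds(path("curated.csv"), "csv")
    split <- utils::read.csv(path("split.csv"), stringsAsFactors = FALSE)
    train_ids <- split$compound_id[split$role == "train"]
    tr <- rownames(selected) %in% train_ids
    y <- curated$label[match(rownames(selected), curated$compound_id)]
    hp <- cfg$training$hyperparameters
    if (isTRUE(cfg$training$tune)) {
      tuned <- tune_hyperparameters(
        selected[tr, , drop = FALSE], y[tr],
        hyperparameter_space(budget = cfg$training$budget, seed = seed),
        folds = cfg$training$folds)
      hp <- list(rf = tuned$rf$par, svm = tuned$svm$par, ann = tuned$ann$par)
      utils::write.csv(tuned$trace, path("tuning_trace.csv"), row.names = FALSE)
    }
    bases <- train_base_models(selected[tr, , drop = FALSE], y[tr], hp,
                               seed = seed)
    ensemble <- build_ensemble(bases, c("voting", "stacking"),
                               matrix = selected[tr, , drop = FALSE],
                               labels = y[tr], seed = seed)
    dir.create(path("models"), showWarnings = FALSE)
    saveRDS(ensemble, path("models", "ensemble.rds"))
    yaml::write_yaml(hp, path("models", "hyperparameters.yaml"))
    pipeline_log(outdir, "train", "bases + voting/stacking trained on %d compounds",
                 sum(tr))
  })

  run_stage("evaluate", function() {
    selected <- read_matrix_csv(path("selected.csv"))
    curated <- read_compounds(path("curated.csv"), "csv")
    split <- utils::read.csv(path("split.csv"), stringsAsFactors = FALSE)
    ensemble <- readRDS(path("models", "ensemble.rds"))
    y <- curated$label[match(rownames(selected), curated$compound_id)]
    te <- rownames(selected) %in% split$compound_id[split$role == "test"]
    conf <- predict_confidence(ensemble, selected[te, , drop = FALSE])
    rows <- lapply(c(conf_voting = "conf_voting", conf_stacking = "conf_stacking"),
                   function(col) {
      mr <- confusion_and_metrics(y[te], conf[[col]],
                                  threshold = cfg$evaluation$threshold)
      data.frame(model = sub("conf_", "", col), context = "test",
                 accuracy = mr$accuracy, precision = mr$precision,
                 recall = mr$recall, f1 = mr$f1,
                 auc = roc_auc(y[te], conf[[col]])$auc)
    })
    metrics <- do.call(rbind, rows)
    utils::write.csv(metrics, path("metrics.csv"), row.names = FALSE)
    roc <- roc_auc(y[te], conf$conf_voting)
    utils::write.csv(roc$points, path("roc_points.csv"), row.names = FALSE)
    utils::write.csv(feature_importance(ensemble$bases$rf),
                     path("importance.csv"), row.names = FALSE)
    pipeline_log(outdir, "evaluate", "test AUC: voting %.3f, stacking %.3f",
                 metrics$auc[1], metrics$auc[2])
  })

  run_stage("predict", function() {
    lib_src <- cfg$inputs$library %||% path("library.csv")
    lib <- utils::read.csv(lib_src, stringsAsFactors = FALSE)
    if (!all(c("conf_voting", "conf_stacking") %in% names(lib))) {
      ensemble <- readRDS(path("models", "ensemble.rds"))
      std <- utils::read.csv(path("standardizer.csv"), stringsAsFactors = FALSE)
      standardizer <- structure(list(center = std$center, scale = std$scale,
                                     descriptor_names = std$descriptor),
                                class = "standardizer")
      report <- read_selection_report(path("selection_report.csv"))
      raw <- compute_descriptors(lib)
      m <- apply_selection(report, apply_standardizer(standardizer, raw))
      conf <- predict_confidence(ensemble, m)
      lib <- merge(lib, conf, by = "compound_id")
    }
    utils::write.csv(lib[, c("compound_id", "conf_voting", "conf_stacking")],
                     path("predictions.csv"), row.names = FALSE)
    utils::write.csv(lib, path("library_annotated.csv"), row.names = FALSE)
    pipeline_log(outdir, "predict", "%d library compounds with dual confidences",
                 nrow(lib))
  })

  run_stage("filter", function() {
    lib <- utils::read.csv(path("library_annotated.csv"), stringsAsFactors = FALSE)
    act <- activity_filter(lib, cfg$screening$confidence_threshold)
    n_act <- nrow(act)
    if (isTRUE(cfg$screening$druglikeness)) {
      act <- druglikeness_filter(act, cfg$screening$lipinski_max_violations)
    }
    utils::write.csv(act, path("filtered.csv"), row.names = FALSE)
    pipeline_log(outdir, "filter", "funnel %d -> %d (activity) -> %d (drug-likeness%s)",
                 nrow(lib), n_act, nrow(act),
                 if (isTRUE(cfg$screening$druglikeness)) "" else " disabled")
  })

  run_stage("consensus", function() {
    filtered <- utils::read.csv(path("filtered.csv"), stringsAsFactors = FALSE)
    scored <- score_library(filtered, cfg$screening$reference_energy_kcal)
    ranked <- rank_candidates(scored, cfg$screening$s_total_threshold)
    utils::write.csv(ranked, path("ranked.csv"), row.names = FALSE)
    pipeline_log(outdir, "consensus", "%d candidates ranked, %d selected (s_total > %.2f)",
                 nrow(ranked), sum(ranked$selected), cfg$screening$s_total_threshold)
  })

  run_stage("ic50", function() {
    plate_src <- cfg$inputs$plate %||% path("plate.csv")
    plate <- utils::read.csv(plate_src, stringsAsFactors = FALSE)
    dr <- percent_inhibition(plate)
    utils::write.csv(dr, path("doseresponse.csv"), row.names = FALSE)
    fit <- fit_ic50(dr$concentration_um, dr$inhibition_percent)
    utils::write.csv(data.frame(
      ic50_um = format_ic50(fit), hill = fit$hill, top = fit$top,
      bottom = fit$bottom, converged = fit$converged), path("ic50.csv"),
      row.names = FALSE)
    pipeline_log(outdir, "ic50", "fitted IC50: %s uM", format_ic50(fit))
  })

  invisible(outdir)
}
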
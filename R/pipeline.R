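#' Pipeline configuration
#'
#' Bundles every stage's settings and seeds: the corpus design and noise
#' model for simulation, the acquisition grid, signature extraction
#' parameters, QC thresholds, the split specification, and the grid-search
#' budget. Defaults reproduce the study-scale design (130 specimens x 3
#' replicates, 68 test specimens, 8,152 features).
#'
#' @param grid [acquisition_grid()].
#' @param noise [noise_model()].
#' @param design [corpus_design()].
#' @param window,polyorder Savitzky-Golay parameters.
#' @param reference_tm Nominal marker temperature (degC).
#' @param theta_h,theta_c QC thresholds.
#' @param train_fraction,group_by_specimen Split settings.
#' @param param_grid Hyperparameter grid ([default_param_grid()]), or
#'   `NULL` to train a single [net_config()] model.
#' @param net [net_config()] used directly (no grid) or as grid baseline.
#' @param max_models,max_runtime_sec Grid-search stopping criteria.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = acquisition_grid(), noise = noise_model(),
                            design = corpus_design(), window = 11L,
                            polyorder = 3L, reference_tm = TM_MARKER_TM,
                            theta_h = 0.1, theta_c = 0.2,
                            train_fraction = 0.7, group_by_specimen = FALSE,
                            param_grid = NULL, net = net_config(),
                            max_models = 30L, max_runtime_sec = Inf,
                            seed = 1L) {
  structure(list(grid = grid, noise = noise, design = design,
                 window = window, polyorder = polyorder,
                 reference_tm = reference_tm, theta_h = theta_h,
                 theta_c = theta_c, train_fraction = train_fraction,
                 group_by_specimen = group_by_specimen,
                 param_grid = param_grid, net = net,
                 max_models = max_models,
                 max_runtime_sec = max_runtime_sec,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads the scalar stage settings (grid, noise, QC thresholds, split,
#' search budget, seed) from a YAML file; unspecified keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg_args <- list()
  if (!is.null(y$grid))
    cfg_args$grid <- do.call(acquisition_grid, y$grid)
  if (!is.null(y$noise))
    cfg_args$noise <- do.call(noise_model, y$noise)
  if (!is.null(y$net))
    cfg_args$net <- do.call(net_config, y$net)
  for (key in c("window", "polyorder", "reference_tm", "theta_h", "theta_c",
                "train_fraction", "group_by_specimen", "max_models",
                "max_runtime_sec", "seed")) {
    if (!is.null(y[[key]])) cfg_args[[key]] <- y[[key]]
  }
  do.call(pipeline_config, cfg_args)
}

#' Run the full melt-curve barcoding pipeline
#'
#' Orchestrates simulate -> signatures -> QC -> features -> train (or grid
#' search) -> predict -> evaluate as one seeded workflow, optionally
#' writing each stage's artifact (corpus exports, signature tables, QC
#' report, grid-search summary, predictions, confusion matrix,
#' distinguishability report, provenance JSON) under `outdir`. Identical
#' config and seed give identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory for artifacts, or `NULL` to skip writing.
#' @param panel Optionally a pre-built panel; defaults to
#'   [build_default_panel()] seeded from the config.
#' @param qc Apply QC filtering (default TRUE).
#' @return A list of class `pipeline_result`: `corpus`, `qc`, `features`,
#'   `model` (and `search` when a grid was given), `predictions`,
#'   `confusion`, `test_accuracy`, `dl_report`, `tallies`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         panel = NULL, qc = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 4)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(panel)) panel <- stage("panel", build_default_panel(seeds[1]))
  design <- config$design
  design$seed <- seeds[2]
  corpus <- stage("simulate",
                  generate_corpus(panel, design, config$grid, config$noise))

  sig_args <- list(grid = config$grid, window = config$window,
                   polyorder = config$polyorder,
                   reference_tm = config$reference_tm)
  sig_train <- stage("signatures",
                     do.call(compute_signatures,
                             c(list(corpus$training), sig_args)))
  sig_test <- stage("signatures",
                    do.call(compute_signatures,
                            c(list(corpus$test), sig_args)))

  if (qc) {
    qc_res <- stage("qc", filter_corpus(sig_train, config$theta_h,
                                        config$theta_c,
                                        reference_tm = config$reference_tm))
    retained <- qc_res$retained
  } else {
    qc_res <- NULL
    retained <- sig_train
  }

  feats <- stage("featurize", build_feature_matrix(retained, config$grid))
  feats_test <- stage("featurize", build_feature_matrix(sig_test, config$grid))

  if (!is.null(config$param_grid)) {
    search <- stage("gridsearch",
                    grid_search(feats, config$param_grid,
                                max_models = config$max_models,
                                max_runtime_sec = config$max_runtime_sec,
                                train_fraction = config$train_fraction,
                                group_by_specimen = config$group_by_specimen,
                                seed = seeds[3], base_config = config$net))
    model <- search$best_model
  } else {
    search <- NULL
    split <- stage("split", split_corpus(feats, config$train_fraction,
                                         seed = seeds[3],
                                         group_by_specimen = config$group_by_specimen))
    net <- config$net
    net$seed <- seeds[4]
    model <- stage("train", train_fann(split$train, split$validation, net))
  }

  predictions <- stage("predict", predict(model, feats_test))
  cm <- stage("evaluate",
              confusion_matrix(feats_test$meta$species, predictions$predicted,
                               labels = sort_panel_labels(panel)))
  dl_report <- stage("evaluate",
                     dl_distinguishability(predictions,
                                           feats_test$meta$species,
                                           species = panel$species_name))
  tallies <- stage("report", panel_tallies())

  result <- structure(
    list(corpus = corpus, qc = qc_res, features = feats,
         features_test = feats_test, search = search, model = model,
         predictions = predictions, confusion = cm,
         test_accuracy = accuracy(cm), dl_report = dl_report,
         tallies = tallies, seed = config$seed),
    class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_artifacts(result, config, outdir)
  result
}

sort_panel_labels <- function(panel) {
  full <- tryCatch(panel_species(), error = function(e) character())
  c(intersect(full, panel$species_name),
    setdiff(panel$species_name, full))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$corpus)
  if (!is.null(x$qc)) print(x$qc$report)
  print(x$model)
  cat(sprintf("  independent test accuracy: %.2f%% (%d of %d correct)\n",
              x$test_accuracy, sum(diag(x$confusion)), sum(x$confusion)))
  invisible(x)
}

write_pipeline_artifacts <- function(result, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_melt_export(result$corpus$training, outdir, "training")
  write_melt_export(result$corpus$test, outdir, "test")
  if (!is.null(result$qc)) {
    readr::write_csv(tidy(result$qc$report), file.path(outdir, "qc_runs.csv"))
    jsonlite::write_json(as.list(glance(result$qc$report)),
                         file.path(outdir, "qc_summary.json"),
                         auto_unbox = TRUE)
  }
  if (!is.null(result$search))
    readr::write_csv(result$search$summaries,
                     file.path(outdir, "grid_search.csv"))
  readr::write_csv(result$predictions[, c("run_id", "predicted", "score",
                                          "margin")],
                   file.path(outdir, "predictions.csv"))
  readr::write_csv(tidy(result$confusion),
                   file.path(outdir, "confusion_matrix.csv"))
  readr::write_csv(result$dl_report,
                   file.path(outdir, "dl_distinguishability.csv"))
  jsonlite::write_json(
    list(seed = result$seed,
         n_training_runs = nrow(result$corpus$training),
         n_retained = if (is.null(result$qc)) nrow(result$corpus$training)
                      else result$qc$report$n_retained,
         n_test = nrow(result$corpus$test),
         n_features = ncol(result$features$x),
         validation_accuracy = result$model$validation_accuracy,
         test_accuracy = result$test_accuracy),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
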
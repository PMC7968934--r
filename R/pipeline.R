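#' Run the full pipeline on synthetic mono-culture scenes
#'
#' Convenience driver that chains every stage on generated data: per class,
#' mono-culture scenes are simulated until at least `cells_per_class`
#' segmented cells accumulate; each scene is segmented and its 16-feature
#' table extracted (the class label is the scene's); the pooled table is
#' then evaluated by stratified cross-validation of the five models.
#' Identical config + seed give identical outputs, byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param scene template [scene_spec()]; its `classes` are generated one at
#'   a time (mono-cultures) and its seed is re-derived per scene from
#'   `config$seed`.
#' @param cells_per_class minimum segmented cells to accumulate per class.
#' @param max_scenes_per_class stop after this many scenes per class even
#'   if short (guards against configurations that segment poorly).
#' @param out_dir optional directory; when given, writes `features.csv`,
#'   `scores.csv`, `report.json` and `manifest.json` there.
#' @return list of class `"pipeline_result"`: `features` (pooled
#'   `FeatureTable`), `report` (an `eval_report`), `manifest`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(seed = 7, folds = 5)
#' res <- run_pipeline(cfg, scene_spec(width = 220, height = 220,
#'                                     n_cells = 12),
#'                     cells_per_class = 15)
#' res$report$scores
#' }
#' @export
run_pipeline <- function(config = pipeline_config(),
                         scene = scene_spec(),
                         cells_per_class = 150L,
                         max_scenes_per_class = 25L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seg_par <- do.call(segmentation_params, config$segmentation)
  timings <- c(simulate_segment = NA_real_, classify = NA_real_)
  warns <- character()

  t0 <- proc.time()[["elapsed"]]
  tables <- list()
  scene_idx <- 0L
  for (cl in scene$classes) {
    got <- 0L; n_scenes <- 0L; parts <- list()
    while (got < cells_per_class && n_scenes < max_scenes_per_class) {
      scene_idx <- scene_idx + 1L
      n_scenes <- n_scenes + 1L
      spec <- scene
      spec$classes <- cl
      spec$class_means <- scene$class_means[cl, , drop = FALSE]
      spec$seed <- as.integer(child_seed(config$seed, scene_idx))
      sc <- withCallingHandlers(
        generate_scene(spec),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      labels <- segment_cells(sc$image, seg_par)
      if (max(labels) == 0L) next
      ft <- extract_features(sc$image, labels,
                             image_id = sprintf("%s_scene%02d", cl, n_scenes),
                             class_label = cl)
      parts[[length(parts) + 1L]] <- ft
      got <- got + nrow(ft)
    }
    if (got < cells_per_class)
      warns <- c(warns, sprintf(
        "class %s: only %d cells segmented from %d scenes", cl, got, n_scenes))
    tables[[cl]] <- do.call(rbind, parts)
  }
  features <- do.call(rbind, tables)
  rownames(features) <- NULL
  class(features) <- c("feature_table", "data.frame")
  timings["simulate_segment"] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  report <- cross_validate(features, features$class,
                           models = model_specs(config$models),
                           folds = config$folds, seed = config$seed,
                           variance_target = config$variance_target,
                           feature_set = config$feature_set)
  timings["classify"] <- proc.time()[["elapsed"]] - t0

  manifest <- run_manifest(config,
                           seeds = list(pipeline = config$seed,
                                        kmeans = seg_par$kmeans_seed),
                           timings = timings, warnings = warns)
  result <- structure(list(features = features, report = report,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    utils::write.csv(report$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(scores = report$scores,
           best_model = report$best_model,
           confusion = as.data.frame.matrix(unclass(report$confusion)),
           pca_components_used = report$pca_components_used),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    write_run_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d cells, %d classes\n",
              nrow(x$features), length(unique(x$features$class))))
  print(x$report)
  invisible(x)
}
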
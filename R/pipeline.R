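#' Default end-to-end run configuration
#'
#' A flat list mirroring the pipeline stages: synthetic two-year trial
#' scenes, classifier choice and parameters, index constants, fusion
#' threshold, regression families and grid profile, split and global seeds.
#' Validated by [validate_run_config()]; serializable as YAML for the
#' command-line interface.
#'
#' @param profile grid profile (`"fast"` for test-scale runs, `"full"` for
#'   the complete search).
#' @param seed global seed; per-year scene seeds and the split seed are
#'   derived from it.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(profile = c("fast", "full"), seed = 1) {
  profile <- match.arg(profile)
  structure(list(
    years = c(2023, 2024),
    scene = list(height = 384, width = 512, sigma_scale = 1),
    classifier = "maximum_likelihood",
    parallelepiped_k = 2,
    priors = "counts",
    n_rois_per_class = 20, roi_size = 3, n_eval_per_class = 1000,
    L = 0.5, Y = 0.16, resavi_form = "canonical",
    fusion_threshold = 0.60, fusion_method = "score",
    model_families = c("ridge", "random_forest", "neural_net"),
    profile = profile, cv_folds = 5,
    seed = as.integer(seed), out_dir = NULL
  ), class = "run_config")
}

#' Validate a run configuration
#' @param config list as produced by [default_run_config()] or read from
#'   YAML via [read_run_config()].
#' @return the validated `run_config` (defaults filled in).
#' @export
validate_run_config <- function(config) {
  base <- default_run_config()
  cfg <- utils::modifyList(unclass(base), unclass(config))
  if (!cfg$classifier %in% c("maximum_likelihood", "mahalanobis", "parallelepiped"))
    stopf("unknown classifier '%s'", cfg$classifier)
  if (!is.numeric(cfg$fusion_threshold) || cfg$fusion_threshold <= 0 ||
      cfg$fusion_threshold > 1)
    stopf("fusion_threshold must be in (0, 1]")
  if (!all(cfg$model_families %in% c("ridge", "random_forest", "neural_net")))
    stopf("unknown model family")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stopf("seed must be an integer")
  if (cfg$parallelepiped_k <= 0) stopf("parallelepiped_k must be > 0")
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) validate_run_config(yaml::read_yaml(path))

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

classify_with <- function(scene, stats, classifier, k = 2) {
  switch(classifier,
    maximum_likelihood = classify_maximum_likelihood(scene, stats),
    mahalanobis = classify_mahalanobis(scene, stats),
    parallelepiped = classify_parallelepiped(scene, stats, k = k),
    stopf("unknown classifier '%s'", classifier))
}

#' Run the full SBW estimation pipeline on synthetic scenes
#'
#' Chains every stage: per-year scene simulation, ROI sampling, supervised
#' classification (all three classifiers are evaluated for accuracy; the
#' configured one provides the boll mask), held-out accuracy assessment,
#' boll masking, sampling-point band means and vegetation indices,
#' Pearson + SHAP feature fusion and selection, stratified 7:3 split, grid
#' search with cross-validation over the configured model families,
#' validation, pixel-level SBW mapping and plot aggregation with relative
#' errors. Deterministic given the configuration seed.
#'
#' @param config a `run_config` (validated internally).
#' @return manifest list with stage metrics: `accuracy` (per year x
#'   classifier), `ranking`, `selected`, `models` (per family calibration /
#'   validation metrics), `best_family`, `validation_r2`,
#'   `validation_rmse_g`, `masked_fraction_pct`, `plot_summary`,
#'   `share_plot_rel_err_below_15pct`, seeds, and the configuration.
#'   Artifacts are written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- validate_run_config(config)
  t0 <- Sys.time()
  acc <- list(); tables <- list(); year_objs <- list()
  for (yi in seq_along(cfg$years)) {
    yr <- cfg$years[[yi]]
    sc_cfg <- do.call(scene_config, c(cfg$scene,
                                      list(year = yr, seed = cfg$seed + 1000L * yi)))
    gen <- generate_scene(sc_cfg)
    rois <- generate_rois(gen$truth, n_per_class = cfg$n_rois_per_class,
                          roi_size = cfg$roi_size, seed = cfg$seed + 17L * yi)
    stats <- fit_class_statistics(gen$scene, rois, priors = cfg$priors)
    eval_px <- sample_eval_pixels(gen$truth, rois,
                                  n_per_class = cfg$n_eval_per_class,
                                  seed = cfg$seed + 29L * yi)
    maps <- lapply(c("maximum_likelihood", "mahalanobis", "parallelepiped"),
                   function(m) classify_with(gen$scene, stats, m, cfg$parallelepiped_k))
    names(maps) <- c("maximum_likelihood", "mahalanobis", "parallelepiped")
    acc_y <- do.call(rbind, lapply(maps, accuracy_summary, eval_pixels = eval_px))
    acc_y$year <- yr
    acc[[yi]] <- acc_y
    message(sprintf("[classify] year %s: %s", yr,
                    paste(sprintf("%s OA %.2f%%", acc_y$classifier,
                                  acc_y$overall_accuracy_pct), collapse = ", ")))
    chosen <- maps[[cfg$classifier]]
    boll <- extract_boll_mask(chosen, gen$scene)
    bm <- zonal_mean_reflectance(boll$masked_scene, gen$truth$sampling_points)
    tables[[yi]] <- build_sample_table(bm, gen$truth$sbw, L = cfg$L, Y = cfg$Y,
                                       resavi_form = cfg$resavi_form)
    year_objs[[yi]] <- list(year = yr, gen = gen, boll = boll, chosen = chosen)
  }
  table <- do.call(rbind, tables)
  message(sprintf("[features] %d sampling-point records, %d indices",
                  nrow(table), length(VI_NAMES)))

  pear <- pearson_scores(table)
  shap <- shap_scores(table, seed = cfg$seed + 7L)
  ranking <- fuse_and_select(pear, shap, cum_threshold = cfg$fusion_threshold,
                             method = cfg$fusion_method)
  sel <- selected_features(ranking)
  message(sprintf("[select] %d features at %.0f%% cumulative contribution: %s",
                  length(sel), 100 * cfg$fusion_threshold, paste(sel, collapse = ", ")))

  split <- split_dataset(table, seed = cfg$seed + 101L)
  models <- list()
  for (fam in cfg$model_families) {
    mdl <- train_sbw_model(split$calibration, fam, sel, profile = cfg$profile,
                           cv_folds = cfg$cv_folds, seed = cfg$seed + 211L)
    val <- evaluate_predictions(split$validation$sbw_g,
                                predict(mdl, split$validation))
    models[[fam]] <- list(model = mdl, validation_r2 = val$r2,
                          validation_rmse_g = val$rmse)
    message(sprintf("[train] %s: calibration R2 %.3f | validation R2 %.3f, RMSE %.3f g",
                    fam, mdl$calibration_r2, val$r2, val$rmse))
  }
  val_r2 <- vapply(models, `[[`, 1, "validation_r2")
  best_family <- names(models)[which.max(val_r2)]
  best <- models[[best_family]]
  predictions <- rbind(
    data.frame(sample_id = split$calibration$sample_id,
               observed_sbw_g = split$calibration$sbw_g,
               predicted_sbw_g = predict(best$model, split$calibration),
               set = "calibration"),
    data.frame(sample_id = split$validation$sample_id,
               observed_sbw_g = split$validation$sbw_g,
               predicted_sbw_g = predict(best$model, split$validation),
               set = "validation"))

  plot_summaries <- list(); mf <- numeric(length(year_objs))
  for (yi in seq_along(year_objs)) {
    yo <- year_objs[[yi]]
    smap <- predict_pixel_sbw(yo$boll$masked_scene, best$model, L = cfg$L, Y = cfg$Y,
                              resavi_form = cfg$resavi_form)
    agg <- aggregate_to_plot(smap, yo$gen$truth$plots)
    obs <- stats::aggregate(sbw_g ~ plot_id, data = yo$gen$truth$sbw, FUN = mean)
    names(obs)[2] <- "observed_sbw_g"
    agg <- merge(agg, obs, by = "plot_id", sort = FALSE)
    agg$relative_error_pct <- ifelse(agg$flagged, NA_real_,
                                     relative_error(agg$predicted_sbw_g,
                                                    agg$observed_sbw_g))
    plot_summaries[[yi]] <- agg
    mf[yi] <- yo$boll$masked_fraction_pct
    year_objs[[yi]]$smap <- smap
  }
  plot_summary <- do.call(rbind, plot_summaries)
  rel_ok <- mean(plot_summary$relative_error_pct < 15, na.rm = TRUE)
  message(sprintf("[map] masked background %.2f%%; %.0f%% of plots within 15%% relative error",
                  mean(mf), 100 * rel_ok))

  manifest <- list(
    package_version = as.character(utils::packageVersion("cottonsbw")),
    seed = cfg$seed, config = unclass(cfg),
    accuracy = do.call(rbind, acc),
    ranking = ranking, selected = sel,
    models = lapply(models, function(m) list(
      best = as.list(m$model$best),
      calibration_r2 = m$model$calibration_r2,
      calibration_rmse_g = m$model$calibration_rmse,
      validation_r2 = m$validation_r2,
      validation_rmse_g = m$validation_rmse_g)),
    best_family = best_family,
    predictions = predictions,
    validation_r2 = best$validation_r2,
    validation_rmse_g = best$validation_rmse_g,
    n_samples = nrow(table),
    n_calibration = nrow(split$calibration),
    n_validation = nrow(split$validation),
    masked_fraction_pct = mean(mf),
    plot_summary = plot_summary,
    share_plot_rel_err_below_15pct = rel_ok,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(manifest, year_objs, table, cfg)
  manifest
}

write_pipeline_artifacts <- function(manifest, year_objs, table, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (yo in year_objs) {
    yd <- file.path(cfg$out_dir, paste0("year_", yo$year))
    dir.create(yd, showWarnings = FALSE, recursive = TRUE)
    write_scene_tiff(yo$gen$scene, file.path(yd, "scene.tif"))
    write_labels_tiff(yo$chosen, file.path(yd, "classmap.tif"))
    write_labels_tiff(matrix(as.integer(yo$boll$mask), nrow(yo$boll$mask)),
                      file.path(yd, "boll_mask.tif"))
    sm <- yo$smap$values
    sm[!is.finite(sm)] <- 0
    tiff::writeTIFF(sm / max(sm, 1), file.path(yd, "sbw_map.tif"),
                    bits.per.sample = 32L)
  }
  utils::write.csv(table, file.path(cfg$out_dir, "sample_table.csv"), row.names = FALSE)
  utils::write.csv(manifest$ranking, file.path(cfg$out_dir, "feature_ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$accuracy, file.path(cfg$out_dir, "accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$plot_summary, file.path(cfg$out_dir, "plot_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$predictions, file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)
  slim <- manifest[setdiff(names(manifest),
                           c("ranking", "plot_summary", "accuracy", "predictions"))]
  jsonlite::write_json(slim, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}
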
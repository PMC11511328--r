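# End-to-end orchestration: simulate -> crop/split/normalize -> extract
# -> LOF + collinearity filter -> grid search + train -> evaluate ->
# Shapley explanation -> gray-level statistics. Every stochastic stage
# receives a sub-seed derived from the master seed.

#' Pipeline configuration
#'
#' Assembles every tunable of the end-to-end run into one serializable
#' list. Defaults reproduce the published acquisition layout (6 drugs x
#' 4 samples x 3 videos x 100 frames at 1456 x 1088, 224-px crops); the
#' `full_scale = FALSE` default shrinks the layout and frame size so a
#' complete run fits in minutes on one CPU while preserving every
#' pipeline stage.
#'
#' @param full_scale Use the full published layout (expensive).
#' @param catalog Drug catalog (list of [drug_spec()]).
#' @param samples_per_drug,videos_per_sample,frames_per_video Layout.
#' @param frame_height_px,frame_width_px Simulated frame size.
#' @param crop_size Center-crop side length.
#' @param split_fraction Training fraction.
#' @param lof_fraction,lof_k Outlier-removal settings.
#' @param pcc_threshold Collinearity threshold.
#' @param family `"rf"` or `"mlp"`. @param grid Hyperparameter grid
#'   (default: the single reference best point, i.e. no search).
#' @param cv_folds Cross-validation folds for the grid search.
#' @param n_boot Bootstrap resamples for evaluation CIs.
#' @param shap_background,shap_samples,shap_permutations Explanation
#'   stage sizes.
#' @param stats_unit ANOVA unit: `"image"` or `"pixel"`.
#' @param sim A [sim_config()]. @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(full_scale = FALSE,
                            catalog = pan_drug_catalog(),
                            samples_per_drug = if (full_scale) 4L else 2L,
                            videos_per_sample = if (full_scale) 3L else 1L,
                            frames_per_video = if (full_scale) 100L else 50L,
                            frame_height_px = if (full_scale) 1088L else 256L,
                            frame_width_px = if (full_scale) 1456L else 256L,
                            crop_size = 224L,
                            split_fraction = 0.8,
                            lof_fraction = 0.10, lof_k = 20L,
                            pcc_threshold = 0.9,
                            family = "mlp",
                            grid = list(best_reference_params(family)),
                            cv_folds = 10L,
                            n_boot = 1000L,
                            shap_background = 100L,
                            shap_samples = 50L,
                            shap_permutations = 50L,
                            stats_unit = "image",
                            sim = sim_config(),
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  ser <- config
  ser$catalog <- lapply(ser$catalog, unclass)
  ser$sim <- unclass(ser$sim)
  jsonlite::write_json(ser, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

stage_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic dataset generated from the
#' configured drug catalog and writes the artifacts (manifest, feature
#' table, feature mask, evaluation report, Shapley export, distribution
#' statistics) to `out_dir` when given. Results are deterministic for a
#' fixed configuration and master seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts.
#' @param quiet Suppress stage logging.
#' @return A `pipeline_result` list with all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  hash <- config_hash(config)
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  ocfg <- optical_config(frame_height_px = config$frame_height_px,
                         frame_width_px = config$frame_width_px)

  stage_log(quiet, "simulate", "layout %d x %d x %d x %d, seed %d",
            length(config$catalog), config$samples_per_drug,
            config$videos_per_sample, config$frames_per_video, seed)
  ds <- run("simulate", build_dataset(
    config$catalog, config$samples_per_drug, config$videos_per_sample,
    config$frames_per_video, config$sim, ocfg,
    seed = derive_seed(seed, 101L)))

  stage_log(quiet, "preprocess", "crop %d, split %.2f", config$crop_size,
            config$split_fraction)
  split <- run("split", split_train_test(ds, config$split_fraction,
                                         seed = derive_seed(seed, 102L)))
  prep <- run("normalize", preprocess_split(split, config$crop_size))

  stage_log(quiet, "extract", "%d train + %d test frames",
            length(prep$train), length(prep$test))
  feat_train <- run("extract", extract_feature_table(prep$train))
  feat_test <- run("extract", extract_feature_table(prep$test))
  fnames <- feature_names()

  stage_log(quiet, "select", "LOF frac %.2f (k=%d), |PCC| >= %.2f",
            config$lof_fraction, config$lof_k, config$pcc_threshold)
  out <- run("lof", remove_outliers(feat_train[, fnames],
                                    fraction = config$lof_fraction,
                                    k = config$lof_k))
  feat_train_kept <- feat_train[out$kept, , drop = FALSE]
  mask <- run("pcc", collinearity_filter(
    feat_train_kept[, fnames], threshold = config$pcc_threshold,
    seed = derive_seed(seed, 103L)))
  stage_log(quiet, "select", "%d -> %d features, %d -> %d samples",
            length(fnames), length(mask$kept), nrow(feat_train),
            length(out$kept))

  Xtr <- feat_train_kept[, mask$kept, drop = FALSE]
  ytr <- feat_train_kept$drug
  Xte <- feat_test[, mask$kept, drop = FALSE]
  yte <- feat_test$drug

  stage_log(quiet, "train", "family %s, grid size %d, %d-fold CV",
            config$family, length(config$grid), config$cv_folds)
  gs <- if (length(config$grid) > 1L)
    run("grid_search", grid_search(Xtr, ytr, config$family, config$grid,
                                   folds = config$cv_folds,
                                   seed = derive_seed(seed, 104L)))
  else list(best = config$grid[[1L]], cv_accuracy = NA_real_,
            best_index = 1L)
  model <- run("train", train_model(Xtr, ytr, config$family, gs$best,
                                    seed = derive_seed(seed, 105L)))

  report <- run("evaluate", evaluate_model(model, Xte, yte,
                                           n_boot = config$n_boot,
                                           seed = derive_seed(seed, 106L)))
  stage_log(quiet, "evaluate", "accuracy %.3f, AUC %.3f",
            report$metrics$value[report$metrics$metric == "accuracy"],
            report$metrics$value[report$metrics$metric == "auc"])

  nb <- min(config$shap_background, nrow(Xtr))
  ns <- min(config$shap_samples, nrow(Xte))
  sidx <- withr::with_seed(derive_seed(seed, 108L),
                           sample.int(nrow(Xte), ns))
  shap_X <- as.matrix(Xte[sidx, , drop = FALSE])
  shap <- run("explain", {
    bidx <- withr::with_seed(derive_seed(seed, 107L),
                             sample.int(nrow(Xtr), nb))
    shapley_values(function(M) predict_proba(model, M),
                   Xtr[bidx, , drop = FALSE], shap_X,
                   n_permutations = config$shap_permutations,
                   seed = derive_seed(seed, 109L))
  })
  importance <- global_importance(shap)
  stage_log(quiet, "explain", "top feature: %s", names(importance)[1])

  dstats <- run("stats", distribution_stats(
    prep$train, unit = config$stats_unit))
  stage_log(quiet, "stats", "ANOVA F = %.2f (p = %.3g)",
            dstats$anova$F, dstats$anova$p)

  result <- structure(list(
    config = config, config_hash = hash, dataset = ds, split = split,
    normalizer = prep$normalizer, features_train = feat_train,
    features_test = feat_test, outliers = out, mask = mask,
    grid = gs, model = model, report = report, shap = shap,
    shap_X = shap_X, importance = importance, stats = dstats),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' Write pipeline artifacts to a directory
#'
#' Emits `features.csv` (train + test with a split column),
#' `mask.json`, `report.json` (confusion matrix, metrics with CIs, best
#' parameters, config hash), `shap.csv`, `stats.json` and
#' `config.json`.
#'
#' @param result A `pipeline_result`. @param out_dir Directory.
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ftr <- cbind(split = "train", result$features_train)
  fte <- cbind(split = "test", result$features_test)
  utils::write.csv(rbind(ftr, fte), file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(kept = result$mask$kept, dropped = result$mask$dropped,
         threshold = result$mask$threshold, seed = result$mask$seed),
    file.path(out_dir, "mask.json"), auto_unbox = TRUE, digits = NA)
  rep <- result$report
  jsonlite::write_json(
    list(config_hash = result$config_hash, family = rep$family,
         best_params = rep$params,
         confusion = list(classes = rownames(rep$confusion),
                          counts = unname(apply(rep$confusion, 1, c,
                                                simplify = FALSE))),
         metrics = rep$metrics, per_class = rep$per_class,
         n_test = rep$n_test),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  shap_tabs <- lapply(result$shap$classes, function(cl)
    cbind(class = cl, beeswarm_export(result$shap, result$shap_X, cl)))
  utils::write.csv(do.call(rbind, shap_tabs),
                   file.path(out_dir, "shap.csv"), row.names = FALSE)
  st <- result$stats
  jsonlite::write_json(
    list(unit = st$unit, anova = st$anova, tukey = st$tukey),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  cfg <- result$config
  cfg$catalog <- lapply(cfg$catalog, unclass)
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
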
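# End-to-end orchestration: preprocess (tile -> QC -> normalize) -> bags ->
# split -> train the six-variant ensemble -> predict -> report. The
# full-synthetic-demo mode exercises the whole flow with zero external
# inputs; train/infer modes work from a cohort manifest CSV on disk.

#' Pipeline configuration
#'
#' @param cohort_manifest Path to a cohort manifest CSV
#'   (`slide_id,label,path,...`); not needed for the synthetic demo.
#' @param work_dir Directory for run artifacts (`NULL` = keep in memory
#'   only).
#' @param tile_size_px,overlap_px,levels Tiling parameters.
#' @param thresholds A [qc_thresholds()] object.
#' @param reference A [fit_reference()] object or path to a reference JSON;
#'   `NULL` uses [default_reference()].
#' @param model_configs Named list of [model_config()] objects (default: the
#'   six-variant ensemble).
#' @param split_ratios Train/val/test ratios.
#' @param seed Global seed; stage seeds are derived from it.
#' @param verbose Log per-stage progress and counts.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort_manifest = NULL, work_dir = NULL,
                            tile_size_px = 64, overlap_px = 16,
                            levels = c("40x", "20x"),
                            thresholds = qc_thresholds(),
                            reference = NULL,
                            model_configs = NULL,
                            split_ratios = c(0.6, 0.2, 0.2),
                            seed = 0, verbose = TRUE) {
  if (is.character(reference)) reference <- read_reference(reference)
  if (is.null(model_configs))
    model_configs <- default_ensemble_configs(seed, input_size_px = tile_size_px)
  structure(
    list(cohort_manifest = cohort_manifest, work_dir = work_dir,
         tile_size_px = tile_size_px, overlap_px = overlap_px,
         levels = levels, thresholds = thresholds, reference = reference,
         model_configs = model_configs, split_ratios = split_ratios,
         seed = seed, verbose = verbose),
    class = "pipeline_config"
  )
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[wsiscreen] ", fmt), ...))
}

#' Preprocess one slide raster into normalized, QC-passing tiles
#'
#' Tiling across the magnification pyramid, the four-stage QC cascade, then
#' stain normalization of the surviving tiles.
#'
#' @param raster Slide raster at the highest requested level.
#' @param slide_id Identifier stamped on the tiles.
#' @param config A [pipeline_config()].
#' @return List with `tiles` (normalized QC-passing tile records) and `qc`
#'   (per-tile QC data frame).
#' @export
preprocess_slide <- function(raster, slide_id, config = pipeline_config()) {
  tiles <- tile_slide(raster, slide_id, config$levels,
                      config$tile_size_px, config$overlap_px)
  tiles <- qc_tiles(tiles, config$thresholds)
  qc_df <- qc_summary(tiles)
  ref <- config$reference %||% default_reference()
  passed <- Filter(function(t) isTRUE(t$qc$passed), tiles)
  passed <- lapply(passed, function(t) {
    t$raster <- normalize_tile(t$raster, ref)
    t
  })
  list(tiles = passed, qc = qc_df)
}

preprocess_cohort <- function(rasters, ids, config) {
  all_tiles <- list()
  qc_rows <- list()
  for (i in seq_along(rasters)) {
    pre <- preprocess_slide(rasters[[i]], ids[i], config)
    all_tiles <- c(all_tiles, pre$tiles)
    qc_rows[[i]] <- pre$qc
    log_stage(config$verbose, "slide %s: %d/%d tiles pass QC",
              ids[i], length(pre$tiles), nrow(pre$qc))
  }
  list(tiles = all_tiles, qc = do.call(rbind, qc_rows))
}

train_ensemble <- function(configs, train_bags, val_bags, verbose = FALSE) {
  models <- list()
  for (nm in names(configs)) {
    log_stage(verbose, "training %s (%s%s)", nm, configs[[nm]]$backbone,
              if (configs[[nm]]$attention) "+attention" else "")
    models[[nm]] <- train_model(configs[[nm]], train_bags, val_bags)
    log_stage(verbose, "  stopped after %d epochs (best %d, val loss %.4f)",
              nrow(models[[nm]]$history), models[[nm]]$best_epoch,
              models[[nm]]$history$val_loss[models[[nm]]$best_epoch])
  }
  models
}

predictions_frame <- function(predictions) {
  do.call(rbind, lapply(predictions, function(p) {
    row <- data.frame(slide_id = p$slide_id, stringsAsFactors = FALSE)
    for (nm in names(p$votes)) row[[paste0("vote_", nm)]] <- p$votes[[nm]]
    for (nm in names(p$probabilities))
      row[[paste0("prob_", nm)]] <- p$probabilities[[nm]]
    row$confidence <- p$confidence
    row$decision <- p$decision
    row
  }))
}

model_metrics_frame <- function(models, bags, truths) {
  probs <- lapply(models, function(m)
    vapply(bags, function(b) forward_bag(m, b)$bag_probability, numeric(1)))
  do.call(rbind, lapply(names(models), function(nm) {
    pr <- probs[[nm]]
    mt <- binary_metrics(pr >= 0.5, truths)
    data.frame(model = nm, accuracy = mt$accuracy, precision = mt$precision,
               recall = mt$recall, f1 = mt$f1,
               auc = auc_score(pr, truths), stringsAsFactors = FALSE)
  }))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a labelled synthetic cohort, preprocesses every slide (tiling,
#' QC, normalization), builds bags, splits slides 6:2:2 stratified by label,
#' trains the six-variant ensemble, and evaluates per-model metrics and the
#' consensus report on the held-out test slides. Entirely self-contained and
#' reproducible from `(arguments, seed)`.
#'
#' @param n_positive,n_negative Cohort composition (default 20/20, giving a
#'   24/8/8 slide split).
#' @param seed Global seed.
#' @param config A [pipeline_config()]; its `seed` field is overridden by
#'   `seed`.
#' @param slide_px Edge length of the synthetic slides.
#' @return An object of class `"demo_result"`: `qc`, `bags` summary,
#'   `split`, trained `models`, per-model `model_metrics`, test-set
#'   `predictions` (data frame) and `ensemble` ([ensemble_report()]).
#' @export
run_synthetic_demo <- function(n_positive = 20, n_negative = 20, seed = 0,
                               config = pipeline_config(seed = seed),
                               slide_px = 160) {
  config$seed <- seed
  verbose <- config$verbose
  log_stage(verbose, "generating synthetic cohort (%d positive, %d negative)",
            n_positive, n_negative)
  cohort <- generate_cohort(n_positive, n_negative, base_seed = seed,
                            overrides = list(width_px = slide_px,
                                             height_px = slide_px))
  ids <- vapply(cohort, function(s) s$spec$slide_id, character(1))
  labels <- stats::setNames(vapply(cohort, function(s) s$spec$label,
                                   character(1)), ids)

  pre <- preprocess_cohort(lapply(cohort, function(s) s$raster), ids, config)
  bags <- build_bags(pre$tiles, labels)
  bag_ids <- vapply(bags, function(b) b$slide_id, character(1))

  split <- split_slides(bag_ids, config$split_ratios,
                        seed = derive_seed(seed, 2), labels = labels[bag_ids])
  part <- split$assignment
  train_bags <- bags[part[bag_ids] == "train"]
  val_bags <- bags[part[bag_ids] == "val"]
  test_bags <- bags[part[bag_ids] == "test"]
  log_stage(verbose, "split: %d train / %d val / %d test bags",
            length(train_bags), length(val_bags), length(test_bags))

  models <- train_ensemble(config$model_configs, train_bags, val_bags,
                           verbose)

  predictions <- lapply(test_bags, function(b) predict_slide(models, b))
  test_truth <- stats::setNames(
    vapply(test_bags, function(b) b$label, character(1)),
    vapply(test_bags, function(b) b$slide_id, character(1)))
  decisions <- score_decisions(predictions, test_truth)
  report <- ensemble_report(decisions)
  metrics <- model_metrics_frame(models, test_bags, unname(test_truth))
  log_stage(verbose, "ensemble on %d test slides: %d%% correct, %d%% indecision, %d%% incorrect",
            report$n, report$percent_correct, report$percent_indecision,
            report$percent_incorrect)

  result <- structure(
    list(qc = pre$qc,
         bags = data.frame(slide_id = bag_ids,
                           label = unname(labels[bag_ids]),
                           instance_count = vapply(bags, function(b)
                             b$instance_count, integer(1)),
                           partition = unname(part[bag_ids]),
                           stringsAsFactors = FALSE),
         split = split, models = models,
         model_metrics = metrics,
         predictions = predictions_frame(predictions),
         decisions = decisions,
         ensemble = report,
         seed = seed),
    class = "demo_result"
  )
  if (!is.null(config$work_dir)) write_run_artifacts(result, config)
  result
}

write_run_artifacts <- function(result, config) {
  dir.create(config$work_dir, recursive = TRUE, showWarnings = FALSE)
  wd <- config$work_dir
  utils::write.csv(result$qc, file.path(wd, "tiles_qc.csv"), row.names = FALSE)
  utils::write.csv(result$bags, file.path(wd, "bags.csv"), row.names = FALSE)
  utils::write.csv(result$predictions, file.path(wd, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(result$model_metrics, file.path(wd, "model_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = result$seed,
         split = as.list(result$split$assignment),
         ensemble = unclass(result$ensemble)),
    file.path(wd, "run.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(result$models)) {
    save_model(result$models[[nm]], file.path(wd, paste0(nm, ".rds")))
    utils::write.csv(result$models[[nm]]$history,
                     file.path(wd, paste0(nm, "_history.csv")),
                     row.names = FALSE)
  }
  invisible(wd)
}

#' @export
print.demo_result <- function(x, ...) {
  cat(sprintf("<demo result> %d slides, %d models\n", nrow(x$bags),
              length(x$models)))
  print(x$ensemble)
  invisible(x)
}

read_cohort_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("slide_id", "path") %in% names(m)))
    stop("cohort manifest needs at least slide_id and path columns",
         call. = FALSE)
  base <- dirname(path)
  m$path <- ifelse(file.exists(m$path), m$path, file.path(base, m$path))
  m
}

#' Run the pipeline in one of its modes
#'
#' `"full-synthetic-demo"` delegates to [run_synthetic_demo()].
#' `"train"` reads the cohort manifest (`slide_id,label,path` with PNG slide
#' rasters), preprocesses, splits, trains all configured models and writes
#' checkpoints plus manifests under `work_dir`. `"infer"` loads checkpoints
#' from `work_dir/`, preprocesses the manifest's slides and writes
#' `predictions.csv`.
#'
#' @param config A [pipeline_config()].
#' @param mode One of `"full-synthetic-demo"`, `"train"`, `"infer"`.
#' @return Mode-dependent: a `"demo_result"`, the trained model list, or
#'   the predictions data frame.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         mode = c("full-synthetic-demo", "train", "infer")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  if (mode == "full-synthetic-demo")
    return(run_synthetic_demo(seed = config$seed, config = config))

  if (is.null(config$cohort_manifest))
    stop("mode '", mode, "' requires a cohort_manifest", call. = FALSE)
  if (is.null(config$work_dir))
    stop("mode '", mode, "' requires a work_dir", call. = FALSE)
  manifest <- read_cohort_manifest(config$cohort_manifest)
  rasters <- lapply(manifest$path, read_tile_png)
  pre <- preprocess_cohort(rasters, manifest$slide_id, config)

  if (mode == "train") {
    if (is.null(manifest$label))
      stop("training requires a label column in the cohort manifest",
           call. = FALSE)
    labels <- stats::setNames(manifest$label, manifest$slide_id)
    bags <- build_bags(pre$tiles, labels)
    bag_ids <- vapply(bags, function(b) b$slide_id, character(1))
    split <- split_slides(bag_ids, config$split_ratios,
                          seed = derive_seed(config$seed, 2),
                          labels = labels[bag_ids])
    part <- split$assignment
    if (sum(part[bag_ids] == "val") == 0)
      stop("validation partition is empty; supply more slides or adjust ",
           "split_ratios", call. = FALSE)
    models <- train_ensemble(config$model_configs,
                             bags[part[bag_ids] == "train"],
                             bags[part[bag_ids] == "val"], config$verbose)
    dir.create(config$work_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pre$qc, file.path(config$work_dir, "tiles_qc.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(split$assignment),
                         file.path(config$work_dir, "split.json"),
                         auto_unbox = TRUE)
    for (nm in names(models))
      save_model(models[[nm]], file.path(config$work_dir, paste0(nm, ".rds")))
    return(invisible(models))
  }

  # infer
  ckpts <- list.files(config$work_dir, pattern = "\\.rds$", full.names = TRUE)
  if (length(ckpts) == 0)
    stop("no model checkpoints (*.rds) found in ", config$work_dir,
         call. = FALSE)
  models <- lapply(ckpts, load_model)
  names(models) <- sub("\\.rds$", "", basename(ckpts))
  labels <- stats::setNames(rep("negative", nrow(manifest)),
                            manifest$slide_id)  # placeholder; unused at inference
  bags <- build_bags(pre$tiles, labels)
  predictions <- predictions_frame(lapply(bags, function(b)
    predict_slide(models, b)))
  utils::write.csv(predictions,
                   file.path(config$work_dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(predictions)
}
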
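# End-to-end orchestration: preprocess -> per-backbone predict -> fuse ->
# evaluate, with every stage's artifacts persisted under one work
# directory and a run manifest recording versions, seeds and the config
# hash.

#' Pipeline configuration
#'
#' A single declarative configuration for [run_pipeline()].  Any field can
#' also be supplied through the command-line interface.
#'
#' @param work_dir Directory for all artifacts (created if needed).
#' @param manifest Path to an image manifest, or `NULL` to generate a
#'   synthetic dataset.
#' @param synth_n,synth_size Size of the synthetic dataset when `manifest`
#'   is `NULL`.
#' @param backbones Character vector of backbone names; repeated names are
#'   allowed and become independently seeded ensemble members.
#' @param loss_name,penalty_mode Loss for the basic models.
#' @param epochs_basic,epochs_hybrid Training epochs for the two stages.
#' @param hybrid_kind `"a"`, `"f"` or `"c"`.
#' @param eval_fraction Fraction of images held out (stratified by grade)
#'   for evaluation.
#' @param positive_grade Positive class for the binary metrics.
#' @param intensity_threshold Black-border binarisation threshold.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A list with class `drh_pipeline_config`.
#' @export
pipeline_config <- function(work_dir, manifest = NULL, synth_n = 200L,
                            synth_size = 64L,
                            backbones = c("TinyCNN", "TinyCNN", "TinyCNN"),
                            loss_name = "ce", penalty_mode = "hard",
                            epochs_basic = 5L, epochs_hybrid = 100L,
                            hybrid_kind = "a", eval_fraction = 0.25,
                            positive_grade = 0L, intensity_threshold = 10,
                            seed = 1L) {
  structure(list(work_dir = work_dir, manifest = manifest,
                 synth_n = as.integer(synth_n),
                 synth_size = as.integer(synth_size), backbones = backbones,
                 loss_name = loss_name, penalty_mode = penalty_mode,
                 epochs_basic = as.integer(epochs_basic),
                 epochs_hybrid = as.integer(epochs_hybrid),
                 hybrid_kind = hybrid_kind,
                 eval_fraction = eval_fraction,
                 positive_grade = as.integer(positive_grade),
                 intensity_threshold = intensity_threshold,
                 seed = as.integer(seed)),
            class = "drh_pipeline_config")
}

#' @noRd
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Stratified train/evaluation split by grade
#'
#' Selects the held-out set according to the grade ratio: within each
#' grade, `round(eval_fraction * count)` images are sampled for
#' evaluation.
#'
#' @param grades Integer grades.
#' @param eval_fraction Held-out fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `eval`.
#' @export
split_stratified <- function(grades, eval_fraction = 0.25, seed = 1L) {
  grades <- check_grades(grades)
  if (eval_fraction <= 0 || eval_fraction >= 1)
    stop_drh("eval_fraction must be in (0, 1)")
  with_seed_opt(seed, {
    ev <- unlist(lapply(0:4, function(g) {
      idx <- which(grades == g)
      if (length(idx) == 0L) return(integer(0))
      k <- min(length(idx), round(eval_fraction * length(idx)))
      if (k == 0L) return(integer(0))
      sample(idx, k)
    }))
    list(train = setdiff(seq_along(grades), ev), eval = sort(ev))
  })
}

#' @noRd
stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[drhybrid] stage %-12s started", name))
  res <- tryCatch(expr, error = function(e)
    stop_drh("stage '", name, "' failed: ", conditionMessage(e)))
  message(sprintf("[drhybrid] stage %-12s done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full grading pipeline
#'
#' Executes the three published steps — image preprocessing, base-model
#' prediction, and hybrid fusion — followed by evaluation, entirely from
#' one configuration.  Reruns with an identical configuration and seed
#' produce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the `metrics_report`, the predictions
#'   data frame, and the paths of the persisted artifacts.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "drh_pipeline_config"))
    stop_drh("config must come from pipeline_config()")
  dir.create(config$work_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- stage("data", {
    if (is.null(config$manifest)) {
      gen_fundus_dataset(config$synth_n, file.path(config$work_dir, "data"),
                         size = config$synth_size, seed = config$seed)
    } else {
      if (!file.exists(config$manifest))
        stop_drh("manifest not found: ", config$manifest)
      config$manifest
    }
  })

  df <- read_manifest(manifest)

  prep <- stage("preprocess", {
    out <- list()
    for (nm in unique(config$backbones)) {
      out[[nm]] <- preprocess_manifest(
        manifest, file.path(config$work_dir, paste0("prep_", nm)),
        model_name = nm,
        intensity_threshold = config$intensity_threshold)
    }
    out
  })

  split <- split_stratified(df$grade, config$eval_fraction,
                            seed = config$seed + 1L)

  outputs <- stage("basic-models", {
    rows <- list()
    for (b in seq_along(config$backbones)) {
      nm <- config$backbones[b]
      tag <- sprintf("%s_%d", nm, b)
      imgs <- load_graded_images(prep[[nm]])
      spec <- backbone_spec(nm)
      model <- build_basic_model(spec, seed = config$seed + 10L + b)
      cfg <- train_config(optimizer_name = "radam",
                          initial_learning_rate = 8e-4,
                          epochs = config$epochs_basic,
                          loss_name = config$loss_name,
                          penalty_mode = config$penalty_mode,
                          batch_size = spec$batch_size,
                          seed = config$seed + 100L + b)
      model <- train_basic_model(model, imgs[split$train], cfg)
      utils::write.table(
        model$history, file.path(config$work_dir, paste0("history_", tag, ".csv")),
        sep = ",", row.names = FALSE, quote = FALSE)
      save_model(model, file.path(config$work_dir, paste0(tag, ".rds")))
      p <- predict_probabilities(model, imgs)
      rows[[tag]] <- data.frame(image_id = basename(df$image_path),
                                grade = df$grade, p, model_name = tag,
                                check.names = FALSE)
    }
    do.call(rbind, rows)
  })
  outputs_path <- file.path(config$work_dir, "outputs.csv")
  write_outputs_csv(outputs, outputs_path)

  fusion <- stage("hybrid", {
    set <- read_outputs_csv(outputs_path)
    train_set <- subset_outputs(set, split$train)
    eval_set <- subset_outputs(set, split$eval)
    M <- length(set$model_order)
    fuser <- switch(config$hybrid_kind,
      a = build_hybrid_a(hybrid_spec("a", n_models = M)),
      f = build_hybrid_f(hybrid_spec("f", n_models = M),
                         seed = config$seed + 2L),
      c = build_hybrid_c(hybrid_spec("c", n_models = M),
                         seed = config$seed + 2L),
      stop_drh("hybrid_kind must be one of a, f, c"))
    if (config$hybrid_kind != "a") {
      fuser <- train_hybrid(fuser, train_set, train_config(
        optimizer_name = "adam", initial_learning_rate = 1e-3,
        epochs = config$epochs_hybrid, loss_name = "ce",
        batch_size = 128L, seed = config$seed + 3L))
      save_model(fuser, file.path(config$work_dir, "fuser.rds"))
    }
    pr <- predict_hybrid(fuser, eval_set)
    list(eval_set = eval_set, pred = pr)
  })

  report <- stage("evaluate", {
    pred_df <- data.frame(image_id = fusion$eval_set$ids %||%
                            sprintf("img_%05d", split$eval),
                          grade = fusion$eval_set$grades,
                          predicted = fusion$pred$grade,
                          fusion$pred$probabilities, check.names = FALSE)
    write.csv(pred_df, file.path(config$work_dir, "predictions.csv"),
              row.names = FALSE, quote = FALSE)
    rep <- evaluate_model(fusion$eval_set$grades, fusion$pred$grade,
                          config$positive_grade)
    write_metrics_report(rep, file.path(config$work_dir, "metrics.csv"))
    rep
  })

  run_manifest <- list(
    package_version = as.character(packageVersion("drhybrid")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = digest::digest(unclass(config)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(run_manifest,
                       file.path(config$work_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(report = report,
                 predictions = file.path(config$work_dir, "predictions.csv"),
                 outputs = outputs_path, work_dir = config$work_dir))
}

#' Subset a base_outputs_set by sample index
#'
#' @param set A `base_outputs_set`.
#' @param idx Integer sample indices.
#' @return The subset `base_outputs_set`.
#' @export
subset_outputs <- function(set, idx) {
  structure(list(probs = set$probs[idx, , , drop = FALSE],
                 grades = set$grades[idx],
                 model_order = set$model_order,
                 ids = set$ids[idx]),
            class = "base_outputs_set")
}
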
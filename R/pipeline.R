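# Pipeline entry points behind the command-line script (inst/cli).  Each
# stage derives its own seed from the master seed, logs counts, and writes
# artifacts carrying the config hash that produced them.

#' Save / load a model checkpoint
#'
#' One JSON archive with the model config, flat parameter vector, fitted
#' scaling and the schema hash; loading refuses a checkpoint whose schema
#' hash does not match the supplied schema.
#'
#' @param fit an `adaptivenet` model.
#' @param path output file (JSON).
#' @return `path` invisibly / the restored `adaptivenet` object.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "adaptivenet"))
  obj <- list(kind = "adaptivenet_checkpoint",
              task = fit$task,
              config = unclass(fit$config),
              dims = as.list(fit$dims),
              params = fit$params,
              scaling = as.data.frame(unclass(fit$scaling)),
              schema_hash = fit$schema_hash,
              best_epoch = fit$best_epoch)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname save_checkpoint
#' @param schema schema the checkpoint must match.
#' @export
load_checkpoint <- function(path, schema = default_schema()) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$kind, "adaptivenet_checkpoint"))
    stop_anet("not an adaptivenet checkpoint: ", path,
              class = "anet_validation_error")
  if (!identical(obj$schema_hash, schema_hash(schema)))
    stop_anet("checkpoint schema hash ", obj$schema_hash,
              " does not match the supplied schema (",
              schema_hash(schema), ")", class = "anet_validation_error")
  scaling <- as.data.frame(obj$scaling)
  class(scaling) <- c("anet_scaling", "data.frame")
  cfg <- do.call(anet_config, obj$config)
  structure(list(params = as.numeric(obj$params),
                 dims = do.call(c, lapply(obj$dims, as.integer)),
                 config = cfg, task = obj$task, schema = schema,
                 scaling = scaling, schema_hash = obj$schema_hash,
                 best_epoch = obj$best_epoch,
                 loss_trace = data.frame()),
            class = "adaptivenet")
}

#' Simulate a registry to disk
#'
#' Wraps [simulate_registry()] + [write_registry()]; the manifest records
#' every generator parameter.
#'
#' @param out_dir output directory.
#' @param config an [sim_config()].
#' @return The registry, invisibly.
#' @export
run_simulate <- function(out_dir, config = sim_config()) {
  reg <- simulate_registry(config)
  write_registry(reg, out_dir)
  message(sprintf("wrote registry (%d patients, %d visits, %d medication events) to %s",
                  nrow(reg$patients), nrow(reg$visits),
                  nrow(reg$medications), out_dir))
  invisible(reg)
}

#' Train and evaluate on a registry directory
#'
#' Full protocol: cohort construction, patient-level k-fold
#' cross-validation, AdaptiveNet and baselines, metric and subgroup
#' reports written as delimited text.
#'
#' @param registry_dir directory with the three registry tables.
#' @param out_dir output directory for reports and checkpoints.
#' @param task `"classification"`, `"regression"`, or `"both"`.
#' @param models models to run (see [cross_validate()]).
#' @param k folds.
#' @param config an [anet_config()].
#' @param seed master seed.
#' @param subgroups evaluate Table-style subgroup metrics for AdaptiveNet.
#' @return Named list of `anet_cv` objects, invisibly.
#' @export
run_train_eval <- function(registry_dir, out_dir,
                           task = c("classification", "regression", "both"),
                           models = c("adaptivenet", "random_forest",
                                      "linear", "svm"),
                           k = 5L, config = anet_config(), seed = 1L,
                           subgroups = TRUE) {
  task <- match.arg(task)
  tasks <- if (task == "both") c("classification", "regression") else task
  registry <- read_registry(registry_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- list()
  for (tk in tasks) {
    t0 <- Sys.time()
    cv <- cross_validate(registry, tk, models, k = k, config = config,
                         seed = seed)
    write_report(cv, file.path(out_dir, paste0("metrics_", tk, ".csv")))
    utils::write.csv(cv$metrics,
                     file.path(out_dir, paste0("fold_metrics_", tk, ".csv")),
                     row.names = FALSE, na = "")
    if (subgroups && "adaptivenet" %in% models) {
      sg <- evaluate_subgroups(cv)
      write_report(sg, file.path(out_dir, paste0("subgroups_", tk, ".csv")))
    }
    message(sprintf("[%s] %d instances, %d folds, models: %s (%.1f s)",
                    tk, nrow(cv$instances$index), k,
                    paste(models, collapse = ", "),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out[[tk]] <- cv
  }
  run_cfg <- list(task = task, models = models, k = k,
                  config = unclass(config), seed = seed,
                  registry_dir = registry_dir,
                  schema_hash = schema_hash(default_schema()))
  jsonlite::write_json(run_cfg, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Impurity-based feature importance for a registry on disk
#'
#' Builds the flat instance view and ranks features by random-forest mean
#' decrease in weighted impurity (drug classes and individual drugs appear
#' as separate slots).
#'
#' @param registry_dir registry directory.
#' @param out_path optional CSV output.
#' @param task `"regression"` (importance for the score change) or
#'   `"classification"` (for the active-disease label).
#' @param seed integer seed.
#' @return The ranked importance data frame.
#' @export
run_importance <- function(registry_dir, out_path = NULL,
                           task = c("regression", "classification"),
                           seed = 1L) {
  task <- match.arg(task)
  registry <- read_registry(registry_dir)
  instances <- build_instances(registry)
  scaling <- fit_scaling(registry)
  fl <- flatten_instances(instances, scaling = scaling)
  y <- if (task == "regression") fl$delta else fl$label
  imp <- feature_importance(fl$x, y, task, seed = derive_seed(seed, "imp"))
  if (!is.null(out_path))
    utils::write.csv(imp, out_path, row.names = FALSE, na = "")
  imp
}

#' Per-instance forecasts from a checkpoint
#'
#' @param checkpoint_path JSON checkpoint from [save_checkpoint()].
#' @param registry_dir registry directory to predict on.
#' @param out_path optional CSV output.
#' @return Data frame with one row per eligible instance: score / predicted
#'   change and the clamped DAS28 forecast.
#' @export
run_predict <- function(checkpoint_path, registry_dir, out_path = NULL) {
  fit <- load_checkpoint(checkpoint_path)
  registry <- read_registry(registry_dir)
  instances <- build_instances(registry)
  if (nrow(instances$index) == 0) {
    warning("registry yields no eligible instances", call. = FALSE)
    out <- data.frame()
  } else if (fit$task == "regression") {
    delta <- predict(fit, instances, type = "delta")
    out <- cbind(instances$index[, c("patient_id", "reference_date",
                                     "target_date", "reference_das28")],
                 predicted_delta = delta,
                 forecast_das28 = clamp(instances$index$reference_das28 +
                                          delta, DAS28_MIN, DAS28_MAX),
                 observed_das28 = instances$index$target_das28)
  } else {
    out <- cbind(instances$index[, c("patient_id", "reference_date",
                                     "target_date", "reference_das28")],
                 score_active = predict(fit, instances, type = "response"),
                 observed_active = instances$index$label_active)
  }
  if (!is.null(out_path))
    utils::write.csv(out, out_path, row.names = FALSE, na = "")
  out
}
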
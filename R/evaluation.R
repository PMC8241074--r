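#' Confusion-matrix metrics at a decision threshold
#'
#' Positives are the active-disease class; a score greater than or equal to
#' the threshold is called positive.  With no positive (or no negative)
#' labels the corresponding rate is undefined and returned as `NA` with a
#' warning.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 labels (1 = active).
#' @param threshold decision threshold (default 0.5).
#' @return A list with `accuracy`, `sensitivity`, `specificity` and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pos <- scores >= threshold
  tp <- sum(pos & labels == 1); fn <- sum(!pos & labels == 1)
  tn <- sum(!pos & labels == 0); fp <- sum(pos & labels == 0)
  sens <- if (tp + fn == 0) {
    warning("no positive labels: sensitivity undefined", call. = FALSE)
    NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negative labels: specificity undefined", call. = FALSE)
    NA_real_
  } else tn / (tn + fp)
  list(accuracy = (tp + tn) / length(labels), sensitivity = sens,
       specificity = spec, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve and AUC
#'
#' The AUC is the all-pairs rank statistic `P(score+ > score-) + 0.5
#' P(tie)` (Mann-Whitney formulation); the curve is a threshold sweep over
#' the unique scores (score >= threshold called positive), anchored at
#' (0,0) and (1,1).  The trapezoid area under that curve equals the rank
#' statistic exactly, which the test suite asserts.
#'
#' @param scores numeric scores (any monotone scale).
#' @param labels 0/1 labels.
#' @return A list with `curve` (data frame `threshold, fpr, tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop_anet("ROC requires both classes present",
              class = "anet_validation_error")
  r <- rank(scores) # midranks: ties get half credit
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / npos, 0)
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / nneg, 0)
  curve <- data.frame(threshold = c(Inf, th, -Inf), fpr = c(0, fpr, 1),
                      tpr = c(0, tpr, 1))
  list(curve = curve, auc = auc)
}

# trapezoid area under the sweep curve; kept as an independent second route
# to the same quantity (see tests)
auc_trapezoid <- function(scores, labels) {
  cv <- roc_auc(scores, labels)$curve
  sum(diff(cv$fpr) * (utils::head(cv$tpr, -1) + utils::tail(cv$tpr, -1)) / 2)
}

#' Mean squared error on the DAS28 scale
#'
#' Applied to the reconstructed forecast (reference score + predicted
#' change, clamped to the instrument range), not to the raw change, so
#' regression results live on the reported scale.
#'
#' @param forecast predicted DAS28-BSR at the target visit.
#' @param target observed DAS28-BSR at the target visit.
#' @return Nonnegative scalar.
#' @export
mse_das28 <- function(forecast, target) {
  stopifnot(length(forecast) == length(target), length(target) >= 1)
  mean((forecast - target)^2)
}

#' Welch's unequal-variance t-test
#'
#' Closed-form two-sided Welch test with Welch-Satterthwaite degrees of
#' freedom, used to compare per-fold AUC values between two models or two
#' patient subgroups.  Degenerate convention: two zero-variance groups with
#' equal means give `t = 0, p = 1` (and `p = 0` when the means differ).
#'
#' @param a,b numeric vectors (e.g. 5 per-fold AUCs each).
#' @param alpha significance level for the `significant` flag.
#' @return A list with `t`, `df`, `p`, `significant`.
#' @export
welch_t_test <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    return(list(t = if (p == 1) 0 else sign(mean(a) - mean(b)) * Inf,
                df = NA_real_, p = p, significant = p <= alpha))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, significant = p <= alpha)
}

#' Impurity-based feature importance
#'
#' Fits the baseline random forest (100 trees, depth 12) and reports the
#' mean decrease in weighted impurity per feature, normalized to sum to 1
#' and ranked.  Slot naming keeps drug classes (`medication.drug_type=*`)
#' and individual drugs (`medication.drug=*`) as separate entries.
#'
#' @param x flattened instance matrix.
#' @param y target (label or change).
#' @param task `"classification"` or `"regression"`.
#' @param seed,num_trees,max_depth forest settings.
#' @return Data frame `feature, importance, rank`, importance summing to 1.
#' @export
feature_importance <- function(x, y, task = c("classification", "regression"),
                               seed = 1L, num_trees = 100L, max_depth = 12L) {
  task <- match.arg(task)
  fit <- fit_random_forest(x, y, task, num_trees = num_trees,
                           max_depth = max_depth, seed = seed)
  imp <- ranger::importance(fit$model)
  names(imp) <- fit$feature_names[match(names(imp),
                                        make.names(fit$feature_names,
                                                   unique = TRUE))]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             rank = seq_along(imp), row.names = NULL,
             stringsAsFactors = FALSE)
}

## ---- cross-validated evaluation pipeline ----

#' Cross-validated training and evaluation
#'
#' Runs the full protocol on a registry: instance construction,
#' patient-level k-fold assignment, per-fold scaling fitted on the training
#' patients only, AdaptiveNet and/or baseline fits, and per-fold test
#' metrics (accuracy/sensitivity/specificity/AUC for classification, MSE of
#' the reconstructed forecast for regression).
#'
#' @param registry an `ra_registry`.
#' @param task `"classification"` or `"regression"`.
#' @param models character subset of
#'   `c("adaptivenet", "random_forest", "linear", "svm")`.
#' @param k number of folds.
#' @param config an [anet_config()] for the network (its seed is re-derived
#'   per fold from `seed`).
#' @param seed master seed (folds, per-fold model seeds).
#' @param schema an `anet_schema`.
#' @return An object of class `anet_cv`: `metrics` (one row per fold x
#'   model), `predictions` (per test instance), `instances`, `folds`.
#' @export
cross_validate <- function(registry,
                           task = c("classification", "regression"),
                           models = c("adaptivenet", "random_forest",
                                      "linear", "svm"),
                           k = 5L, config = anet_config(), seed = 1L,
                           schema = default_schema()) {
  task <- match.arg(task)
  models <- match.arg(models, several.ok = TRUE)
  instances <- build_instances(registry, schema)
  folds <- assign_folds(instances, k = k, seed = seed)

  metrics <- list()
  preds <- list()
  for (f in seq_len(k)) {
    test_i <- which(folds$instance_fold == f)
    train_i <- which(folds$instance_fold != f)
    tr <- subset_instances(instances, train_i)
    te <- subset_instances(instances, test_i)
    scaling <- fit_scaling(registry, unique(tr$index$patient_id), schema)

    scores <- list()
    if ("adaptivenet" %in% models) {
      cfg <- config
      cfg$seed <- derive_seed(seed, "model", f)
      fit <- adaptivenet(tr, task, cfg, schema, scaling)
      scores$adaptivenet <- predict(fit, te, type = "response")
    }
    if (any(c("random_forest", "linear", "svm") %in% models)) {
      ftr <- flatten_instances(tr, schema, scaling)
      fte <- flatten_instances(te, schema, scaling)
      ytr <- if (task == "classification") ftr$label else ftr$delta
      if ("random_forest" %in% models) {
        bl <- fit_random_forest(ftr$x, ytr, task,
                                seed = derive_seed(seed, "rf", f))
        scores$random_forest <- predict(bl, fte$x)
      }
      if ("linear" %in% models) {
        bl <- fit_linear_or_logistic(ftr$x, ytr, task)
        scores$linear <- predict(bl, fte$x)
      }
      if ("svm" %in% models) {
        bl <- fit_svm(ftr$x, ytr, task)
        scores$svm <- predict(bl, fte$x)
      }
    }

    for (mname in names(scores)) {
      s <- scores[[mname]]
      preds[[length(preds) + 1L]] <- data.frame(
        model = mname, fold = f, instance = test_i,
        patient_id = te$index$patient_id, score = s,
        stringsAsFactors = FALSE)
      metrics[[length(metrics) + 1L]] <-
        cbind(data.frame(model = mname, fold = f,
                         n_test = length(test_i)),
              fold_metrics(s, te$index, task))
    }
  }
  structure(list(metrics = do.call(rbind, metrics),
                 predictions = do.call(rbind, preds),
                 instances = instances, folds = folds, task = task,
                 k = as.integer(k), seed = seed, models = models),
            class = "anet_cv")
}

# per-fold metric row from scores + instance index
fold_metrics <- function(scores, index, task) {
  if (task == "classification") {
    cm <- confusion_metrics(scores, index$label_active)
    auc <- roc_auc(scores, index$label_active)$auc
    data.frame(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
               specificity = cm$specificity, auc = auc, mse = NA_real_)
  } else {
    forecast <- clamp(index$reference_das28 + scores, DAS28_MIN, DAS28_MAX)
    data.frame(accuracy = NA_real_, sensitivity = NA_real_,
               specificity = NA_real_, auc = NA_real_,
               mse = mse_das28(forecast, index$target_das28))
  }
}

#' @export
print.anet_cv <- function(x, ...) {
  cat("Cross-validated", x$task, "over", x$k, "folds\n")
  print(summary(x))
  invisible(x)
}

#' Mean and SD of each metric over folds, per model
#' @param object an `anet_cv`.
#' @param ... unused.
#' @export
summary.anet_cv <- function(object, ...) {
  m <- object$metrics
  cols <- c("accuracy", "sensitivity", "specificity", "auc", "mse")
  out <- do.call(rbind, lapply(split(m, m$model), function(g) {
    row <- data.frame(model = g$model[1], n = sum(g$n_test))
    for (cc in cols) {
      row[[paste0(cc, "_mean")]] <- mean(g[[cc]])
      row[[paste0(cc, "_sd")]] <- stats::sd(g[[cc]])
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Subgroup evaluation of cross-validated predictions
#'
#' Recomputes the per-fold test metrics inside each patient subgroup (the
#' model is trained once on all patients; only the test instances are
#' filtered), reports mean and SD over folds per subgroup, and compares
#' complementary subgroup pairs with Welch's t-test on the per-fold AUCs
#' (classification) or per-fold MSEs (regression).
#'
#' @param cv an `anet_cv`.
#' @param model which model's predictions to evaluate.
#' @param criteria criteria names, see [subgroup_criteria()].
#' @return A list of class `anet_subgroups`: `table` (per-subgroup summary,
#'   including the `all` row), `per_fold`, and `tests` (pairwise Welch
#'   results).
#' @export
evaluate_subgroups <- function(cv, model = "adaptivenet",
                               criteria = names(subgroup_criteria())) {
  stopifnot(inherits(cv, "anet_cv"))
  pr <- cv$predictions[cv$predictions$model == model, , drop = FALSE]
  if (nrow(pr) == 0) stop_anet("no predictions for model '", model, "'")
  index <- cv$instances$index
  groups <- c(list(all = rep(TRUE, nrow(index))),
              stats::setNames(lapply(criteria, function(cr)
                subgroup_filter(cv$instances, cr)), criteria))

  per_fold <- list()
  for (g in names(groups)) {
    sel_g <- groups[[g]]
    for (f in sort(unique(pr$fold))) {
      prf <- pr[pr$fold == f, , drop = FALSE]
      in_g <- sel_g[prf$instance]
      if (sum(in_g) == 0) next
      idx <- index[prf$instance[in_g], , drop = FALSE]
      ok <- length(unique(idx$label_active)) == 2 ||
        cv$task == "regression"
      if (!ok) next
      per_fold[[length(per_fold) + 1L]] <-
        cbind(data.frame(subgroup = g, fold = f, n = sum(in_g)),
              fold_metrics(prf$score[in_g], idx, cv$task))
    }
  }
  per_fold <- do.call(rbind, per_fold)

  cols <- c("accuracy", "sensitivity", "specificity", "auc", "mse")
  tab <- do.call(rbind, lapply(split(per_fold, per_fold$subgroup),
                               function(g) {
    row <- data.frame(subgroup = g$subgroup[1], n_folds = nrow(g),
                      n = sum(g$n))
    for (cc in cols) {
      row[[paste0(cc, "_mean")]] <- mean(g[[cc]])
      row[[paste0(cc, "_sd")]] <- stats::sd(g[[cc]])
    }
    row
  }))
  tab <- tab[match(intersect(names(groups), tab$subgroup), tab$subgroup), ]
  rownames(tab) <- NULL

  stat_col <- if (cv$task == "classification") "auc" else "mse"
  tests <- list()
  for (pair in subgroup_pairs()) {
    a <- per_fold[per_fold$subgroup == pair[1], stat_col]
    b <- per_fold[per_fold$subgroup == pair[2], stat_col]
    if (length(a) < 2 || length(b) < 2) next
    w <- welch_t_test(a, b)
    tests[[paste(pair, collapse = "_vs_")]] <-
      data.frame(group_a = pair[1], group_b = pair[2], statistic = stat_col,
                 mean_a = mean(a), mean_b = mean(b), t = w$t, df = w$df,
                 p = w$p, significant = w$significant)
  }
  structure(list(table = tab, per_fold = per_fold,
                 tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
                 model = model, task = cv$task),
            class = "anet_subgroups")
}

#' @export
print.anet_subgroups <- function(x, ...) {
  cat("Subgroup evaluation (", x$model, ", ", x$task, ")\n", sep = "")
  print(x$table, digits = 3)
  if (!is.null(x$tests) && nrow(x$tests) > 0) {
    cat("\nComplementary-pair Welch tests:\n")
    print(x$tests, digits = 3)
  }
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' @param x an `anet_cv` or `anet_subgroups`.
#' @param path output file (CSV).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  tab <- if (inherits(x, "anet_subgroups")) x$table else summary(x)
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
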
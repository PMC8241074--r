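# Classical baselines on the flattened (last-visit + last-medication)
# instance view.  Uniform interface: every fit_* returns an `anet_baseline`
# with predict(model, x) -> numeric score (probability-like score for
# classification, predicted DAS28 change for regression).

new_baseline <- function(model, kind, task, extra = list()) {
  structure(c(list(model = model, kind = kind, task = task), extra),
            class = "anet_baseline")
}

check_task_labels <- function(y, task) {
  if (task == "classification" && length(unique(y)) < 2)
    stop_anet("classification training set has a single class",
              class = "anet_validation_error")
}

#' Random forest baseline
#'
#' 100 trees with maximum depth 12 (the published configuration), impurity
#' importance enabled, single-threaded for determinism.
#'
#' @param x numeric feature matrix (flattened instances).
#' @param y target: numeric change for regression, 0/1 label for
#'   classification.
#' @param task `"regression"` or `"classification"`.
#' @param num_trees,max_depth forest size and depth cap.
#' @param seed integer seed.
#' @return An `anet_baseline`.
#' @export
fit_random_forest <- function(x, y, task = c("regression", "classification"),
                              num_trees = 100L, max_depth = 12L, seed = 1L) {
  task <- match.arg(task)
  check_task_labels(y, task)
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x), unique = TRUE)
  df$..target.. <- if (task == "classification") factor(y, levels = c(0, 1))
                   else y
  fit <- ranger::ranger(
    dependent.variable.name = "..target..", data = df,
    num.trees = num_trees, max.depth = max_depth, seed = seed,
    importance = "impurity", num.threads = 1,
    probability = (task == "classification"))
  new_baseline(fit, "random_forest", task,
               list(feature_names = colnames(x)))
}

#' Linear / logistic regression baseline
#'
#' Ordinary least squares for the numeric change, logistic regression for
#' the active-disease label.
#'
#' @inheritParams fit_random_forest
#' @return An `anet_baseline`.
#' @export
fit_linear_or_logistic <- function(x, y,
                                   task = c("regression", "classification")) {
  task <- match.arg(task)
  if (any(!is.finite(x)))
    stop_anet("non-finite feature values", class = "anet_validation_error")
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x), unique = TRUE)
  df$..target.. <- y
  if (task == "regression") {
    fit <- stats::lm(..target.. ~ ., data = df)
  } else {
    if (length(unique(y)) < 2)
      warning("single-class labels: logistic fit is a degenerate constant",
              call. = FALSE)
    fit <- suppressWarnings(
      stats::glm(..target.. ~ ., data = df, family = stats::binomial()))
  }
  new_baseline(fit, "linear", task, list(feature_names = colnames(x)))
}

#' Support vector machine baseline
#'
#' Radial-basis-function kernel with regularization parameter `C = 10`
#' (epsilon-regression for the numeric change; C-classification for the
#' label, scored by the decision value oriented so that larger means
#' active).
#'
#' @inheritParams fit_random_forest
#' @param cost regularization parameter C.
#' @param gamma kernel width (default `1/ncol(x)`, the e1071 default).
#' @return An `anet_baseline`.
#' @export
fit_svm <- function(x, y, task = c("regression", "classification"),
                    cost = 10, gamma = 1 / ncol(x)) {
  task <- match.arg(task)
  check_task_labels(y, task)
  if (task == "regression") {
    fit <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    orient <- 1
  } else {
    fit <- e1071::svm(x, factor(y, levels = c(0, 1)),
                      type = "C-classification", kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    # decision-value sign depends on internal label order; orient on train
    orient <- if (roc_auc(dv, y)$auc >= 0.5) 1 else -1
  }
  new_baseline(fit, "svm", task, list(orient = orient))
}

#' @export
predict.anet_baseline <- function(object, x, ...) {
  if (object$kind == "random_forest") {
    df <- as.data.frame(x)
    names(df) <- make.names(colnames(x), unique = TRUE)
    p <- stats::predict(object$model, data = df, num.threads = 1)$predictions
    if (object$task == "classification") return(unname(p[, "1"]))
    return(unname(p))
  }
  if (object$kind == "linear") {
    df <- as.data.frame(x)
    names(df) <- make.names(colnames(x), unique = TRUE)
    type <- if (object$task == "classification") "response" else NULL
    # one-hot blocks are exactly collinear by construction; the
    # rank-deficiency note from predict.lm is expected and harmless
    p <- withCallingHandlers(
      if (is.null(type)) stats::predict(object$model, newdata = df)
      else stats::predict(object$model, newdata = df, type = type),
      warning = function(w) {
        if (grepl("rank-deficient", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    return(unname(p))
  }
  if (object$kind == "svm") {
    if (object$task == "regression")
      return(unname(stats::predict(object$model, x)))
    dv <- attr(stats::predict(object$model, x, decision.values = TRUE),
               "decision.values")[, 1]
    # squash the oriented decision value into (0,1) so all classifiers
    # share a probability-like score scale
    return(unname(stats::plogis(object$orient * dv)))
  }
  stop_anet("unknown baseline kind ", object$kind)
}

#' @export
print.anet_baseline <- function(x, ...) {
  cat("Baseline model:", x$kind, "(", x$task, ")\n")
  invisible(x)
}

#' Tune a baseline by random search
#'
#' Draws hyperparameter settings uniformly from a documented search space,
#' evaluates each on a patient-level holdout split of the training
#' instances, and refits the winner on all training data.  The searched
#' space and per-draw scores are returned for logging.
#'
#' @param x,y,task as in the `fit_*` functions.
#' @param patient_id per-row patient identifiers (for the holdout split).
#' @param kind `"random_forest"` or `"svm"`.
#' @param n_draws number of random draws.
#' @param seed integer seed.
#' @return An `anet_baseline` with a `search_log` element.
#' @export
tune_baseline <- function(x, y, task, patient_id,
                          kind = c("random_forest", "svm"),
                          n_draws = 10L, seed = 1L) {
  kind <- match.arg(kind)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, "tune"))
  pids <- unique(patient_id)
  hold <- sample(pids, max(1, floor(0.2 * length(pids))))
  itr <- !(patient_id %in% hold)
  score <- function(fitobj) {
    p <- predict(fitobj, x[!itr, , drop = FALSE])
    if (task == "regression") -mean((p - y[!itr])^2)
    else roc_auc(p, y[!itr])$auc
  }
  log <- list()
  best <- NULL
  for (i in seq_len(n_draws)) {
    if (kind == "random_forest") {
      hp <- list(num_trees = sample(c(50L, 100L, 200L), 1),
                 max_depth = sample(c(6L, 9L, 12L, 15L), 1))
      f <- fit_random_forest(x[itr, , drop = FALSE], y[itr], task,
                             num_trees = hp$num_trees,
                             max_depth = hp$max_depth, seed = seed + i)
    } else {
      hp <- list(cost = 10^stats::runif(1, -1, 2),
                 gamma = (1 / ncol(x)) * 10^stats::runif(1, -1, 1))
      f <- fit_svm(x[itr, , drop = FALSE], y[itr], task,
                   cost = hp$cost, gamma = hp$gamma)
    }
    s <- score(f)
    log[[i]] <- c(hp, score = s)
    if (is.null(best) || s > best$s) best <- list(s = s, hp = hp)
  }
  final <- if (kind == "random_forest")
    fit_random_forest(x, y, task, num_trees = best$hp$num_trees,
                      max_depth = best$hp$max_depth, seed = seed)
  else fit_svm(x, y, task, cost = best$hp$cost, gamma = best$hp$gamma)
  final$search_log <- log
  final$chosen <- best$hp
  final
}
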
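#' AdaptiveNet model configuration
#'
#' Architecture and optimization hyperparameters.  The optimizer settings
#' are pinned to the published procedure: Adam with learning rate `1e-4`,
#' batch size 256, MSE loss for regression and binary cross-entropy for
#' classification.  The second fully-connected layer of the visit and
#' medication encoders is one shared parameter block (always; the
#' architecture has no unshared variant here).  Activations are
#' rectified-linear in the encoders and head.
#'
#' @param latent_dim width of the shared latent event space.
#' @param encoder_hidden width of the first (type-specific) encoder layer.
#' @param lstm_hidden width of the LSTM pooling layer; also the length of
#'   the encoded-history vector.
#' @param head_hidden width of the prediction head's hidden layer.
#' @param learning_rate Adam learning rate (pinned default `1e-4`).
#' @param batch_size minibatch size (pinned default 256).
#' @param epochs training epochs; the returned model carries the parameters
#'   of the epoch with the lowest validation loss.
#' @param val_fraction fraction of training *patients* carved out as the
#'   validation split for checkpoint selection (0 disables and the final
#'   epoch is kept).
#' @param seed integer seed for weight initialisation and batch shuffling.
#' @return A list of class `anet_config`.
#' @export
anet_config <- function(latent_dim = 32L, encoder_hidden = 64L,
                        lstm_hidden = 64L, head_hidden = 64L,
                        learning_rate = 1e-4, batch_size = 256L,
                        epochs = 40L, val_fraction = 0.1, seed = 1L) {
  stopifnot(latent_dim >= 1, encoder_hidden >= 1, lstm_hidden >= 1,
            head_hidden >= 1, learning_rate > 0, batch_size >= 1, epochs >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_hidden = as.integer(encoder_hidden),
                 lstm_hidden = as.integer(lstm_hidden),
                 head_hidden = as.integer(head_hidden),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "anet_config")
}

anet_dims <- function(config, n_general) {
  c(Dv = 21L, Dm = 18L, H1 = config$encoder_hidden, L = config$latent_dim,
    H = config$lstm_hidden, G = as.integer(n_general),
    Hh = config$head_hidden)
}

anet_n_params <- function(d) {
  unname(d["H1"] * d["Dv"] + d["H1"] + d["H1"] * d["Dm"] + d["H1"] +
           d["L"] * d["H1"] + d["L"] + 4 * d["H"] * d["L"] +
           4 * d["H"] * d["H"] + 4 * d["H"] + d["Hh"] * (d["H"] + d["G"]) +
           d["Hh"] + d["Hh"] + 1)
}

# parameter layout (must mirror the C++ Off struct)
anet_param_shapes <- function(d) {
  list(W1_visits = c(d[["H1"]], d[["Dv"]]), b1_visits = c(d[["H1"]], 1),
       W1_meds = c(d[["H1"]], d[["Dm"]]), b1_meds = c(d[["H1"]], 1),
       W2_shared = c(d[["L"]], d[["H1"]]), b2_shared = c(d[["L"]], 1),
       W_lstm_x = c(4 * d[["H"]], d[["L"]]),
       W_lstm_h = c(4 * d[["H"]], d[["H"]]), b_lstm = c(4 * d[["H"]], 1),
       W_head = c(d[["Hh"]], d[["H"]] + d[["G"]]), b_head = c(d[["Hh"]], 1),
       W_out = c(1, d[["Hh"]]), b_out = c(1, 1))
}

anet_unflatten <- function(params, d) {
  shapes <- anet_param_shapes(d)
  out <- list()
  o <- 0L
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    k <- s[1] * s[2]
    out[[nm]] <- matrix(params[(o + 1):(o + k)], s[1], s[2])
    o <- o + k
  }
  stopifnot(o == length(params))
  out
}

anet_flatten <- function(plist) {
  unlist(lapply(plist, as.numeric), use.names = FALSE)
}

# He initialisation for the relu layers, small uniform for the LSTM,
# forget-gate bias at 1 (standard recurrent initialisation).
anet_init_params <- function(d, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, "init"))
  he <- function(r, c) matrix(stats::rnorm(r * c, 0, sqrt(2 / c)), r, c)
  H <- d[["H"]]
  u <- 1 / sqrt(H)
  b_lstm <- matrix(0, 4 * H, 1)
  b_lstm[(H + 1):(2 * H), 1] <- 1
  anet_flatten(list(
    W1_visits = he(d[["H1"]], d[["Dv"]]), b1_visits = matrix(0, d[["H1"]], 1),
    W1_meds = he(d[["H1"]], d[["Dm"]]), b1_meds = matrix(0, d[["H1"]], 1),
    W2_shared = he(d[["L"]], d[["H1"]]), b2_shared = matrix(0, d[["L"]], 1),
    W_lstm_x = matrix(stats::runif(4 * H * d[["L"]], -u, u), 4 * H, d[["L"]]),
    W_lstm_h = matrix(stats::runif(4 * H * H, -u, u), 4 * H, H),
    b_lstm = b_lstm,
    W_head = he(d[["Hh"]], H + d[["G"]]), b_head = matrix(0, d[["Hh"]], 1),
    W_out = he(1, d[["Hh"]]), b_out = matrix(0, 1, 1)))
}

#' Prepare instances for the network
#'
#' Encodes the registry tables once and represents every instance as its
#' date-sorted event index sequence (0 = visit, 1 = medication, with
#' 0-based columns into the encoded event matrices), plus the general
#' vector and targets.  Used internally by [adaptivenet()] and
#' [predict.adaptivenet()].
#'
#' @param instances an `anet_instances`.
#' @param schema an `anet_schema`.
#' @param scaling an `anet_scaling`.
#' @param task `"regression"` (target = score change) or `"classification"`
#'   (target = active-disease label).
#' @return A list consumed by the C++ forward/backward pass.
#' @keywords internal
#' @export
prepare_model_data <- function(instances, schema, scaling,
                               task = c("regression", "classification")) {
  task <- match.arg(task)
  enc <- encode_registry(instances$registry, schema, scaling)
  n <- nrow(instances$index)
  # the derived time-since-adjustment slot must not leak events outside the
  # instance window: a medication whose table predecessor is out of window
  # reads the slot as 0 ("no known predecessor"), served from a shadow copy
  n_med <- nrow(enc$medication)
  med_zero <- enc$medication
  if (n_med > 0) med_zero[, "time_since_adjustment"] <- 0
  med_pid <- instances$registry$medications$patient_id
  events <- vector("list", n)
  for (i in seq_len(n)) {
    h <- instances$history[[i]]
    # canonical order regardless of how events were supplied: by date,
    # medication before a same-day visit (stable)
    h <- h[order(h$date, h$type == "visit"), , drop = FALSE]
    col <- as.integer(h$row) - 1L
    is_med <- h$type == "medication"
    if (any(is_med)) {
      first_med <- h$row[is_med][1]
      prev_in_window <- first_med > 1 &&
        (first_med - 1L) %in% h$row[is_med] # predecessor row visible?
      has_prev <- first_med > 1 &&
        med_pid[first_med - 1L] == med_pid[first_med]
      if (has_prev && !prev_in_window) {
        j <- which(is_med)[1]
        col[j] <- col[j] + n_med # point at the zeroed shadow column
      }
    }
    events[[i]] <- rbind(type = as.integer(is_med), col = col)
  }
  gen_i <- match(instances$index$patient_id,
                 instances$registry$patients$patient_id)
  target <- if (task == "regression") instances$index$delta_das28
            else as.numeric(instances$index$label_active)
  list(xv = t(enc$visit), xm = cbind(t(enc$medication), t(med_zero)),
       general = t(enc$general[gen_i, , drop = FALSE]),
       events = events, target = target,
       reference_das28 = instances$index$reference_das28,
       patient_id = instances$index$patient_id,
       n = n, task_code = if (task == "regression") 0L else 1L)
}

#' Fit an AdaptiveNet model
#'
#' Trains the recurrent event-history network on prediction instances with
#' Adam at the pinned learning rate and batch size, minimising MSE on the
#' DAS28-BSR change (regression) or binary cross-entropy on the
#' active-disease label (classification).  A patient-level validation split
#' is carved from the training instances and the parameters of the best
#' validation epoch are kept.
#'
#' @param instances an `anet_instances` from [build_instances()] (training
#'   instances only; use [subset_instances()] for fold splits).
#' @param task `"regression"` or `"classification"`.
#' @param config an [anet_config()].
#' @param schema an `anet_schema`.
#' @param scaling an `anet_scaling`; when `NULL`, fitted on the given
#'   instances' patients (for cross-validation pass the fold-train scaling
#'   explicitly).
#' @return An object of class `adaptivenet` with methods `print`,
#'   `summary`, `coef`, `predict`, `plot`, `residuals`.
#' @export
adaptivenet <- function(instances,
                        task = c("regression", "classification"),
                        config = anet_config(),
                        schema = default_schema(),
                        scaling = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(instances, "anet_instances"))
  if (nrow(instances$index) < 1)
    stop_anet("no training instances", class = "anet_validation_error")
  if (is.null(scaling))
    scaling <- fit_scaling(instances$registry,
                           unique(instances$index$patient_id), schema)
  data <- prepare_model_data(instances, schema, scaling, task)
  dims <- anet_dims(config, nrow(data$general))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(config$seed, "train"))

  # patient-level validation split
  pids <- unique(data$patient_id)
  n_val_p <- floor(config$val_fraction * length(pids))
  val_pids <- if (n_val_p > 0) sample(pids, n_val_p) else character(0)
  val_idx <- which(data$patient_id %in% val_pids)
  train_idx <- setdiff(seq_len(data$n), val_idx)
  if (length(train_idx) == 0)
    stop_anet("validation split left no training instances")

  params <- anet_init_params(dims, config$seed)
  m <- v <- numeric(length(params))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))

  eval_loss <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    tot <- 0
    for (ch in split(idx, ceiling(seq_along(idx) / 4096))) {
      r <- anet_pass(params, dims, data, ch, data$task_code, FALSE)
      tot <- tot + r$loss * length(ch)
    }
    tot / length(idx)
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bidx in batches) {
      r <- anet_pass(params, dims, data, bidx, data$task_code, TRUE)
      if (!is.finite(r$loss))
        stop_anet("non-finite training loss at epoch ", epoch,
                  "; check feature scaling and learning rate",
                  class = "anet_runtime_error")
      g <- r$grad
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      params <- params - lr * mhat / (sqrt(vhat) + eps)
      ep_loss <- ep_loss + r$loss * length(bidx)
    }
    ep_loss <- ep_loss / length(ord)
    vl <- eval_loss(val_idx)
    trace <- rbind(trace, data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = vl))
    sel <- if (is.na(vl)) ep_loss else vl
    if (sel < best$loss) best <- list(loss = sel, params = params,
                                      epoch = epoch)
  }

  fit <- structure(list(
    params = best$params, dims = dims, config = config, task = task,
    schema = schema, scaling = scaling, loss_trace = trace,
    best_epoch = best$epoch, schema_hash = schema_hash(schema),
    n_train = length(train_idx), n_val = length(val_idx),
    call = match.call()), class = "adaptivenet")
  # training residuals on the fitted scale
  pr <- predict(fit, instances, type = if (task == "regression") "delta"
                                       else "response")
  fit$residuals <- data$target - pr
  fit$fitted_values <- pr
  fit
}

#' Predict from a fitted AdaptiveNet model
#'
#' @param object an `adaptivenet` fit.
#' @param instances an `anet_instances` to predict for.
#' @param type `"response"` (classification probability / score change),
#'   `"delta"` (score change), `"forecast"` (reference DAS28-BSR plus
#'   predicted change, clamped to the instrument range; regression only),
#'   or `"link"` (raw network output).
#' @param ... unused.
#' @return Numeric vector, one value per instance.
#' @export
predict.adaptivenet <- function(object, instances,
                                type = c("response", "delta", "forecast",
                                         "link"), ...) {
  type <- match.arg(type)
  data <- prepare_model_data(instances, object$schema, object$scaling,
                             object$task)
  y <- numeric(data$n)
  for (ch in split(seq_len(data$n), ceiling(seq_len(data$n) / 4096))) {
    r <- anet_pass(object$params, object$dims, data, ch, data$task_code,
                   FALSE)
    y[ch] <- r$pred
  }
  if (type == "link") return(y)
  if (object$task == "classification") {
    if (type %in% c("delta", "forecast"))
      stop_anet("type '", type, "' is only defined for regression models")
    return(stats::plogis(y))
  }
  switch(type,
         response = y,
         delta = y,
         forecast = clamp(data$reference_das28 + y, DAS28_MIN, DAS28_MAX))
}

#' @export
print.adaptivenet <- function(x, ...) {
  cat("AdaptiveNet", x$task, "model\n")
  d <- x$dims
  cat(sprintf("  encoders: visits %d->%d->%d, meds %d->%d->%d (second layer shared)\n",
              d[["Dv"]], d[["H1"]], d[["L"]], d[["Dm"]], d[["H1"]], d[["L"]]))
  cat(sprintf("  LSTM hidden: %d; head: [%d + %d general] -> %d -> 1\n",
              d[["H"]], d[["H"]], d[["G"]], d[["Hh"]]))
  cat(sprintf("  parameters: %d; trained %d epochs (best epoch %d)\n",
              length(x$params), nrow(x$loss_trace), x$best_epoch))
  invisible(x)
}

#' @export
summary.adaptivenet <- function(object, ...) {
  tr <- object$loss_trace
  out <- list(task = object$task, dims = object$dims,
              n_params = length(object$params),
              n_train = object$n_train, n_val = object$n_val,
              best_epoch = object$best_epoch,
              final_train_loss = tr$train_loss[nrow(tr)],
              best_val_loss = if (object$n_val > 0)
                min(tr$val_loss, na.rm = TRUE) else NA_real_)
  class(out) <- "summary.adaptivenet"
  out
}

#' @export
print.summary.adaptivenet <- function(x, ...) {
  cat("AdaptiveNet", x$task, "model —", x$n_params, "parameters\n")
  cat(sprintf("  train instances: %d; validation instances: %d\n",
              x$n_train, x$n_val))
  cat(sprintf("  final training loss: %.4f\n", x$final_train_loss))
  if (!is.na(x$best_val_loss))
    cat(sprintf("  best validation loss: %.4f (epoch %d)\n",
                x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
coef.adaptivenet <- function(object, ...) {
  anet_unflatten(object$params, object$dims)
}

#' @export
residuals.adaptivenet <- function(object, ...) object$residuals

#' @export
plot.adaptivenet <- function(x, ...) {
  tr <- x$loss_trace
  ylim <- range(c(tr$train_loss, tr$val_loss), na.rm = TRUE)
  graphics::plot(tr$epoch, tr$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", ylim = ylim, ...)
  if (any(!is.na(tr$val_loss))) {
    graphics::lines(tr$epoch, tr$val_loss, lty = 2)
    graphics::legend("topright", c("training", "validation"), lty = 1:2,
                     bty = "n")
  }
  graphics::abline(v = x$best_epoch, col = "grey", lty = 3)
  invisible(x)
}

## ---- reference (pure-R) forward path: the testable module surface ----

#' Encode an instance's events into the latent sequence
#'
#' Pure-R reference implementation of the encoder stage: each event is
#' mapped by its type's two-layer relu encoder (second layer shared) to the
#' latent space, in date-sorted order.  Independent of the C++ training
#' path; used as its oracle in the tests.
#'
#' @param object an `adaptivenet` fit (or a list with `params`, `dims`,
#'   `schema`, `scaling`).
#' @param instances an `anet_instances`.
#' @param i instance number.
#' @return Matrix `latent_dim x n_events` (0 columns for an empty history).
#' @export
encode_history <- function(object, instances, i = 1L) {
  data <- prepare_model_data(instances, object$schema, object$scaling,
                             if (is.null(object$task)) "regression"
                             else object$task)
  W <- anet_unflatten(object$params, object$dims)
  ev <- data$events
  relu <- function(x) pmax(x, 0)
  enc1 <- function(x, W1, b1) relu(W1 %*% x + as.numeric(b1))
  ev_i <- ev[[i]]
  k <- ncol(ev_i)
  out <- matrix(0, object$dims[["L"]], k)
  for (t in seq_len(k)) {
    if (ev_i["type", t] == 0L) {
      x <- data$xv[, ev_i["col", t] + 1L]
      h1 <- enc1(x, W$W1_visits, W$b1_visits)
    } else {
      x <- data$xm[, ev_i["col", t] + 1L]
      h1 <- enc1(x, W$W1_meds, W$b1_meds)
    }
    out[, t] <- relu(W$W2_shared %*% h1 + as.numeric(W$b2_shared))
  }
  out
}

#' Pool a latent event sequence into a fixed-length history encoding
#'
#' Pure-R reference LSTM: standard gate equations (input, forget, cell,
#' output; forget-gate ordering matches the trained parameter layout),
#' starting from the zero state; the final hidden state is the encoded
#' history.  An empty sequence returns the zero vector.
#'
#' @param latents matrix `latent_dim x n_events` (e.g. from
#'   [encode_history()]).
#' @param object an `adaptivenet` fit (or list with `params`, `dims`).
#' @return Numeric vector of length `lstm_hidden`.
#' @export
pool_history <- function(latents, object) {
  W <- anet_unflatten(object$params, object$dims)
  H <- object$dims[["H"]]
  sig <- function(x) 1 / (1 + exp(-x))
  h <- numeric(H); cc <- numeric(H)
  k <- ncol(latents)
  for (t in seq_len(k)) {
    a <- as.numeric(W$W_lstm_x %*% latents[, t] + W$W_lstm_h %*% h +
                      W$b_lstm)
    i <- sig(a[1:H]); f <- sig(a[(H + 1):(2 * H)])
    g <- tanh(a[(2 * H + 1):(3 * H)]); o <- sig(a[(3 * H + 1):(4 * H)])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  h
}

# full pure-R forward pass for one instance: oracle for the C++ path
anet_forward_R <- function(object, instances, i, data = NULL) {
  if (is.null(data))
    data <- prepare_model_data(instances, object$schema, object$scaling,
                               object$task %||% "regression")
  W <- anet_unflatten(object$params, object$dims)
  lat <- encode_history(object, instances, i)
  h <- pool_history(lat, object)
  z <- c(h, data$general[, i])
  u <- pmax(W$W_head %*% z + as.numeric(W$b_head), 0)
  as.numeric(W$W_out %*% u + as.numeric(W$b_out))
}
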
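make_small_problem <- function(n_patients = 15, seed = 41) {
  reg <- simulate_registry(sim_config(n_patients = n_patients, seed = seed))
  inst <- build_instances(reg)
  sc <- fit_scaling(reg)
  list(reg = reg, inst = inst, sc = sc,
       data = prepare_model_data(inst, default_schema(), sc, "regression"))
}

test_that("the compiled forward pass matches the pure-R reference network", {
  p <- make_small_problem()
  dims <- tiny_dims()
  params <- random_params(dims, seed = 2)
  fit <- fake_fit(params, dims, scaling = p$sc)
  n <- min(8, nrow(p$inst$index))
  y_cpp <- adaptivenet:::anet_pass(params, dims, p$data, seq_len(n), 0L,
                                   FALSE)$pred
  y_r <- vapply(seq_len(n),
                function(i) adaptivenet:::anet_forward_R(fit, p$inst, i,
                                                         p$data), 0)
  expect_equal(y_cpp, y_r, tolerance = 1e-12)
})

test_that("a single recurrent step reproduces the hand-computed gate equations", {
  # H = 2, L = 2, every weight written out; one latent event x = (1, -1)
  dims <- c(Dv = 21L, Dm = 18L, H1 = 2L, L = 2L, H = 2L, G = 10L, Hh = 2L)
  shapes <- adaptivenet:::anet_param_shapes(dims)
  plist <- lapply(shapes, function(s) matrix(0, s[1], s[2]))
  Wx <- rbind(c(0.5, 0.1), c(-0.2, 0.3),   # input gate rows
              c(0.1, 0.0), c(0.2, -0.1),   # forget gate rows
              c(0.3, 0.4), c(-0.5, 0.2),   # cell candidate rows
              c(0.0, 0.6), c(0.1, 0.1))    # output gate rows
  b <- c(0.05, -0.05, 1, 1, 0.2, -0.2, 0.1, 0)
  plist$W_lstm_x <- Wx
  plist$b_lstm <- matrix(b, 8, 1)
  params <- adaptivenet:::anet_flatten(plist)
  x <- c(1, -1)
  a <- as.numeric(Wx %*% x + b) # zero initial state: no recurrent term
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(a[1:2]); f <- sig(a[3:4]); g <- tanh(a[5:6]); o <- sig(a[7:8])
  h_hand <- o * tanh(i * g) # c_prev = 0
  obj <- list(params = params, dims = dims)
  expect_equal(pool_history(matrix(x, 2, 1), obj), h_hand,
               tolerance = 1e-12)
  # empty sequence pools to the zero initial state
  expect_equal(pool_history(matrix(0, 2, 0), obj), c(0, 0))
  # two steps differ from one: order/state sensitivity exists
  h2 <- pool_history(matrix(c(x, x), 2, 2), obj)
  expect_false(isTRUE(all.equal(h2, h_hand)))
})

test_that("analytic gradients match central finite differences", {
  p <- make_small_problem(8, seed = 43)
  dims <- c(Dv = 21L, Dm = 18L, H1 = 4L, L = 3L, H = 3L, G = 10L, Hh = 3L)
  params <- random_params(dims, seed = 5)
  # a toy instance set including a multi-event history
  lens <- vapply(p$data$events, ncol, 0L)
  idx <- order(-lens)[1:3]
  h <- 1e-5
  for (task in c(0L, 1L)) {
    g <- adaptivenet:::anet_pass(params, dims, p$data, idx, task, TRUE)$grad
    probe <- seq(1, length(params), length.out = 60)
    fd <- vapply(round(probe), function(j) {
      p1 <- params; p1[j] <- p1[j] + h
      p2 <- params; p2[j] <- p2[j] - h
      (adaptivenet:::anet_pass(p1, dims, p$data, idx, task, FALSE)$loss -
         adaptivenet:::anet_pass(p2, dims, p$data, idx, task, FALSE)$loss) /
        (2 * h)
    }, 0)
    rel <- abs(g[round(probe)] - fd) / pmax(abs(fd), abs(g[round(probe)]), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("a zero-weight classifier scores exactly one half", {
  p <- make_small_problem(6, seed = 47)
  dims <- tiny_dims()
  fit <- fake_fit(numeric(adaptivenet:::anet_n_params(dims)), dims,
                  scaling = p$sc, task = "classification")
  expect_equal(unique(predict(fit, p$inst)), 0.5)
})

test_that("predictions are invariant to the order events are supplied in", {
  p <- make_small_problem(10, seed = 53)
  dims <- tiny_dims()
  fit <- fake_fit(random_params(dims, 7), dims, scaling = p$sc)
  y1 <- predict(fit, p$inst)
  shuffled <- p$inst
  set.seed(3)
  shuffled$history <- lapply(shuffled$history, function(h)
    h[sample(nrow(h)), , drop = FALSE])
  expect_equal(predict(fit, shuffled), y1, tolerance = 1e-14)
})

test_that("events just outside the five-year window cannot move predictions", {
  # one instance: reference day 1700, so the window is (-126.25, 1700];
  # the medication at day -200 is outside, the one at day 1600 inside
  reg <- toy_registry(c(0, 1700, 1800), c(3, 4, 5), med_days = c(-200, 1600))
  reg_del <- reg
  reg_del$medications <- reg_del$medications[-1, ]
  inst <- build_instances(reg)
  inst_del <- build_instances(reg_del)
  # the out-of-window medication is absent from the history
  expect_equal(sum(vapply(inst$history, nrow, 0L)),
               sum(vapply(inst_del$history, nrow, 0L)))
  sc <- fit_scaling(reg)
  dims <- tiny_dims()
  fit <- fake_fit(random_params(dims, 11), dims, scaling = sc)
  # deleting the out-of-window event is bit-identical (including the
  # derived time-since-adjustment slot of the in-window medication)
  expect_identical(predict(fit, inst_del), predict(fit, inst))
})

test_that("the encoded history length is fixed for histories of length 0 to 100", {
  dims <- tiny_dims()
  obj <- list(params = random_params(dims, 13), dims = dims)
  set.seed(4)
  for (k in c(0:5, 20, 50, 100)) {
    h <- pool_history(matrix(rnorm(dims[["L"]] * k), dims[["L"]], k), obj)
    expect_length(h, dims[["H"]])
    expect_true(all(is.finite(h)))
  }
})

test_that("both encoders project through the one shared second layer", {
  p <- make_small_problem(8, seed = 59)
  dims <- tiny_dims()
  # gradient from any batch containing both event types must write the
  # shared block once, fed by both branches: zeroing W2 kills all latents
  plist <- adaptivenet:::anet_unflatten(random_params(dims, 17), dims)
  plist$W2_shared[] <- 0
  plist$b2_shared[] <- 0
  fit <- fake_fit(adaptivenet:::anet_flatten(plist), dims, scaling = p$sc)
  lat <- encode_history(fit, p$inst, 1)
  expect_true(all(lat == 0))
  # parameter layout has exactly one second-layer block
  expect_named(adaptivenet:::anet_param_shapes(dims),
               c("W1_visits", "b1_visits", "W1_meds", "b1_meds", "W2_shared",
                 "b2_shared", "W_lstm_x", "W_lstm_h", "b_lstm", "W_head",
                 "b_head", "W_out", "b_out"))
})

test_that("shared second-layer weights stay identical through training", {
  p <- make_small_problem(12, seed = 61)
  fit <- adaptivenet(p$inst, "regression",
                     anet_config(latent_dim = 6, encoder_hidden = 6,
                                 lstm_hidden = 6, head_hidden = 6,
                                 epochs = 3, val_fraction = 0, seed = 3),
                     scaling = p$sc)
  W <- coef(fit)
  # the latent space both encoders project into is one parameter block; its
  # gradient collected contributions from both event types during training
  expect_equal(dim(W$W2_shared), c(6, 6))
  expect_equal(length(fit$params),
               adaptivenet:::anet_n_params(fit$dims))
})

test_that("a single instance can be memorized to near-zero loss", {
  reg <- simulate_registry(sim_config(n_patients = 4, seed = 8))
  one <- subset_instances(build_instances(reg), 1)
  fit <- adaptivenet(one, "regression",
                     anet_config(latent_dim = 8, encoder_hidden = 8,
                                 lstm_hidden = 8, head_hidden = 8,
                                 epochs = 3000, val_fraction = 0, seed = 1))
  expect_lt(tail(fit$loss_trace$train_loss, 1), 1e-4)
})

test_that("training is deterministic given the seed", {
  p <- make_small_problem(10, seed = 67)
  cfg <- anet_config(latent_dim = 6, encoder_hidden = 6, lstm_hidden = 6,
                     head_hidden = 6, epochs = 2, seed = 5)
  f1 <- adaptivenet(p$inst, "classification", cfg, scaling = p$sc)
  f2 <- adaptivenet(p$inst, "classification", cfg, scaling = p$sc)
  expect_identical(f1$params, f2$params)
  expect_equal(predict(f1, p$inst), predict(f2, p$inst))
})

test_that("model methods print, summarize, plot and expose residuals", {
  p <- make_small_problem(10, seed = 71)
  fit <- adaptivenet(p$inst, "regression",
                     anet_config(latent_dim = 4, encoder_hidden = 4,
                                 lstm_hidden = 4, head_hidden = 4,
                                 epochs = 2, seed = 2), scaling = p$sc)
  expect_output(print(fit), "AdaptiveNet regression")
  expect_output(print(summary(fit)), "parameters")
  expect_length(residuals(fit), nrow(p$inst$index))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # forecast stays inside the instrument range
  fc <- predict(fit, p$inst, type = "forecast")
  expect_true(all(fc >= 0 & fc <= 9.4))
})
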
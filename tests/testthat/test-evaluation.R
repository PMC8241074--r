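test_that("confusion metrics match hand-enumerated cells", {
  m <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(1, 1, 1))
  # ties at the threshold count as positive calls
  m <- confusion_metrics(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  # at the default threshold 0.5, 0.9 and 0.8 are both positive calls
  m <- confusion_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(1, 1, 1, 1))
  expect_equal(m$accuracy, 0.5)
  # raising the threshold past 0.8 leaves a single (correct) positive call
  m <- confusion_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0),
                         threshold = 0.85)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(1, 1, 2, 0))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)
  expect_warning(m <- confusion_metrics(c(0.2, 0.8), c(0, 0)),
                 "no positive labels")
  expect_true(is.na(m$sensitivity))
})

test_that("confusion metrics agree with exhaustive enumeration on random inputs", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    s <- round(runif(n), 1)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    th <- runif(1)
    m <- confusion_metrics(s, l, th)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_len(n)) {
      if (s[i] >= th && l[i] == 1) tp <- tp + 1
      if (s[i] >= th && l[i] == 0) fp <- fp + 1
      if (s[i] < th && l[i] == 0) tn <- tn + 1
      if (s[i] < th && l[i] == 1) fn <- fn + 1
    }
    expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(tp, fp, tn, fn))
    expect_equal(m$accuracy, (tp + tn) / n)
  }
})

test_that("AUC equals the all-pairs rank statistic and handles examples", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7), c(1, 1, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_auc(c(0.3, 0.4), c(1, 1)),
               class = "anet_validation_error")
  # all-pairs brute force with tie credit, random cases
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    s <- round(runif(n), 1)
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    pairs <- 0; wins <- 0
    for (i in which(l == 1)) for (j in which(l == 0)) {
      pairs <- pairs + 1
      wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    expect_equal(roc_auc(s, l)$auc, wins / pairs, tolerance = 1e-12)
  }
})

test_that("the ROC curve is monotone with fixed endpoints and trapezoid area equal to the rank AUC", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    s <- round(runif(n), sample(1:3, 1))
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    r <- roc_auc(s, l)
    cv <- r$curve
    expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
    expect_equal(c(cv$fpr[nrow(cv)], cv$tpr[nrow(cv)]), c(1, 1))
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    expect_equal(adaptivenet:::auc_trapezoid(s, l), r$auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- runif(300)
  l <- rbinom(300, 1, plogis(3 * s - 1.5))
  expect_equal(roc_auc(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("label-independent scores give a null AUC near one half", {
  set.seed(17)
  s <- runif(10000)
  l <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(s, l)$auc - 0.5), 0.02)
})

test_that("MSE matches hand arithmetic and the variance identity", {
  expect_equal(mse_das28(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_das28(c(1, 2), c(2, 4)), 2.5)
  set.seed(19)
  y <- rnorm(500, 3, 1)
  expect_equal(mse_das28(rep(mean(y), 500), y),
               stats::var(y) * 499 / 500, tolerance = 1e-12)
  expect_error(mse_das28(numeric(0), numeric(0)))
})

test_that("Welch's test matches the closed form and its conventions", {
  a <- c(0.7, 0.72, 0.71, 0.73, 0.69)
  b <- c(0.6, 0.62, 0.61, 0.63, 0.59)
  w <- welch_t_test(a, b)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  expect_true(w$significant)
  # identical groups: t = 0, p = 1 (zero-variance convention)
  w0 <- welch_t_test(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(c(w0$t, w0$p), c(0, 1))
  expect_equal(welch_t_test(c(0.4, 0.4), c(0.6, 0.6))$p, 0)
  # symmetry under group swap
  ws <- welch_t_test(b, a)
  expect_equal(ws$t, -w$t)
  expect_equal(ws$p, w$p)
  # doubling each group's distance from the common mean (spread unchanged)
  # increases |t|
  m <- mean(c(a, b))
  w2 <- welch_t_test(a + (mean(a) - m), b + (mean(b) - m))
  expect_gt(abs(w2$t), abs(w$t))
})

test_that("Welch's test matches t.test on random inputs", {
  set.seed(23)
  for (rep in 1:20) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), 0.3)
    w <- welch_t_test(a, b)
    tt <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("forest importances are normalized and ignore constant features", {
  set.seed(29)
  x <- cbind(signal = runif(300), flat = rep(1, 300), noise = runif(300))
  y <- 2 * x[, "signal"] + rnorm(300, 0, 0.1)
  imp <- feature_importance(x, y, "regression", seed = 1)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "signal")
  expect_equal(imp$importance[imp$feature == "flat"], 0)
})

test_that("subgroup evaluation recombines to the overall metrics", {
  reg <- simulate_registry(sim_config(n_patients = 120, seed = 43))
  cv <- cross_validate(reg, "classification", models = "random_forest",
                       k = 4, seed = 2)
  suppressWarnings(sg <- evaluate_subgroups(cv, model = "random_forest",
                                            criteria = c("female", "male")))
  tab <- sg$table
  # the 'all' row equals the plain cross-validated summary
  s <- summary(cv)
  expect_equal(tab$auc_mean[tab$subgroup == "all"], s$auc_mean,
               tolerance = 1e-12)
  # complementary subgroup instance counts recombine (gender never missing)
  expect_equal(tab$n[tab$subgroup == "female"] + tab$n[tab$subgroup == "male"],
               tab$n[tab$subgroup == "all"])
  expect_true(all(c("group_a", "p") %in% names(sg$tests)))
})

test_that("a subgroup with boosted signal-to-noise scores a higher AUC", {
  # construct: females get a strong planted signal, males none
  miss <- miss_zero()
  cfg <- sim_config(n_patients = 300, noise_sd = 0.25, baseline_das_mean = 2.6,
                    baseline_das_sd = 0, flare_prob = 0, treatment_effect = 0,
                    missingness_rates = miss, seed = 47)
  reg <- simulate_registry(cfg)
  regf <- plant_signal(reg, "haq", weight = 1.2, center = TRUE)
  males <- reg$patients$patient_id[reg$patients$gender == "male"]
  keep <- regf$visits$patient_id %in% males
  regf$visits$das28_bsr[keep] <- reg$visits$das28_bsr[keep]
  cv <- cross_validate(regf, "classification", models = "random_forest",
                       k = 5, seed = 3)
  suppressWarnings(sg <- evaluate_subgroups(cv, model = "random_forest",
                                            criteria = c("female", "male")))
  tab <- sg$table
  expect_gt(tab$auc_mean[tab$subgroup == "female"],
            tab$auc_mean[tab$subgroup == "male"])
})
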
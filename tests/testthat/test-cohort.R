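test_that("active-disease labelling follows the 2.6 threshold convention", {
  expect_equal(label_active(c(2.61, 2.6, 0, 9.4)), c(1L, 0L, 0L, 1L))
})

test_that("pairing follows the 1-12 month gap rule on the next eligible visit", {
  # two visits half a month apart: gap too short, no instance
  expect_equal(nrow(build_instances(
    toy_registry(c(0, 15), c(3, 4)))$index), 0)
  # months {0, 6, 20}: one instance (0 -> 6); 6 -> 20 exceeds 12 months
  inst <- build_instances(toy_registry(c(0, 183, 609), c(3, 4, 5)))
  expect_equal(nrow(inst$index), 1)
  expect_equal(inst$index$delta_das28, 1)
  expect_equal(as.numeric(inst$index$gap_days), 183)
  # a single visit yields nothing
  expect_equal(nrow(build_instances(toy_registry(0, 3))$index), 0)
})

test_that("gap boundaries are inclusive in days ([30.44, 365.25])", {
  expect_equal(nrow(build_instances(toy_registry(c(0, 31), c(3, 4)))$index), 1)
  expect_equal(nrow(build_instances(toy_registry(c(0, 30), c(3, 4)))$index), 0)
  expect_equal(nrow(build_instances(toy_registry(c(0, 365), c(3, 4)))$index), 1)
  expect_equal(nrow(build_instances(toy_registry(c(0, 366), c(3, 4)))$index), 0)
})

test_that("visits without a DAS28 score never anchor an instance", {
  # middle visit lacks the score: it is skipped as reference AND as target,
  # and the 0 -> 300 day pair is itself out of the 1-12 month rule? no: 300
  # days is eligible, so exactly one instance spanning the scoreless visit
  inst <- build_instances(toy_registry(c(0, 100, 300), c(3, NA, 5)))
  expect_equal(nrow(inst$index), 1)
  expect_equal(inst$index$target_das28, 5)
  # but the scoreless visit still appears in the history events
  h <- inst$history[[1]]
  expect_equal(sum(h$type == "visit"), 1) # only events up to the reference
})

test_that("instance counts match the brute-force pairing oracle", {
  for (s in 1:5) {
    reg <- simulate_registry(sim_config(n_patients = 30, seed = 100 + s))
    expect_equal(nrow(build_instances(reg)$index), brute_force_pairs(reg))
  }
})

test_that("histories hold exactly the 5-year window, medications before same-day visits", {
  reg <- toy_registry(c(0, 400, 2400, 2600), c(2, 3, 4, 5),
                      med_days = c(400, 2400, 2550))
  inst <- build_instances(reg)
  # reference 2400: visit at day 400 is ~5.5 years earlier -> excluded
  ref <- which(inst$index$reference_date == reg$visits$date[3])
  h <- inst$history[[ref]]
  expect_false(as.Date("2015-01-01") %in% h$date)       # day-0 visit out
  expect_false((as.Date("2015-01-01") + 400) %in% h$date[h$type == "visit"])
  # same-day medication (day 2400) sorts before the visit
  sameday <- h[h$date == as.Date("2015-01-01") + 2400, ]
  expect_equal(sameday$type, c("medication", "visit"))
})

test_that("deleting events older than five years leaves instances intact", {
  reg <- toy_registry(c(0, 2400, 2600), c(2, 4, 5), med_days = c(5, 2500))
  reg2 <- reg
  reg2$visits <- reg2$visits[-1, ]       # visit ~6.6 years before reference
  reg2$medications <- reg2$medications[-1, ]
  i1 <- build_instances(reg)
  i2 <- build_instances(reg2)
  expect_equal(nrow(i1$index), nrow(i2$index))
  expect_equal(i1$index$delta_das28, i2$index$delta_das28)
  h1 <- i1$history[[nrow(i1$index)]]
  h2 <- i2$history[[nrow(i2$index)]]
  expect_equal(h1[, c("type", "date")], h2[, c("type", "date")])
})

test_that("folds partition patients with balanced instance counts", {
  regs <- lapply(1:10, function(i)
    toy_registry(c(0, 100), c(3, 4), patient_id = sprintf("P%03d", i)))
  inst <- build_instances(do.call(bind_registries, regs))
  folds <- assign_folds(inst, k = 5, seed = 1)
  expect_equal(as.integer(table(folds$patients$fold)), rep(2L, 5))
  # determinism and partition
  expect_identical(assign_folds(inst, k = 5, seed = 1), folds)
  for (f1 in 1:4) for (f2 in (f1 + 1):5) {
    a <- folds$patients$patient_id[folds$patients$fold == f1]
    b <- folds$patients$patient_id[folds$patients$fold == f2]
    expect_length(intersect(a, b), 0)
  }
  expect_error(assign_folds(inst, k = 50, seed = 1),
               class = "anet_validation_error")
})

test_that("fold test shares stay near 20% on realistic registries", {
  reg <- simulate_registry(sim_config(n_patients = 200, seed = 23))
  inst <- build_instances(reg)
  folds <- assign_folds(inst, k = 5, seed = 4)
  shares <- table(folds$instance_fold) / nrow(inst$index)
  expect_true(all(abs(shares - 0.2) <= 0.02))
})

test_that("subgroup criteria use the stated boundary conventions", {
  reg <- bind_registries(
    toy_registry(c(0, 100), c(3, 4), patient_id = "A001", age = 50),
    toy_registry(c(0, 100), c(3, 4), patient_id = "B001", age = 49))
  inst <- build_instances(reg)
  expect_equal(subgroup_filter(inst, "age_ge_50"), c(TRUE, FALSE))
  expect_equal(subgroup_filter(inst, "age_lt_50"), c(FALSE, TRUE))
  expect_error(subgroup_filter(inst, "bmi_high"),
               class = "anet_validation_error")
})

test_that("complementary subgroups partition the non-missing stratifier", {
  reg <- simulate_registry(sim_config(n_patients = 80, seed = 29))
  inst <- build_instances(reg)
  pts <- reg$patients
  i <- match(inst$index$patient_id, pts$patient_id)
  pos <- subgroup_filter(inst, "rf_positive")
  suppressWarnings(neg <- subgroup_filter(inst, "rf_negative"))
  expect_false(any(pos & neg))
  expect_equal(sum(pos | neg), sum(!is.na(pts$rf_status[i])))
  # a criterion with no members warns
  all_pos <- reg
  all_pos$patients$rf_status <- "positive"
  inst2 <- build_instances(all_pos)
  expect_warning(subgroup_filter(inst2, "rf_negative"), "no instances")
})

test_that("the flat view exposes last visit, last medication and recency", {
  reg <- toy_registry(c(0, 100, 200), c(3, 3.5, 4), med_days = c(50, 120))
  sc <- fit_scaling(reg)
  fl <- flatten_instances(build_instances(reg), scaling = sc)
  expect_equal(nrow(fl$x), 2)
  expect_equal(ncol(fl$x), 10 + 21 + 18 + 1)
  # instance with reference at day 100: last medication was day 50
  expect_equal(unname(fl$x[2, "months_since_last_adjustment"]),
               ((100 - 50) / 30.44) / 60, tolerance = 1e-12)
  expect_equal(fl$delta, c(0.5, 0.5))
  expect_equal(fl$label, c(1L, 1L))
})
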
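test_that("identical config and seed give byte-identical registries", {
  cfg <- sim_config(n_patients = 40, seed = 7)
  r1 <- simulate_registry(cfg)
  r2 <- simulate_registry(cfg)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$visits, r2$visits)
  expect_identical(r1$medications, r2$medications)
})

test_that("noiseless zero-AR trajectories are constant at the patient baseline", {
  reg <- simulate_registry(det_config(n_patients = 3, seed = 2))
  for (pid in reg$patients$patient_id) {
    das <- reg$visits$das28_bsr[reg$visits$patient_id == pid]
    expect_true(length(unique(das)) == 1)
  }
  # and with noise back on, flares/noise vary the trajectory
  regn <- simulate_registry(sim_config(n_patients = 3, noise_sd = 0.5,
                                       missingness_rates = miss_zero(),
                                       seed = 2))
  das <- regn$visits$das28_bsr[regn$visits$patient_id ==
                                 regn$patients$patient_id[1]]
  expect_gt(length(unique(das)), 1)
})

test_that("generated registries satisfy structural invariants", {
  reg <- simulate_registry(sim_config(n_patients = 60, seed = 5))
  expect_setequal(unique(reg$visits$patient_id), reg$patients$patient_id)
  for (pid in reg$patients$patient_id) {
    d <- reg$visits$date[reg$visits$patient_id == pid]
    expect_gte(length(d), 1)
    if (length(d) > 1) expect_true(all(diff(as.numeric(d)) > 0))
  }
  das <- reg$visits$das28_bsr
  expect_true(all(is.na(das) | (das >= 0 & das <= 9.4)))
  # visit features carry the configured missingness pattern (some NA)
  expect_gt(mean(is.na(reg$visits$smoker)), 0.4)
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_registry(sim_config(n_patients = 0)),
               class = "anet_config_error")
  expect_error(sim_validate <- simulate_registry(
    sim_config(n_patients = 5, missingness_rates = list(haq = 1.5))),
    class = "anet_config_error")
  expect_error(simulate_registry(sim_config(n_patients = 5,
                                            ar_coefficient = 1)),
               class = "anet_config_error")
  expect_error(simulate_registry(sim_config(n_patients = 5,
                                            treatment_effect = 0.2)),
               class = "anet_config_error")
})

test_that("realized missingness tracks the configured rates", {
  reg <- simulate_registry(sim_config(n_patients = 1600, seed = 31))
  n_cells <- nrow(reg$visits)
  expect_gt(n_cells, 8000)
  rates <- default_missingness()
  for (f in c("das28_bsr", "haq", "weight")) {
    expect_lt(abs(mean(is.na(reg$visits[[f]])) - rates[[f]]), 0.03)
  }
})

test_that("plant_signal with weight 0 leaves targets unchanged", {
  reg <- simulate_registry(det_config(n_patients = 4, seed = 3))
  expect_identical(plant_signal(reg, "pain", 0)$visits, reg$visits)
})

test_that("noiseless planted signal makes the score change exactly the feature", {
  cfg <- det_config(n_patients = 6, seed = 9, baseline_das_mean = 1,
                    baseline_das_sd = 0)
  reg <- plant_signal(simulate_registry(cfg), "pain", weight = 0.1)
  inst <- build_instances(reg)
  expect_gt(nrow(inst$index), 0)
  # reference-visit pain drives the delta exactly (weight 0.1, no noise)
  pain_ref <- vapply(seq_len(nrow(inst$index)), function(i) {
    h <- inst$history[[i]]
    vr <- h$row[h$type == "visit"]
    reg$visits$pain[vr[length(vr)]]
  }, 0)
  expect_equal(inst$index$delta_das28, 0.1 * pain_ref, tolerance = 1e-12)
})

test_that("plant_signal validates the feature name and records metadata", {
  reg <- simulate_registry(det_config(n_patients = 2, seed = 4))
  expect_error(plant_signal(reg, "no_such_feature", 1),
               class = "anet_schema_error")
  pl <- attr(plant_signal(reg, "haq", 0.5, lag = 2, center = TRUE),
             "planted")
  expect_equal(pl$feature, "haq")
  expect_equal(pl$lag, 2L)
  expect_true(pl$center)
})
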
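# Shared fixtures, all built in code.

# zero-missingness rate list (clean targets/features for oracle tests)
miss_zero <- function() {
  as.list(stats::setNames(rep(0, length(default_missingness())),
                          names(default_missingness())))
}

# a noiseless, treatment-free generator config (deterministic AR)
det_config <- function(n_patients = 5, seed = 1, baseline_das_sd = 0.8, ...) {
  sim_config(n_patients = n_patients, noise_sd = 0, ar_coefficient = 0,
             treatment_effect = 0, baseline_das_sd = baseline_das_sd,
             missingness_rates = miss_zero(), seed = seed, ...)
}

# hand-built toy registry: visits at given day offsets with given DAS28
# values (NA allowed), optional medication day offsets
toy_registry <- function(visit_days, das28, med_days = integer(0),
                         patient_id = "T001", age = 55,
                         origin = as.Date("2015-01-01")) {
  stopifnot(length(visit_days) == length(das28))
  k <- length(visit_days)
  patients <- data.frame(
    patient_id = patient_id, enrolment_date = origin, age = age,
    gender = "female", rf_status = "positive", anti_ccp = "negative",
    disease_duration = 5, minimal_disease_activity = 1.2,
    stringsAsFactors = FALSE)
  visits <- data.frame(
    patient_id = rep(patient_id, k), date = origin + visit_days,
    das28_bsr = das28, bsr = rep(15, k), swollen_count = rep(2L, k),
    painful_count = rep(3L, k), pain = rep(3.5, k), radai = rep(3, k),
    haq = rep(0.9, k), weight = rep(70, k), height = rep(165, k),
    morning_stiffness = rep("none", k), smoker = rep("never", k),
    crp = rep(8, k), euroqol = rep(0.7, k), stringsAsFactors = FALSE)
  m <- length(med_days)
  medications <- data.frame(
    patient_id = rep(patient_id, m), date = origin + med_days,
    drug = rep("methotrexate", m), drug_type = rep("csDMARD", m),
    prednisone_dose_stratum = rep("none", m), stringsAsFactors = FALSE)
  structure(list(patients = patients, visits = visits,
                 medications = medications), class = "ra_registry")
}

# merge several single-patient toy registries
bind_registries <- function(...) {
  regs <- list(...)
  structure(list(patients = do.call(rbind, lapply(regs, `[[`, "patients")),
                 visits = do.call(rbind, lapply(regs, `[[`, "visits")),
                 medications = do.call(rbind, lapply(regs, `[[`, "medications"))),
            class = "ra_registry")
}

# brute-force pairing oracle: consecutive DAS28-complete visit pairs with
# the gap rule (independent of build_instances internals)
brute_force_pairs <- function(registry) {
  out <- 0L
  for (pid in registry$patients$patient_id) {
    v <- registry$visits[registry$visits$patient_id == pid, ]
    v <- v[order(v$date), ]
    v <- v[!is.na(v$das28_bsr), ]
    if (nrow(v) < 2) next
    for (j in seq_len(nrow(v) - 1)) {
      gap <- as.numeric(v$date[j + 1] - v$date[j])
      if (gap >= 30.44 && gap <= 365.25) out <- out + 1L
    }
  }
  out
}

# small random network pieces for forward-pass oracles
tiny_dims <- function(G = 10L) {
  c(Dv = 21L, Dm = 18L, H1 = 5L, L = 4L, H = 3L, G = G, Hh = 4L)
}

random_params <- function(dims, seed = 1, sd = 0.3) {
  set.seed(seed)
  stats::rnorm(adaptivenet:::anet_n_params(dims), 0, sd)
}

# minimal fit-like object for the pure-R forward helpers
fake_fit <- function(params, dims, schema = default_schema(), scaling,
                     task = "regression") {
  structure(list(params = params, dims = dims, schema = schema,
                 scaling = scaling, task = task,
                 schema_hash = schema_hash(schema)),
            class = "adaptivenet")
}
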
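#' Simulation configuration for a synthetic RA registry
#'
#' Defaults are calibrated to the printed cohort statistics of a national RA
#' registry: patients have on average 6.3 (SD 5.3) visits and 2.5 (SD 2.7)
#' medication adjustments over a maximal 5-year observation window, with a
#' mean inter-visit interval of 8.1 (SD 2.9) months; per-feature missingness
#' and categorical level frequencies follow the published cohort table.
#'
#' The disease-activity process is a latent AR(1) per patient:
#' `a_t = mu_i + phi * (a_{t-1} - mu_i) + tau * treated_t + flare_t + eps_t`,
#' with `eps_t ~ N(0, noise_sd)`, `tau = treatment_effect` applied when a
#' DMARD/biologic adjustment occurred since the previous visit, and rare
#' positive flare spikes that are part of the stochastic innovation (flares
#' are only drawn when `noise_sd > 0`, so a noiseless configuration is a
#' deterministic AR(1)).  The observed DAS28-BSR is the latent activity
#' clamped to the instrument range `[0, 9.4]`.
#'
#' @param n_patients number of patients.
#' @param years_followup maximal observation span in years.
#' @param mean_visits,sd_visits marginal visit-count moments; counts are
#'   drawn as `1 + NegBinomial` matched to these moments so every patient has
#'   at least one visit while preserving the configured mean.
#' @param mean_med_adjustments,sd_med_adjustments medication-event count
#'   moments (negative binomial, may be zero).
#' @param mean_visit_interval_months,sd_visit_interval_months inter-visit gap
#'   moments; 90% of gaps are drawn from this normal truncated to
#'   `[1, 12]` months and 10% from its complement tails, so downstream
#'   pairing rules see both eligible and ineligible gaps.
#' @param out_of_window_gap_rate fraction of gaps drawn outside `[1, 12]`
#'   months.
#' @param ar_coefficient AR(1) coefficient `phi` in `[0, 1)`.
#' @param noise_sd innovation SD of the activity process.
#' @param treatment_effect additive activity shift (must be `<= 0`) applied
#'   at visits preceded by a DMARD/biologic adjustment.
#' @param baseline_das_mean,baseline_das_sd distribution of the per-patient
#'   long-run activity level `mu_i`.
#' @param flare_prob per-visit probability of a flare spike.
#' @param flare_magnitude mean size of a flare spike (DAS28 units).
#' @param interval_coupling optional coupling in `[0, 1]` between baseline
#'   severity and visit frequency (0 = independent, the default; positive
#'   values shorten intervals for sicker patients).
#' @param missingness_rates named list/vector of per-feature missingness
#'   probabilities in `[0, 1]`; defaults follow the cohort table.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return A list of class `anet_sim_config`.
#' @export
sim_config <- function(n_patients = 100,
                       years_followup = 5,
                       mean_visits = 6.3,
                       sd_visits = 5.3,
                       mean_med_adjustments = 2.5,
                       sd_med_adjustments = 2.7,
                       mean_visit_interval_months = 8.1,
                       sd_visit_interval_months = 2.9,
                       out_of_window_gap_rate = 0.1,
                       ar_coefficient = 0.7,
                       noise_sd = 0.5,
                       treatment_effect = -0.3,
                       baseline_das_mean = 3.3,
                       baseline_das_sd = 1.2,
                       flare_prob = 0.05,
                       flare_magnitude = 1.5,
                       interval_coupling = 0,
                       missingness_rates = default_missingness(),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$missingness_rates <- as.list(missingness_rates)
  structure(cfg, class = "anet_sim_config")
}

#' @rdname sim_config
#' @export
default_missingness <- function() {
  list(age = 0, minimal_disease_activity = 0.016, disease_duration = 0.027,
       gender = 0, rf_status = 0.091, anti_ccp = 0.316,
       swollen_count = 0.066, painful_count = 0.069, bsr = 0.146,
       das28_bsr = 0.164, pain = 0.224, radai = 0.227, haq = 0.278,
       weight = 0.365, height = 0.408, morning_stiffness = 0.227,
       smoker = 0.602, crp = 0.146, euroqol = 0.30,
       drug = 0, drug_type = 0, prednisone_dose_stratum = 0)
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1)
    stop_anet("n_patients must be a positive integer", class = "anet_config_error")
  rates <- c(unlist(cfg$missingness_rates), cfg$out_of_window_gap_rate,
             cfg$flare_prob, cfg$interval_coupling)
  if (any(rates < 0 | rates > 1))
    stop_anet("rates/probabilities must lie in [0, 1]", class = "anet_config_error")
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1)
    stop_anet("ar_coefficient must lie in [0, 1)", class = "anet_config_error")
  sds <- c(cfg$sd_visits, cfg$sd_med_adjustments, cfg$sd_visit_interval_months,
           cfg$noise_sd, cfg$baseline_das_sd)
  if (any(sds < 0))
    stop_anet("standard deviations must be >= 0", class = "anet_config_error")
  if (cfg$treatment_effect > 0)
    stop_anet("treatment_effect must be <= 0", class = "anet_config_error")
  invisible(cfg)
}

# Categorical level frequencies from the cohort table (conditional on being
# observed; missingness is applied separately).
sim_categorical_probs <- function() {
  norm <- function(x) x / sum(x)
  list(
    gender = c(female = 0.74, male = 0.26),
    rf_status = norm(c(positive = 62.9, negative = 28.0)),
    anti_ccp = norm(c(positive = 42.4, negative = 26.0)),
    morning_stiffness = norm(c(none = 36.8, lt_half_hour = 15.4,
                               half_to_one_hour = 12.0, gt_four_hours = 1.6,
                               twelve_hours = 6.1, twenty_four_hours = 3.5,
                               all_day = 1.9)),
    smoker = norm(c(never = 18.2, current = 9.3, former = 12.3)),
    drug = norm(c(methotrexate = 24.1, prednisone = 16.8, adalimumab = 7.9,
                  etanercept = 7.3, tocilizumab = 4.0, abatacept = 4.0,
                  rituximab = 3.5, golimumab = 2.4, other = 30.1)),
    prednisone_dose_stratum = norm(c(none = 41.3, lt10 = 9.6,
                                     `10to15` = 12.6, gt15 = 36.5))
  )
}

drug_type_map <- c(methotrexate = "csDMARD", prednisone = "prednisone",
                   adalimumab = "biologic", etanercept = "biologic",
                   tocilizumab = "biologic", abatacept = "biologic",
                   rituximab = "biologic", golimumab = "biologic",
                   other = "other")

# 1 + negative binomial matched to (mean, sd); falls back to a shifted
# Poisson when the target variance is not overdispersed.
rcount_shifted <- function(n, mean, sd) {
  m <- mean - 1
  v <- sd^2
  if (m <= 0) return(rep(1L, n))
  if (v > m + 1e-8) {
    size <- m^2 / (v - m)
    1L + stats::rnbinom(n, mu = m, size = size)
  } else {
    1L + stats::rpois(n, m)
  }
}

rcount_nb <- function(n, mean, sd) {
  v <- sd^2
  if (mean <= 0) return(rep(0L, n))
  if (v > mean + 1e-8) {
    stats::rnbinom(n, mu = mean, size = mean^2 / (v - mean))
  } else {
    stats::rpois(n, mean)
  }
}

# Truncated-normal sampling by inverse CDF.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

sample_gap_months <- function(n, cfg) {
  m <- cfg$mean_visit_interval_months
  s <- cfg$sd_visit_interval_months
  out <- rtruncnorm(n, m, s, 1, 12)
  oow <- stats::runif(n) < cfg$out_of_window_gap_rate
  n_oow <- sum(oow)
  if (n_oow > 0) {
    # complement tails of the same normal: below 1 month (floored at 0.25)
    # or above 12 months (capped at 24), in their natural proportion
    w_lo <- stats::pnorm(1, m, s) - stats::pnorm(0.25, m, s)
    w_hi <- stats::pnorm(24, m, s) - stats::pnorm(12, m, s)
    lo <- stats::runif(n_oow) < w_lo / (w_lo + w_hi)
    tail_draw <- ifelse(lo,
                        rtruncnorm(n_oow, m, s, 0.25, 1),
                        rtruncnorm(n_oow, m, s, 12, 24))
    out[oow] <- tail_draw
  }
  out
}

#' Simulate a synthetic RA registry
#'
#' Generates the three relational tables (patients, visits, medication
#' events) with the feature schema, missingness pattern and marginal
#' statistics described in [sim_config()].  Output is byte-identical for
#' identical config + seed.
#'
#' @param config an [sim_config()] object.
#' @return An object of class `ra_registry`: a list with data frames
#'   `patients`, `visits`, `medications`, carrying the generating config and
#'   latent trajectories as attributes (used by [plant_signal()]).
#' @export
simulate_registry <- function(config = sim_config()) {
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(config$seed, "registry"))

  n <- as.integer(config$n_patients)
  probs <- sim_categorical_probs()
  miss <- config$missingness_rates
  mrate <- function(f) miss[[f]] %||% 0

  rcat <- function(m, p) sample(names(p), m, replace = TRUE, prob = p)
  apply_missing <- function(x, f) {
    r <- mrate(f)
    if (r > 0) x[stats::runif(length(x)) < r] <- NA
    x
  }

  ## ---- patients ----
  pid <- sprintf("P%05d", seq_len(n))
  age <- round(clamp(stats::rnorm(n, 58.8, 13.0), 18, 95), 1)
  mda <- round(clamp(stats::rnorm(n, 1.3, 1.1), 0, 10), 2)
  duration <- round(clamp(stats::rnorm(n, 12.2, 9.5), 0, 60), 2)
  gender <- rcat(n, probs$gender)
  rf <- rcat(n, probs$rf_status)
  accp <- rcat(n, probs$anti_ccp)
  start <- as.Date("2012-01-01") + floor(stats::runif(n, 0, 365))
  patients <- data.frame(
    patient_id = pid,
    enrolment_date = start,
    age = apply_missing(age, "age"),
    gender = apply_missing(gender, "gender"),
    rf_status = apply_missing(rf, "rf_status"),
    anti_ccp = apply_missing(accp, "anti_ccp"),
    disease_duration = apply_missing(duration, "disease_duration"),
    minimal_disease_activity = apply_missing(mda, "minimal_disease_activity"),
    stringsAsFactors = FALSE)

  mu <- clamp(stats::rnorm(n, config$baseline_das_mean, config$baseline_das_sd),
              0.5, 8)
  n_visits <- rcount_shifted(n, config$mean_visits, config$sd_visits)
  n_meds <- rcount_nb(n, config$mean_med_adjustments, config$sd_med_adjustments)

  phi <- config$ar_coefficient
  tau <- config$treatment_effect
  sdn <- config$noise_sd

  vis_list <- vector("list", n)
  med_list <- vector("list", n)
  latent <- vector("list", n)

  for (i in seq_len(n)) {
    k <- n_visits[i]
    gaps <- sample_gap_months(max(k - 1, 0), config)
    if (config$interval_coupling > 0) {
      # sicker patients (higher mu) visit more often: shrink gaps smoothly
      shrink <- 1 - config$interval_coupling * 0.5 *
        clamp((mu[i] - config$baseline_das_mean) / 3, -1, 1)
      gaps <- gaps * shrink
    }
    # note: the 5-year history window is a cohort-builder rule, not a cap on
    # follow-up; visits beyond years_followup are kept so the configured
    # visit-count and interval marginals are preserved exactly
    offs <- cumsum(c(0, round(gaps * DAYS_PER_MONTH)))
    dates <- start[i] + offs

    ## medication events: uniform over the observed span, at most one
    ## adjustment event per day (the registry key is patient + date)
    m <- n_meds[i]
    span <- max(offs[k], m, 1)
    med_dates <- start[i] + sort(sample.int(span + 1L, m) - 1L)
    med_drug <- rcat(m, probs$drug)
    meds <- data.frame(
      patient_id = rep(pid[i], m),
      date = med_dates,
      drug = med_drug,
      drug_type = unname(drug_type_map[med_drug]),
      prednisone_dose_stratum = rcat(m, probs$prednisone_dose_stratum),
      stringsAsFactors = FALSE)

    ## latent activity
    treated <- logical(k)
    if (m > 0 && k > 1) {
      for (t in 2:k) {
        treated[t] <- any(med_dates > dates[t - 1] & med_dates <= dates[t] &
                            drug_type_map[med_drug] %in% c("csDMARD", "biologic"))
      }
    }
    eps <- stats::rnorm(k, 0, sdn)
    flare <- if (sdn > 0 && config$flare_prob > 0) {
      (stats::runif(k) < config$flare_prob) *
        abs(stats::rnorm(k, config$flare_magnitude, config$flare_magnitude / 3))
    } else numeric(k)
    a <- numeric(k)
    a[1] <- mu[i] + if (phi < 1) eps[1] / sqrt(1 - phi^2) else eps[1]
    if (k > 1) {
      for (t in 2:k) {
        a[t] <- mu[i] + phi * (a[t - 1] - mu[i]) + tau * treated[t] +
          flare[t] + eps[t]
      }
    }
    das_true <- round(clamp(a, DAS28_MIN, DAS28_MAX), 2)

    vis <- data.frame(
      patient_id = rep(pid[i], k),
      date = dates,
      das28_bsr = das_true,
      bsr = round(clamp(stats::rnorm(k, 18.5, 17.1), 0, 140), 1),
      swollen_count = pmin(pmax(round(stats::rnorm(k, 3.3, 4.6)), 0), 28),
      painful_count = pmin(pmax(round(stats::rnorm(k, 3.5, 5.3)), 0), 28),
      pain = round(clamp(0.6 * a + stats::rnorm(k, 1.3, 2.2), 0, 10), 1),
      radai = round(clamp(0.6 * a + stats::rnorm(k, 1.4, 2.2), 0, 10), 1),
      haq = round(clamp(stats::rnorm(k, 0.8, 0.7), 0, 3), 2),
      weight = round(clamp(stats::rnorm(k, 70.7, 15.6), 35, 160), 1),
      height = round(clamp(stats::rnorm(k, 165.3, 12.2), 130, 210), 1),
      morning_stiffness = rcat(k, probs$morning_stiffness),
      smoker = rcat(k, probs$smoker),
      crp = round(clamp(stats::rnorm(k, 10, 15), 0, 200), 1),
      euroqol = round(clamp(stats::rnorm(k, 0.7, 0.2), 0, 1), 2),
      stringsAsFactors = FALSE)
    for (f in c("das28_bsr", "bsr", "swollen_count", "painful_count", "pain",
                "radai", "haq", "weight", "height", "morning_stiffness",
                "smoker", "crp", "euroqol")) {
      vis[[f]] <- apply_missing(vis[[f]], f)
    }
    vis_list[[i]] <- vis
    med_list[[i]] <- meds
    latent[[i]] <- list(patient_id = pid[i], mu = mu[i], activity = a,
                        das_true = das_true, flare = flare > 0,
                        treated = treated)
  }

  registry <- structure(
    list(patients = patients,
         visits = do.call(rbind, vis_list),
         medications = do.call(rbind, med_list)),
    class = "ra_registry")
  rownames(registry$visits) <- NULL
  rownames(registry$medications) <- NULL
  attr(registry, "config") <- config
  attr(registry, "latent") <- latent
  registry
}

#' Plant a linear signal into the next-visit DAS28-BSR target
#'
#' Rewrites each patient's DAS28-BSR trajectory so that the change between
#' consecutive visits gains an additive term `weight * x`, where `x` is the
#' chosen visit feature observed `lag` visits before the reference visit
#' (terms with no such visit contribute 0).  With `center = TRUE` the
#' feature's registry-wide mean is subtracted first, which keeps the
#' trajectory mean-stationary and the generator's irreducible next-visit
#' error exactly `noise_sd^2`.  The planted ground truth is recorded in the
#' `planted` attribute.  Values are re-clamped to the instrument range.
#'
#' @param registry an `ra_registry` from [simulate_registry()].
#' @param feature name of a visit feature (e.g. `"pain"`, `"haq"`).
#' @param weight signal weight (0 leaves the registry unchanged).
#' @param lag how many visits before the reference visit the driving feature
#'   is read from (0 = the reference visit itself).
#' @param center subtract the feature's mean before applying the weight.
#' @return The modified registry.
#' @export
plant_signal <- function(registry, feature, weight, lag = 0L, center = FALSE) {
  stopifnot(inherits(registry, "ra_registry"))
  if (!feature %in% names(registry$visits))
    stop_anet("unknown feature '", feature, "'", class = "anet_schema_error")
  if (weight == 0) return(registry)
  latent <- attr(registry, "latent")
  if (is.null(latent))
    stop_anet("registry lacks latent metadata (was it round-tripped through disk?)")
  vis <- registry$visits
  x_all <- suppressWarnings(as.numeric(vis[[feature]]))
  fmean <- if (center) mean(x_all, na.rm = TRUE) else 0

  for (i in seq_along(latent)) {
    li <- latent[[i]]
    idx <- which(vis$patient_id == li$patient_id)
    k <- length(idx)
    if (k < 2) next
    x <- x_all[idx]
    x[is.na(x)] <- fmean # missing feature contributes no signal
    orig <- li$das_true
    new <- numeric(k)
    new[1] <- orig[1]
    for (t in 2:k) {
      ref <- t - 1 - lag
      sig <- if (ref >= 1) weight * (x[ref] - fmean) else 0
      new[t] <- clamp(new[t - 1] + (orig[t] - orig[t - 1]) + sig,
                      DAS28_MIN, DAS28_MAX)
    }
    new <- round(new, 2)
    obs <- vis$das28_bsr[idx]
    vis$das28_bsr[idx] <- ifelse(is.na(obs), NA, new)
    latent[[i]]$das_true <- new
  }
  registry$visits <- vis
  attr(registry, "latent") <- latent
  attr(registry, "planted") <- list(feature = feature, weight = weight,
                                    lag = as.integer(lag), center = center,
                                    feature_mean = fmean)
  registry
}

#' @export
print.ra_registry <- function(x, ...) {
  cat("Synthetic RA registry\n")
  cat("  patients:   ", nrow(x$patients), "\n")
  cat("  visits:     ", nrow(x$visits), "\n")
  cat("  medications:", nrow(x$medications), "\n")
  pl <- attr(x, "planted")
  if (!is.null(pl))
    cat(sprintf("  planted signal: %.3g x %s (lag %d)\n",
                pl$weight, pl$feature, pl$lag))
  invisible(x)
}
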
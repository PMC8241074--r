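#' Label disease state from a DAS28-BSR value
#'
#' Active disease is `DAS28-BSR > 2.6`; remission is `<= 2.6` (boundary
#' inclusive on the remission side).
#'
#' @param das28 numeric DAS28-BSR value(s).
#' @return Integer vector: 1 = active, 0 = remission.
#' @export
label_active <- function(das28) as.integer(das28 > 2.6)

#' Build supervised prediction instances from a registry
#'
#' Each visit with an observed DAS28-BSR is paired with the *next* visit
#' carrying an observed DAS28-BSR; the pair becomes an instance when the gap
#' lies between 1 month and 1 year (inclusive, 1 month = 30.44 days, 1 year
#' = 365.25 days).  The instance's history contains every visit and
#' medication event dated in `(reference - 5 years, reference]`, sorted by
#' date with medication events ordered before a same-day visit.  The
#' regression target is the score change `target - reference`; the
#' classification label is active disease at the target visit.
#'
#' @param registry an `ra_registry`.
#' @param schema an `anet_schema`.
#' @return An object of class `anet_instances`: list with `index` (one row
#'   per instance), `history` (per-instance event table: type + registry row
#'   + date), the `registry`, and a `report` of cohort counts.
#' @export
build_instances <- function(registry, schema = default_schema()) {
  vis <- registry$visits
  med <- registry$medications
  gap_lo <- 1 * DAYS_PER_MONTH
  gap_hi <- 12 * DAYS_PER_MONTH
  window <- 5 * DAYS_PER_YEAR

  vsplit <- split(seq_len(nrow(vis)), vis$patient_id)
  msplit <- split(seq_len(nrow(med)), med$patient_id)

  idx_rows <- list()
  history <- list()
  n_skipped <- 0L
  for (pid in registry$patients$patient_id) {
    vrows <- vsplit[[pid]] %||% integer(0)
    mrows <- msplit[[pid]] %||% integer(0)
    vdates <- as.numeric(vis$date[vrows])
    mdates <- as.numeric(med$date[mrows])
    das <- vis$das28_bsr[vrows]
    elig <- which(!is.na(das))
    made <- 0L
    if (length(elig) >= 2) {
      for (j in seq_len(length(elig) - 1)) {
        a <- elig[j]; b <- elig[j + 1]
        gap <- vdates[b] - vdates[a]
        if (gap < gap_lo || gap > gap_hi) next
        ref_t <- vdates[a]
        keep_v <- which(vdates > ref_t - window & vdates <= ref_t)
        keep_m <- which(mdates > ref_t - window & mdates <= ref_t)
        h <- data.frame(
          type = c(rep("medication", length(keep_m)),
                   rep("visit", length(keep_v))),
          row = c(mrows[keep_m], vrows[keep_v]),
          date = as.Date(c(mdates[keep_m], vdates[keep_v]),
                         origin = "1970-01-01"),
          stringsAsFactors = FALSE)
        # stable sort by date: medication events listed first win ties, so a
        # visit "sees" same-day treatment changes
        h <- h[order(h$date), , drop = FALSE]
        rownames(h) <- NULL
        history[[length(history) + 1L]] <- h
        idx_rows[[length(idx_rows) + 1L]] <- data.frame(
          patient_id = pid,
          reference_date = as.Date(ref_t, origin = "1970-01-01"),
          target_date = as.Date(vdates[b], origin = "1970-01-01"),
          gap_days = gap,
          reference_das28 = das[a],
          target_das28 = das[b],
          delta_das28 = das[b] - das[a],
          label_active = label_active(das[b]),
          n_events = nrow(h),
          stringsAsFactors = FALSE)
        made <- made + 1L
      }
    }
    if (made == 0L) n_skipped <- n_skipped + 1L
  }
  index <- if (length(idx_rows) > 0) do.call(rbind, idx_rows) else
    data.frame(patient_id = character(0))
  rownames(index) <- NULL
  structure(
    list(index = index, history = history, registry = registry,
         report = list(
           n_patients = nrow(registry$patients),
           n_patients_skipped = n_skipped,
           n_instances = nrow(index),
           n_reference_visits = nrow(index),
           n_target_visits = length(unique(paste(index$patient_id,
                                                 index$target_date))))),
    class = "anet_instances")
}

#' @export
print.anet_instances <- function(x, ...) {
  r <- x$report
  cat("Prediction instances:", r$n_instances, "\n")
  cat("  patients:", r$n_patients, "(", r$n_patients_skipped,
      "yielded no instance )\n")
  cat("  reference visits:", r$n_reference_visits,
      "; distinct target visits:", r$n_target_visits, "\n")
  if (r$n_instances > 0)
    cat(sprintf("  active at target: %.1f%%\n",
                100 * mean(x$index$label_active)))
  invisible(x)
}

#' Subset an instance collection
#'
#' @param instances an `anet_instances`.
#' @param which integer or logical index over instances.
#' @return A new `anet_instances` restricted to the selected instances.
#' @export
subset_instances <- function(instances, which) {
  if (is.logical(which)) which <- base::which(which)
  instances$index <- instances$index[which, , drop = FALSE]
  rownames(instances$index) <- NULL
  instances$history <- instances$history[which]
  instances$report$n_instances <- nrow(instances$index)
  instances
}

#' Assign patient-level cross-validation folds
#'
#' All instances of one patient share a fold (visit-level splitting would
#' leak near-duplicate histories between train and test).  Patients are
#' shuffled under the seed and greedily assigned to the currently smallest
#' fold by instance count, keeping test folds near 20% of instances each
#' for k = 5.
#'
#' @param instances an `anet_instances`.
#' @param k number of folds.
#' @param seed integer seed.
#' @return An object of class `anet_folds`: data frame `patients`
#'   (patient_id, fold) and integer vector `instance_fold`.
#' @export
assign_folds <- function(instances, k = 5L, seed = 1L) {
  counts <- table(instances$index$patient_id)
  pids <- names(counts)
  if (length(pids) < k)
    stop_anet("k = ", k, " folds but only ", length(pids),
              " patients with instances", class = "anet_validation_error")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, "folds"))
  ord <- sample(seq_along(pids))
  fold_of <- integer(length(pids))
  names(fold_of) <- pids
  load <- numeric(k)
  for (i in ord) {
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + counts[i]
  }
  structure(list(
    patients = data.frame(patient_id = pids, fold = unname(fold_of),
                          stringsAsFactors = FALSE),
    instance_fold = unname(fold_of[instances$index$patient_id]),
    k = as.integer(k)),
    class = "anet_folds")
}

#' Subgroup criteria for test-set stratification
#'
#' The boundary conventions: age >= 50 and disease duration >= 3 years fall
#' in the upper bucket.  Instances whose stratifier is missing belong to
#' neither bucket of a pair.
#'
#' @return Named list of criterion descriptions; names are the accepted
#'   `criterion` values of [subgroup_filter()].
#' @export
subgroup_criteria <- function() {
  list(age_ge_50 = "Age >= 50 years", age_lt_50 = "Age < 50 years",
       duration_lt_3 = "Disease duration < 3 years",
       duration_ge_3 = "Disease duration >= 3 years",
       rf_positive = "Rheumatoid factor positive",
       rf_negative = "Rheumatoid factor negative",
       accp_negative = "Anti-CCP negative", accp_positive = "Anti-CCP positive",
       male = "Male", female = "Female")
}

# complementary pairs compared by the cross-fold Welch test
subgroup_pairs <- function() {
  list(c("age_ge_50", "age_lt_50"), c("duration_ge_3", "duration_lt_3"),
       c("rf_positive", "rf_negative"), c("accp_positive", "accp_negative"),
       c("male", "female"))
}

#' Filter instances by a patient subgroup criterion
#'
#' @param instances an `anet_instances`.
#' @param criterion one of `names(subgroup_criteria())`.
#' @return Logical vector over instances (TRUE = in subgroup).
#' @export
subgroup_filter <- function(instances, criterion) {
  if (!criterion %in% names(subgroup_criteria()))
    stop_anet("unknown subgroup criterion '", criterion, "'",
              class = "anet_validation_error")
  pts <- instances$registry$patients
  i <- match(instances$index$patient_id, pts$patient_id)
  sel <- switch(criterion,
    age_ge_50 = pts$age[i] >= 50,
    age_lt_50 = pts$age[i] < 50,
    duration_ge_3 = pts$disease_duration[i] >= 3,
    duration_lt_3 = pts$disease_duration[i] < 3,
    rf_positive = pts$rf_status[i] == "positive",
    rf_negative = pts$rf_status[i] == "negative",
    accp_positive = pts$anti_ccp[i] == "positive",
    accp_negative = pts$anti_ccp[i] == "negative",
    male = pts$gender[i] == "male",
    female = pts$gender[i] == "female")
  sel[is.na(sel)] <- FALSE
  if (!any(sel))
    warning("subgroup '", criterion, "' selects no instances", call. = FALSE)
  sel
}

#' Flatten instances for the baseline models
#'
#' The flat view concatenates the general patient vector, the reference
#' (last) visit's 21-slot vector, the most recent medication event's 18-slot
#' vector inside the window (all-zero when the patient has none), and the
#' time from that adjustment to the reference visit (months, scaled over
#' 0-60).  Baselines see exactly this view and never the full sequence.
#'
#' @param instances an `anet_instances`.
#' @param schema an `anet_schema`.
#' @param scaling an `anet_scaling`.
#' @return A list with `x` (numeric matrix, named columns), and the target
#'   columns `delta`, `label`, `reference_das28`, `target_das28`.
#' @export
flatten_instances <- function(instances, schema = default_schema(), scaling) {
  enc <- encode_registry(instances$registry, schema, scaling)
  n <- nrow(instances$index)
  gen_i <- match(instances$index$patient_id,
                 instances$registry$patients$patient_id)
  xg <- enc$general[gen_i, , drop = FALSE]
  nv <- ncol(enc$visit); nm <- ncol(enc$medication)
  xv <- matrix(0, n, nv, dimnames = list(NULL, colnames(enc$visit)))
  xm <- matrix(0, n, nm, dimnames = list(NULL, colnames(enc$medication)))
  tsl <- numeric(n)
  for (i in seq_len(n)) {
    h <- instances$history[[i]]
    vrows <- h$row[h$type == "visit"]
    if (length(vrows) > 0) xv[i, ] <- enc$visit[vrows[length(vrows)], ]
    mrows <- h$row[h$type == "medication"]
    if (length(mrows) > 0) {
      last_m <- mrows[length(mrows)]
      xm[i, ] <- enc$medication[last_m, ]
      # the event-level recency slot must not reference an adjustment
      # outside the instance window
      med_pid <- instances$registry$medications$patient_id
      has_prev <- last_m > 1 && med_pid[last_m - 1L] == med_pid[last_m]
      if (has_prev && !((last_m - 1L) %in% mrows))
        xm[i, "time_since_adjustment"] <- 0
      tsl[i] <- as.numeric(instances$index$reference_date[i] -
                             instances$registry$medications$date[last_m]) /
        DAYS_PER_MONTH
    }
  }
  colnames(xg) <- paste0("general.", colnames(xg))
  colnames(xv) <- paste0("visit.", colnames(xv))
  colnames(xm) <- paste0("medication.", colnames(xm))
  x <- cbind(xg, xv, xm,
             months_since_last_adjustment = scale01(tsl, 0, 60))
  list(x = x,
       delta = instances$index$delta_das28,
       label = instances$index$label_active,
       reference_das28 = instances$index$reference_das28,
       target_das28 = instances$index$target_das28)
}
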
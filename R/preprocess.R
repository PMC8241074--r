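#' Fit feature scaling on training data
#'
#' Learns per-numeric-feature (min, max, median) from the given patients'
#' rows only, so cross-validation folds never leak test statistics.  All
#' features are later scaled into `[0, 1]`; out-of-range values seen at
#' transform time are clipped, constant features map to 0, and missing
#' numerics are imputed with the training median (with companion missing
#' indicators for the features that carry one in the schema).
#'
#' @param registry an `ra_registry`.
#' @param patient_ids patients to learn from (default: all).
#' @param schema an `anet_schema`.
#' @return A data frame of class `anet_scaling` with columns
#'   `feature, group, min, max, median`.
#' @export
fit_scaling <- function(registry, patient_ids = NULL, schema = default_schema()) {
  take <- function(df) {
    if (is.null(patient_ids)) df
    else df[df$patient_id %in% patient_ids, , drop = FALSE]
  }
  pts <- take(registry$patients)
  vis <- take(registry$visits)
  rows <- list()
  for (group in c("general", "visit")) {
    src <- if (group == "general") pts else vis
    for (f in schema[[group]]) {
      if (f$kind != "numeric" || isTRUE(f$optional) || isTRUE(f$derived)) next
      x <- suppressWarnings(as.numeric(src[[f$name]]))
      x <- x[!is.na(x)]
      if (length(x) == 0)
        stop_anet("cannot fit scaling: feature '", f$name,
                  "' has no observed values in the training data",
                  class = "anet_validation_error")
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f$name, group = group,
        min = min(x), max = max(x), median = stats::median(x),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("anet_scaling", "data.frame")
  out
}

scaling_row <- function(scaling, feature) {
  i <- match(feature, scaling$feature)
  if (is.na(i)) stop_anet("no scaling fitted for feature '", feature, "'")
  scaling[i, ]
}

# Scale already-imputed values into [0,1] with clipping; constant -> 0.
scale01 <- function(x, mn, mx) {
  if (mx > mn) clamp((x - mn) / (mx - mn), 0, 1) else rep(0, length(x))
}

encode_numeric <- function(x, sc, with_indicator) {
  miss <- is.na(x)
  x[miss] <- sc$median
  v <- scale01(x, sc$min, sc$max)
  if (with_indicator) cbind(v, as.numeric(miss)) else cbind(v)
}

encode_categorical <- function(x, levels, feature) {
  x <- as.character(x)
  m <- matrix(0, nrow = length(x), ncol = length(levels))
  idx <- match(x, levels)
  unseen <- !is.na(x) & is.na(idx)
  if (any(unseen))
    warning(sprintf("feature '%s': %d value(s) at unseen level(s) %s mapped to all-zero block",
                    feature, sum(unseen),
                    paste(unique(x[unseen]), collapse = ", ")), call. = FALSE)
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1
  m
}

encode_group <- function(df, group, schema, scaling) {
  n <- nrow(df)
  cols <- list()
  for (f in schema[[group]]) {
    if (isTRUE(f$optional) || isTRUE(f$derived)) next
    if (f$kind == "numeric") {
      sc <- scaling_row(scaling, f$name)
      cols[[f$name]] <- encode_numeric(df[[f$name]], sc,
                                       isTRUE(f$missing_indicator))
    } else if (identical(f$encode, "binary_female")) {
      cols[[f$name]] <- cbind(as.numeric(!is.na(df[[f$name]]) &
                                           df[[f$name]] == "female"))
    } else {
      cols[[f$name]] <- encode_categorical(df[[f$name]], unlist(f$levels),
                                           f$name)
    }
  }
  m <- do.call(cbind, cols)
  nms <- character(0)
  for (f in schema[[group]]) {
    if (isTRUE(f$optional) || isTRUE(f$derived)) next
    if (f$kind == "numeric") {
      nms <- c(nms, f$name,
               if (isTRUE(f$missing_indicator)) paste0(f$name, "_missing"))
    } else if (identical(f$encode, "binary_female")) {
      nms <- c(nms, paste0(f$name, "=female"))
    } else {
      nms <- c(nms, paste0(f$name, "=", unlist(f$levels)))
    }
  }
  colnames(m) <- nms
  m
}

#' Encode registry tables into fixed-width numeric vectors
#'
#' Expands each visit row to the 21-slot visit vector, each medication event
#' to the 18-slot medication vector (including the derived
#' time-since-previous-adjustment slot, scaled over 0-60 months), and each
#' patient to the general feature vector.  Categorical features are one-hot
#' over the schema's level sets; unseen levels map to an all-zero block with
#' a warning; missing numerics are median-imputed under `scaling`.
#'
#' @param registry an `ra_registry`.
#' @param schema an `anet_schema`.
#' @param scaling an `anet_scaling` from [fit_scaling()].
#' @return A list with matrices `visit` (n_visits x 21), `medication`
#'   (n_medications x 18), `general` (n_patients x width), each with slot
#'   column names, rows aligned with the registry tables.
#' @export
encode_registry <- function(registry, schema = default_schema(), scaling) {
  vis <- encode_group(registry$visits, "visit", schema, scaling)

  med_df <- registry$medications
  med <- encode_group(med_df, "medication", schema, scaling)
  tsa <- numeric(nrow(med_df))
  if (nrow(med_df) > 0) {
    d <- as.numeric(med_df$date)
    prev_same <- c(FALSE, med_df$patient_id[-1] ==
                     med_df$patient_id[-nrow(med_df)])
    gap_days <- c(0, diff(d))
    gap_days[!prev_same] <- 0
    tsa <- gap_days / DAYS_PER_MONTH
  }
  tf <- schema_features(schema, "medication")$time_since_adjustment
  med <- cbind(med, time_since_adjustment = scale01(tsa, tf$scale$min,
                                                    tf$scale$max))
  stopifnot(identical(colnames(med), slot_names(schema, "medication")))

  gen <- encode_group(registry$patients, "general", schema, scaling)
  list(visit = vis, medication = med, general = gen)
}
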
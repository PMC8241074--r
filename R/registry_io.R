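#' Write a registry to delimited text
#'
#' Three comma-separated UTF-8 tables (`patients.csv`, `visits.csv`,
#' `medications.csv`; empty string = missing, ISO-8601 dates) plus a
#' `manifest.json` recording the generating configuration (when present),
#' any planted signal, and the schema hash.
#'
#' @param registry an `ra_registry`.
#' @param dir output directory (created if needed).
#' @param schema schema used for the manifest hash.
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir, schema = default_schema()) {
  stopifnot(inherits(registry, "ra_registry"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("patients", "visits", "medications")) {
    utils::write.csv(registry[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  cfg <- attr(registry, "config")
  manifest <- list(
    schema_hash = schema_hash(schema),
    n_patients = nrow(registry$patients),
    n_visits = nrow(registry$visits),
    n_medications = nrow(registry$medications),
    config = if (!is.null(cfg)) unclass(cfg) else NULL,
    planted = attr(registry, "planted"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read and validate a registry from delimited text
#'
#' Loads the three tables written by [write_registry()] (or any tables with
#' the schema's columns), parses ISO-8601 dates, rejects rows with
#' unparseable dates (with row-level diagnostics), sorts events by date
#' within patient, and validates: required columns present, no duplicate
#' (patient, date) keys per event type, DAS28-BSR inside `[0, 9.4]`, and no
#' event dated before the patient's birth as implied by enrolment date and
#' age.
#'
#' @param dir directory containing `patients.csv`, `visits.csv`,
#'   `medications.csv`.
#' @param schema an `anet_schema`.
#' @return An `ra_registry`.
#' @export
read_registry <- function(dir, schema = default_schema()) {
  read1 <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop_anet("missing table: ", path,
                                      class = "anet_validation_error")
    utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
  }
  registry <- structure(list(patients = read1("patients"),
                             visits = read1("visits"),
                             medications = read1("medications")),
                        class = "ra_registry")
  validate_registry(registry, schema)
}

#' Validate a registry against the schema
#'
#' @param registry an `ra_registry` (tables may come from any source).
#' @param schema an `anet_schema`.
#' @return The validated registry (events date-sorted), invisibly usable.
#' @export
validate_registry <- function(registry, schema = default_schema()) {
  need <- list(
    patients = c("patient_id", schema_columns(schema, "general")),
    visits = c("patient_id", "date", schema_columns(schema, "visit")),
    medications = c("patient_id", "date", schema_columns(schema, "medication")))
  for (tab in names(need)) {
    missing_cols <- setdiff(need[[tab]], names(registry[[tab]]))
    if (length(missing_cols) > 0)
      stop_anet("table '", tab, "' is missing column(s): ",
                paste(missing_cols, collapse = ", "),
                class = "anet_validation_error")
  }

  parse_dates <- function(tab) {
    df <- registry[[tab]]
    if (nrow(df) == 0) {
      df$date <- as.Date(character(0))
      return(df)
    }
    d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(df$date))
    if (length(bad) > 0) {
      warning(sprintf("%s: dropping %d row(s) with unparseable dates (rows %s)",
                      tab, length(bad),
                      paste(utils::head(bad, 10), collapse = ", ")),
              call. = FALSE)
      df <- df[-bad, , drop = FALSE]
      d <- d[-bad]
    }
    keep <- !is.na(d)
    df <- df[keep, , drop = FALSE]
    df$date <- d[keep]
    df[order(df$patient_id, df$date), , drop = FALSE]
  }

  for (tab in c("visits", "medications")) {
    df <- parse_dates(tab)
    key <- paste(df$patient_id, df$date)
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      stop_anet("table '", tab, "' has duplicate (patient, date) rows: ",
                paste(utils::head(dup, 5), collapse = "; "),
                class = "anet_validation_error")
    }
    rownames(df) <- NULL
    registry[[tab]] <- df
  }

  das <- registry$visits$das28_bsr
  if (any(!is.na(das) & (das < DAS28_MIN | das > DAS28_MAX)))
    stop_anet("das28_bsr value(s) outside [", DAS28_MIN, ", ", DAS28_MAX, "]",
              class = "anet_validation_error")

  # impossible-age guard: no event may predate birth implied by enrolment
  # date and age at enrolment (only checkable when both are present)
  pts <- registry$patients
  if ("enrolment_date" %in% names(pts) && "age" %in% names(pts)) {
    registry$patients$enrolment_date <-
      as.Date(as.character(pts$enrolment_date), format = "%Y-%m-%d")
    enrol <- registry$patients$enrolment_date
    birth <- enrol - round(pts$age * DAYS_PER_YEAR)
    names(birth) <- pts$patient_id
    for (tab in c("visits", "medications")) {
      df <- registry[[tab]]
      b <- birth[df$patient_id]
      bad <- which(!is.na(b) & df$date < b)
      if (length(bad) > 0)
        stop_anet("table '", tab, "' has event(s) before patient birth ",
                  "(implied age < 0): rows ",
                  paste(utils::head(bad, 5), collapse = ", "),
                  class = "anet_validation_error")
    }
  }
  registry
}

#' Split a registry into per-patient records
#'
#' @param registry an `ra_registry`.
#' @return A named list (one element per patient) with components `general`
#'   (one-row data frame), `visits` and `medications` (date-sorted data
#'   frames, possibly empty).
#' @export
patient_records <- function(registry) {
  pid <- registry$patients$patient_id
  vsplit <- split(seq_len(nrow(registry$visits)), registry$visits$patient_id)
  msplit <- split(seq_len(nrow(registry$medications)),
                  registry$medications$patient_id)
  out <- lapply(seq_along(pid), function(i) {
    id <- pid[i]
    list(patient_id = id,
         general = registry$patients[i, , drop = FALSE],
         visits = registry$visits[vsplit[[id]] %||% integer(0), , drop = FALSE],
         medications = registry$medications[msplit[[id]] %||% integer(0), ,
                                            drop = FALSE])
  })
  names(out) <- pid
  out
}
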
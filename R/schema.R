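#' Load the feature schema
#'
#' The schema is the single source of truth for which registry columns exist,
#' their kind (numeric or categorical with a fixed level set), which group
#' they belong to (general patient features, per-visit features, per-
#' medication-event features), and how they expand into the fixed encoded
#' widths the network expects: 21 visit slots, 18 medication slots.
#' Numeric features flagged `missing_indicator` contribute an extra 0/1 slot
#' inside those budgets; features flagged `optional` (CRP, EuroQol) are
#' carried in the tables but excluded from the default encoding.
#'
#' @param path path to a schema JSON file; defaults to the schema shipped
#'   with the package.
#' @return An object of class `anet_schema`.
#' @export
default_schema <- function(path = system.file("extdata", "feature_schema.json",
                                              package = "adaptivenet")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  schema <- structure(raw, class = "anet_schema")
  validate_schema(schema)
  schema
}

validate_schema <- function(schema) {
  for (grp in c("general", "visit", "medication")) {
    if (is.null(schema[[grp]])) stop_anet("schema missing group '", grp, "'")
  }
  nms <- unlist(lapply(c("general", "visit", "medication"),
                       function(g) vapply(schema[[g]], `[[`, "", "name")))
  if (anyDuplicated(nms))
    stop_anet("feature(s) in more than one group: ",
              paste(unique(nms[duplicated(nms)]), collapse = ", "))
  for (grp in c("visit", "medication")) {
    got <- length(slot_names(schema, grp))
    want <- schema$encoded_widths[[if (grp == "visit") "visit" else "medication"]]
    if (got != want)
      stop_anet("schema group '", grp, "' expands to ", got,
                " slots, expected ", want)
  }
  invisible(schema)
}

schema_features <- function(schema, group) {
  feats <- schema[[group]]
  names(feats) <- vapply(feats, `[[`, "", "name")
  feats
}

# Encoded slot names for a group, in slot order.  Convention: numeric -> name,
# missing indicator -> name_missing, categorical level -> name=level.
slot_names <- function(schema, group) {
  out <- character(0)
  for (f in schema[[group]]) {
    if (isTRUE(f$optional)) next
    if (f$kind == "numeric") {
      out <- c(out, f$name)
      if (isTRUE(f$missing_indicator)) out <- c(out, paste0(f$name, "_missing"))
    } else if (identical(f$encode, "binary_female")) {
      out <- c(out, paste0(f$name, "=female"))
    } else {
      out <- c(out, paste0(f$name, "=", unlist(f$levels)))
    }
  }
  out
}

# Registry column names expected for a group's table (besides ids/dates).
# Derived features (time_since_adjustment) are computed, not stored.
schema_columns <- function(schema, group) {
  feats <- Filter(function(f) !isTRUE(f$derived), schema[[group]])
  vapply(feats, `[[`, "", "name")
}

#' Hash a schema
#'
#' 32-bit FNV-1a hash of the canonical JSON serialization.  Checkpoints store
#' this hash and refuse to load against a different schema.
#'
#' @param schema an `anet_schema`.
#' @return A character hash.
#' @export
schema_hash <- function(schema) {
  json <- jsonlite::toJSON(unclass(schema), auto_unbox = TRUE, digits = NA)
  sprintf("%08x", fnv1a32(as.character(json)))
}
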
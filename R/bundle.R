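#' Four-table claims bundle
#'
#' The unit of raw input for every analysis: an enrollment table
#' (observation window plus age/sex per patient), a diagnosis table
#' (ICD-10 coded), a drug-claim table (biologic administrations with class
#' and care setting) and a cost table (amounts in JPY by category). All
#' dates are integer day offsets from a common origin; [write_bundle()]
#' and [read_bundle()] translate to and from ISO-8601 dates on disk.
#'
#' Required columns:
#' \describe{
#'   \item{enrollment}{`patient_id`, `obs_start`, `obs_end`, `age`, `sex`}
#'   \item{diagnoses}{`patient_id`, `date`, `icd10`}
#'   \item{drug_claims}{`patient_id`, `date`, `drug_code`, `bt_class`,
#'     `setting` (one of `"inpatient"`, `"outpatient"`)}
#'   \item{costs}{`patient_id`, `date`, `amount_jpy`, `category` (one of
#'     `"IP"`, `"OP"`, `"RX"`), `is_bt_drug_cost`}
#' }
#'
#' @param enrollment,diagnoses,drug_claims,costs data frames as above.
#' @param origin ISO date string mapped to day 0 for disk round trips.
#' @param validate run [validate_claims_bundle()] on construction.
#' @return A `claims_bundle` (list of the four tables).
#' @export
claims_bundle <- function(enrollment, diagnoses, drug_claims, costs,
                          origin = "2010-01-01", validate = TRUE) {
  b <- structure(
    list(enrollment = as.data.frame(enrollment),
         diagnoses = as.data.frame(diagnoses),
         drug_claims = as.data.frame(drug_claims),
         costs = as.data.frame(costs)),
    origin = origin,
    class = "claims_bundle"
  )
  if (validate) validate_claims_bundle(b)
  b
}

bundle_columns <- list(
  enrollment = c("patient_id", "obs_start", "obs_end", "age", "sex"),
  diagnoses = c("patient_id", "date", "icd10"),
  drug_claims = c("patient_id", "date", "drug_code", "bt_class", "setting"),
  costs = c("patient_id", "date", "amount_jpy", "category", "is_bt_drug_cost")
)

#' An empty claims bundle with the correct schema
#' @inheritParams claims_bundle
#' @return A zero-row `claims_bundle`.
#' @export
empty_bundle <- function(origin = "2010-01-01") {
  claims_bundle(
    enrollment = data.frame(patient_id = character(), obs_start = integer(),
                            obs_end = integer(), age = integer(),
                            sex = character(), stringsAsFactors = FALSE),
    diagnoses = data.frame(patient_id = character(), date = integer(),
                           icd10 = character(), stringsAsFactors = FALSE),
    drug_claims = data.frame(patient_id = character(), date = integer(),
                             drug_code = character(), bt_class = character(),
                             setting = character(), stringsAsFactors = FALSE),
    costs = data.frame(patient_id = character(), date = integer(),
                       amount_jpy = numeric(), category = character(),
                       is_bt_drug_cost = logical(), stringsAsFactors = FALSE),
    origin = origin
  )
}

#' Validate a claims bundle
#'
#' Checks the schema (an error names the offending table and column),
#' referential integrity (child-table patients must exist in enrollment)
#' and that every dated record lies inside its patient's observation
#' window.
#'
#' @param bundle a `claims_bundle`.
#' @return `bundle`, invisibly; errors describe the first violation found.
#' @export
validate_claims_bundle <- function(bundle) {
  for (tab in names(bundle_columns)) {
    missing <- setdiff(bundle_columns[[tab]], names(bundle[[tab]]))
    if (length(missing))
      stop_("claims bundle table '%s' is missing column '%s'",
            tab, missing[1])
  }
  enr <- bundle$enrollment
  if (anyDuplicated(enr$patient_id))
    stop_("enrollment has duplicated patient_id values")
  if (any(enr$obs_end < enr$obs_start))
    stop_("enrollment has obs_end before obs_start")
  for (tab in c("diagnoses", "drug_claims", "costs")) {
    df <- bundle[[tab]]
    if (!nrow(df)) next
    i <- match(df$patient_id, enr$patient_id)
    if (anyNA(i))
      stop_("table '%s' refers to patient '%s' absent from enrollment",
            tab, df$patient_id[which(is.na(i))[1]])
    bad <- df$date < enr$obs_start[i] | df$date > enr$obs_end[i]
    if (any(bad))
      stop_("table '%s' has a claim outside the observation window (row %d)",
            tab, which(bad)[1])
  }
  if (nrow(bundle$drug_claims) &&
      !all(bundle$drug_claims$setting %in% c("inpatient", "outpatient")))
    stop_("drug_claims$setting must be 'inpatient' or 'outpatient'")
  if (nrow(bundle$costs) &&
      !all(bundle$costs$category %in% c("IP", "OP", "RX")))
    stop_("costs$category must be one of 'IP', 'OP', 'RX'")
  invisible(bundle)
}

#' Write / read a claims bundle as four CSV files
#'
#' `write_bundle()` writes `enrollment.csv`, `diagnoses.csv`,
#' `drug_claims.csv` and `costs.csv` with ISO-8601 dates;
#' `read_bundle()` reads them back. The pair round-trips a bundle
#' field-for-field when the same `origin` is used.
#'
#' @param bundle a `claims_bundle`.
#' @param directory path to write into / read from (created if needed).
#' @param origin ISO date string mapped to day 0 (read side; the write
#'   side uses the bundle's own origin attribute).
#' @return `write_bundle()` the file paths, invisibly; `read_bundle()` a
#'   validated `claims_bundle`.
#' @export
write_bundle <- function(bundle, directory) {
  validate_claims_bundle(bundle)
  origin <- attr(bundle, "origin") %||% "2010-01-01"
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  o <- as.Date(origin)
  to_iso <- function(day) format(o + as.integer(day))
  enr <- bundle$enrollment
  enr$obs_start <- to_iso(enr$obs_start)
  enr$obs_end <- to_iso(enr$obs_end)
  tabs <- list(enrollment = enr)
  for (tab in c("diagnoses", "drug_claims", "costs")) {
    df <- bundle[[tab]]
    df$date <- to_iso(df$date)
    tabs[[tab]] <- df
  }
  paths <- file.path(directory, paste0(names(tabs), ".csv"))
  for (i in seq_along(tabs))
    utils::write.csv(tabs[[i]], paths[i], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

parse_iso_days <- function(x, origin, table) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d))
    stop_("table '%s': malformed date '%s' (row %d)",
          table, as.character(x)[which(is.na(d))[1]], which(is.na(d))[1])
  as.integer(d - as.Date(origin))
}

#' @rdname write_bundle
#' @export
read_bundle <- function(directory, origin = "2010-01-01") {
  paths <- file.path(directory, paste0(names(bundle_columns), ".csv"))
  names(paths) <- names(bundle_columns)
  for (p in paths) if (!file.exists(p)) stop_("missing bundle file: %s", p)
  raw <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE,
                colClasses = c(patient_id = "character"))
  for (tab in names(raw)) {
    missing <- setdiff(bundle_columns[[tab]], names(raw[[tab]]))
    if (length(missing))
      stop_("bundle file '%s.csv' is missing column '%s'", tab, missing[1])
  }
  enr <- raw$enrollment
  enr$obs_start <- parse_iso_days(enr$obs_start, origin, "enrollment")
  enr$obs_end <- parse_iso_days(enr$obs_end, origin, "enrollment")
  for (tab in c("diagnoses", "drug_claims", "costs"))
    raw[[tab]]$date <- parse_iso_days(raw[[tab]]$date, origin, tab)
  raw$costs$is_bt_drug_cost <- as.logical(raw$costs$is_bt_drug_cost)
  claims_bundle(enr, raw$diagnoses, raw$drug_claims, raw$costs,
                origin = origin)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (tab in names(bundle_columns))
    cat(sprintf("  %-11s %6d rows\n", tab, nrow(x[[tab]])))
  cat(sprintf("  origin      %s\n", attr(x, "origin") %||% "2010-01-01"))
  invisible(x)
}
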
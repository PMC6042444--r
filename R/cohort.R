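#' Select patients with the inclusion diagnosis and a biologic claim
#'
#' First stage of the selection cascade: keep exactly the patients with at
#' least one diagnosis matching an inclusion prefix (psoriasis L40 by
#' default) and at least one biologic drug claim. Stage counts (claims
#' and patients at each step) are attached as the `"cascade"` attribute
#' for flow-diagram reporting.
#'
#' @param bundle a [claims_bundle()].
#' @param codes a [code_policy()].
#' @return Character vector of patient ids (sorted), with a `cascade`
#'   attribute data frame of `stage` / `count`.
#' @examples
#' sim <- generate_cohort(simulation_config(n_patients = 100, seed = 3))
#' pts <- select_psoriasis_bt_patients(sim$bundle)
#' attr(pts, "cascade")
#' @export
select_psoriasis_bt_patients <- function(bundle,
                                         codes = default_code_policy()) {
  dg <- bundle$diagnoses
  inc_hit <- match_icd_prefix(dg$icd10, codes$inclusion_codes)
  dx_patients <- unique(dg$patient_id[inc_hit])
  bt_patients <- unique(bundle$drug_claims$patient_id)
  keep <- sort(intersect(dx_patients, bt_patients))
  cascade <- data.frame(
    stage = c("inclusion_dx_claims", "inclusion_dx_patients",
              "bt_claims", "bt_patients", "dx_and_bt_patients"),
    count = c(sum(inc_hit), length(dx_patients),
              nrow(bundle$drug_claims), length(bt_patients),
              length(keep)),
    stringsAsFactors = FALSE)
  structure(keep, cascade = cascade)
}

#' Remove patients carrying an exclusion diagnosis
#'
#' Drops any patient with at least one diagnosis, at any time, matching
#' one of the exclusion prefixes (rheumatoid arthritis, inflammatory
#' bowel disease, ankylosing spondylitis, juvenile arthritis by default).
#'
#' @param patients character vector of patient ids (typically from
#'   [select_psoriasis_bt_patients()]).
#' @inheritParams select_psoriasis_bt_patients
#' @return The retained patient ids, with a `cascade` attribute
#'   continuing the stage counts.
#' @export
apply_exclusions <- function(patients, bundle,
                             codes = default_code_policy()) {
  dg <- bundle$diagnoses
  flagged <- unique(dg$patient_id[match_icd_prefix(dg$icd10,
                                                   codes$exclusion_codes)])
  keep <- sort(setdiff(patients, flagged))
  cascade <- rbind(
    attr(patients, "cascade"),
    data.frame(stage = c("excluded_by_dx", "after_exclusions"),
               count = c(length(patients) - length(keep), length(keep)),
               stringsAsFactors = FALSE))
  structure(keep, cascade = cascade)
}

#' Build patient-units: one analysis record per patient x biologic
#'
#' A patient contributes one unit per biologic class received, indexed at
#' that biologic's first claim date; multiple treatment cycles in one
#' patient are deliberately counted as separate units and never
#' deduplicated across drugs.
#'
#' @param patients character vector of patient ids after exclusions.
#' @inheritParams select_psoriasis_bt_patients
#' @param drugs recognised biologic classes; a drug claim with a
#'   `bt_class` outside this set is an error naming the offending code.
#' @return Data frame with one row per unit: `unit_id`, `patient_id`,
#'   `drug`, `index_day`, `obs_start`, `obs_end`, `age`, `sex`.
#' @export
build_patient_units <- function(patients, bundle, drugs = BT_DRUGS) {
  dc <- bundle$drug_claims[bundle$drug_claims$patient_id %in% patients, ,
                           drop = FALSE]
  unknown <- setdiff(unique(dc$bt_class), drugs)
  if (length(unknown))
    stop_("drug claim with unknown bt_class '%s'", unknown[1])
  if (!nrow(dc)) {
    return(data.frame(unit_id = character(), patient_id = character(),
                      drug = character(), index_day = integer(),
                      obs_start = integer(), obs_end = integer(),
                      age = integer(), sex = character(),
                      stringsAsFactors = FALSE))
  }
  first <- stats::aggregate(date ~ patient_id + bt_class, data = dc,
                            FUN = min)
  names(first) <- c("patient_id", "drug", "index_day")
  enr <- bundle$enrollment
  i <- match(first$patient_id, enr$patient_id)
  units <- data.frame(
    unit_id = paste(first$patient_id, first$drug, sep = ":"),
    patient_id = first$patient_id,
    drug = first$drug,
    index_day = as.integer(first$index_day),
    obs_start = enr$obs_start[i],
    obs_end = enr$obs_end[i],
    age = enr$age[i],
    sex = enr$sex[i],
    stringsAsFactors = FALSE)
  units <- units[order(units$patient_id, units$index_day, units$drug), ,
                 drop = FALSE]
  rownames(units) <- NULL
  units
}

#' Classify biologic-naive status of patient-units
#'
#' A unit is naive when no claim of any biologic falls in the 365 days
#' before its index date (the window `[index - 365, index - 1]`, both
#' bounds inside). Proving naivety additionally requires 365 days of
#' pre-index enrollment; units indexed too early to observe a full
#' look-back year and without a visible prior claim are labelled
#' according to `unknown_as` ("experienced" by default).
#'
#' @param units data frame from [build_patient_units()].
#' @inheritParams select_psoriasis_bt_patients
#' @param lookback_days look-back window length in days.
#' @param unknown_as label for units whose look-back window is not fully
#'   enrolled and shows no prior claim: `"experienced"` or `"naive"`.
#' @return `units` with a logical `naive` column added.
#' @export
classify_naive <- function(units, bundle, lookback_days = 365L,
                           unknown_as = c("experienced", "naive")) {
  unknown_as <- match.arg(unknown_as)
  dc <- bundle$drug_claims
  by_patient <- split(dc$date, dc$patient_id)
  prior <- vapply(seq_len(nrow(units)), function(k) {
    d <- by_patient[[units$patient_id[k]]]
    idx <- units$index_day[k]
    any(d >= idx - lookback_days & d <= idx - 1L)
  }, logical(1))
  observable <- units$index_day - units$obs_start >= lookback_days
  units$naive <- !prior & (observable | unknown_as == "naive")
  units
}

#' Restrict to units eligible for the pre/post cost analysis
#'
#' Keeps units with at least 12 months of enrollment on both sides of
#' the index date: `obs_start <= index - 365` and
#' `obs_end >= index + 365`.
#'
#' @param units data frame from [build_patient_units()].
#' @return The eligible subset of `units`.
#' @export
select_cost_population <- function(units) {
  keep <- units$obs_start <= units$index_day - DAYS_12M &
    units$obs_end >= units$index_day + DAYS_12M
  out <- units[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-condition comorbidity flags for patient-units
#'
#' One logical flag per condition in the policy's comorbidity map, true
#' when the unit's patient has at least one matching diagnosis at any
#' time.
#'
#' @inheritParams classify_naive
#' @return Data frame: `unit_id` plus one logical column per condition.
#' @export
comorbidity_flags <- function(units, bundle,
                              codes = default_code_policy()) {
  dg <- bundle$diagnoses
  out <- data.frame(unit_id = units$unit_id, stringsAsFactors = FALSE)
  for (cond in names(codes$comorbidity_code_map)) {
    flagged <- unique(dg$patient_id[
      match_icd_prefix(dg$icd10, codes$comorbidity_code_map[[cond]])])
    out[[cond]] <- units$patient_id %in% flagged
  }
  out
}
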
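#' Refill-gap policy for treatment-episode construction
#'
#' A gap policy fixes, per drug, the scheduled treatment interval (days
#' between administrations under the approved regimen) and the permissible
#' medication gap (extra refill delay tolerated before therapy counts as
#' discontinued). Their sum is the non-biologic refill period: a span
#' without an index-drug claim longer than this period defines a
#' gap-discontinuation.
#'
#' The base case uses a 30-day interval for ADL, IFX and SCK, a 90-day
#' interval for UST, and a 60-day medication gap for all four, giving
#' non-refill periods of 90/90/90/150 days.
#'
#' @param treatment_interval_days named integer vector, days between
#'   scheduled claims per drug.
#' @param medication_gap_days permissible gap in days; a single value
#'   (recycled) or a vector named like `treatment_interval_days`.
#' @return A `gap_policy` data frame with columns `drug`,
#'   `treatment_interval_days`, `medication_gap_days`, `non_refill_days`.
#' @examples
#' default_gap_policy()
#' gap_policy(medication_gap_days = 90)  # sensitivity variant
#' @export
gap_policy <- function(treatment_interval_days = c(ADL = 30L, IFX = 30L,
                                                   SCK = 30L, UST = 90L),
                       medication_gap_days = 60L) {
  drugs <- names(treatment_interval_days)
  if (is.null(drugs) || any(!nzchar(drugs)))
    stop_("treatment_interval_days must be a named vector of drugs")
  ti <- as.integer(treatment_interval_days)
  gap <- as.integer(medication_gap_days)
  if (length(gap) == 1L) gap <- rep(gap, length(ti))
  else if (!is.null(names(medication_gap_days)))
    gap <- as.integer(medication_gap_days[drugs])
  if (length(gap) != length(ti) || anyNA(gap))
    stop_("medication_gap_days must be scalar or named per drug")
  if (any(ti <= 0L) || any(gap <= 0L))
    stop_("treatment interval and medication gap must be positive")
  out <- data.frame(
    drug = drugs,
    treatment_interval_days = ti,
    medication_gap_days = gap,
    non_refill_days = ti + gap,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gap_policy", "data.frame")
  out
}

#' @rdname gap_policy
#' @export
default_gap_policy <- function() gap_policy()

#' Sensitivity set of gap policies
#'
#' Builds a named list of [gap_policy()] objects sharing the base treatment
#' intervals but varying the medication gap, for gap-sensitivity analyses.
#' Defaults to the base case (60 days) plus 30- and 90-day variants.
#'
#' @param gaps integer vector of medication gaps in days; names become the
#'   policy labels (unnamed gaps are labelled `gap<days>`).
#' @inheritParams gap_policy
#' @return Named list of `gap_policy` objects.
#' @export
sensitivity_policies <- function(gaps = c(base = 60L, SA1 = 30L, SA2 = 90L),
                                 treatment_interval_days = c(ADL = 30L,
                                   IFX = 30L, SCK = 30L, UST = 90L)) {
  labels <- names(gaps)
  if (is.null(labels)) labels <- paste0("gap", gaps)
  labels[!nzchar(labels)] <- paste0("gap", gaps[!nzchar(labels)])
  out <- lapply(gaps, function(g)
    gap_policy(treatment_interval_days, medication_gap_days = g))
  names(out) <- labels
  out
}

policy_row <- function(policy, drug) {
  i <- match(drug, policy$drug)
  if (is.na(i)) stop_("no gap policy entry for drug '%s'", drug)
  policy[i, ]
}

normalize_icd <- function(x) gsub("[. ]", "", toupper(as.character(x)))

# TRUE for codes starting with any of the (normalized) prefixes.
match_icd_prefix <- function(codes, prefixes) {
  codes <- normalize_icd(codes)
  prefixes <- normalize_icd(prefixes)
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

#' ICD-10 code policy: inclusion, exclusion and comorbidity code sets
#'
#' Diagnosis matching is by code prefix on normalised codes (upper case,
#' dots stripped), so prefix `"L40"` matches `"L40.5"`. Defaults:
#' psoriasis (L40) for inclusion; rheumatoid arthritis (M05-M06),
#' inflammatory bowel disease (K50-K51), ankylosing spondylitis (M45) and
#' juvenile arthritis (M08) for exclusion; and a seven-condition
#' comorbidity map (obesity E66; diabetes without/with complication as two
#' E10-E14 subsets split on the fourth character; hypertension I10-I15;
#' hyperlipidemia E78; old myocardial infarction I21/I22/I25.2; heart
#' failure I50). All sets are overridable.
#'
#' @param inclusion_codes character, ICD-10 prefixes selecting the disease
#'   of interest.
#' @param exclusion_codes character, prefixes of diseases whose carriers
#'   are removed from the cohort.
#' @param comorbidity_code_map named list of prefix sets, one per
#'   comorbid condition.
#' @return A `code_policy` list.
#' @examples
#' pol <- default_code_policy()
#' names(pol$comorbidity_code_map)
#' @export
code_policy <- function(inclusion_codes = "L40",
                        exclusion_codes = c("M05", "M06", "K50", "K51",
                                            "M45", "M08"),
                        comorbidity_code_map = default_comorbidity_map()) {
  inc <- normalize_icd(inclusion_codes)
  exc <- normalize_icd(exclusion_codes)
  clash <- c(outer(inc, exc, startsWith), outer(exc, inc, startsWith))
  if (any(clash))
    stop_("inclusion and exclusion code sets overlap")
  structure(
    list(inclusion_codes = inc, exclusion_codes = exc,
         comorbidity_code_map = lapply(comorbidity_code_map, normalize_icd)),
    class = "code_policy"
  )
}

#' @rdname code_policy
#' @export
default_code_policy <- function() code_policy()

#' @rdname code_policy
#' @export
default_comorbidity_map <- function() {
  dm <- paste0("E1", 0:4)
  list(
    obesity = "E66",
    # fourth character 9 = "without complications"; 0-8 = complicated
    diabetes_uncomplicated = paste0(dm, "9"),
    diabetes_complicated = as.vector(outer(dm, 0:8, paste0)),
    hypertension = paste0("I1", 0:5),
    hyperlipidemia = "E78",
    old_mi = c("I21", "I22", "I252"),
    heart_failure = "I50"
  )
}
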
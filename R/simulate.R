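#' Configuration for the synthetic claims generator
#'
#' Defines a simulated employer-insurance population of psoriasis patients
#' on injectable biologics, with known ground truth. Discontinuation is
#' sampled per 30-day cycle with a per-drug hazard (geometric), so the
#' probability of discontinuing within 12 months is `1 - (1 - h)^12`.
#' Index-drug claims are emitted at the drug's dosing interval strictly
#' before the sampled discontinuation day; a switch, when sampled, places
#' the first claim of the new biologic one dosing interval after the last
#' index-drug claim.
#'
#' Defaults describe a cohort shaped like the published Japanese
#' psoriasis biologics population this generator emulates: drug mix
#' 42/52/21/90 over 205 across ADL/IFX/SCK/UST, per-cycle hazards derived
#' from 12-month persistence around 47/53/55/79 percent, 86.3% biologic
#' naive, 18.1% female, mean age 47, and monthly cost levels scaled from
#' yearly per-patient costs around 0.64M JPY pre- and 2.8M JPY
#' post-initiation.
#'
#' @param n_patients number of simulated patients (>= 0).
#' @param drug_mix per-drug probability of the index biologic; must sum
#'   to 1 (tolerance 1e-9).
#' @param monthly_discontinuation_hazard per-drug discontinuation
#'   probability per 30-day cycle, in \[0, 1\].
#' @param switch_probability probability that a sampled discontinuation is
#'   a switch to another biologic rather than a stop.
#' @param dosing_interval_days per-drug scheduled days between claims.
#' @param pre_cost_params,post_cost_params per-category (`IP`, `OP`, `RX`)
#'   `c(mean, dispersion)` of the monthly background cost in JPY, before
#'   and after the index date. Amounts are gamma distributed with the
#'   given mean and squared coefficient of variation `dispersion`;
#'   dispersion 0 gives the mean deterministically.
#' @param bt_cost_per_claim per-drug mean JPY billed per biologic
#'   administration (flagged `is_bt_drug_cost`, category IP or OP by
#'   setting).
#' @param enrollment_span_days observation length per patient, days.
#' @param index_day_range integer length-2, admissible index days within
#'   the enrollment window; default `c(365, enrollment_span_days - 365)`
#'   so each unit has a full look-back year and 12 months of follow-up.
#' @param naive_fraction fraction of biologic users with no biologic claim
#'   in the year before index; the rest carry a prior treatment sequence
#'   of a different biologic ending in a switch to the index drug.
#' @param female_fraction probability of female sex.
#' @param comorbidity_prevalence named per-condition probabilities;
#'   condition names must match the comorbidity map in use.
#' @param exclusion_prevalence probability of carrying a diagnosis of one
#'   of the excluded diseases (rheumatoid arthritis, inflammatory bowel
#'   disease, ankylosing spondylitis, juvenile arthritis).
#' @param l40_fraction fraction of patients carrying a psoriasis (L40)
#'   diagnosis; the rest carry a decoy dermatitis code (L20).
#' @param bt_fraction fraction of patients receiving any biologic; the
#'   rest are background patients exercising the selection cascade.
#' @param inpatient_claim_prob per-drug probability that an
#'   administration is billed in the inpatient setting.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   tables.
#' @return A validated `simulation_config` list.
#' @examples
#' cfg <- simulation_config(n_patients = 50, seed = 42)
#' sim <- generate_cohort(cfg)
#' sim$bundle
#' head(sim$truth)
#' @export
simulation_config <- function(
    n_patients = 500L,
    drug_mix = c(ADL = 42, IFX = 52, SCK = 21, UST = 90) / 205,
    monthly_discontinuation_hazard = c(ADL = 0.0613, IFX = 0.0515,
                                       SCK = 0.0480, UST = 0.0190),
    switch_probability = 0.30,
    dosing_interval_days = c(ADL = 30L, IFX = 30L, SCK = 30L, UST = 90L),
    pre_cost_params = list(IP = c(mean = 15700, dispersion = 1),
                           OP = c(mean = 17500, dispersion = 1),
                           RX = c(mean = 20300, dispersion = 1)),
    post_cost_params = list(IP = c(mean = 34700, dispersion = 1),
                            OP = c(mean = 40000, dispersion = 1),
                            RX = c(mean = 19900, dispersion = 1)),
    bt_cost_per_claim = c(ADL = 120000, IFX = 180000,
                          SCK = 120000, UST = 450000),
    enrollment_span_days = 1460L,
    index_day_range = NULL,
    naive_fraction = 0.863,
    female_fraction = 0.181,
    comorbidity_prevalence = c(obesity = 0.005,
                               diabetes_uncomplicated = 0.059,
                               diabetes_complicated = 0.034,
                               hypertension = 0.239,
                               hyperlipidemia = 0.224,
                               old_mi = 0.010,
                               heart_failure = 0.068),
    exclusion_prevalence = 0.546,
    l40_fraction = 0.95,
    bt_fraction = 0.90,
    inpatient_claim_prob = c(ADL = 0.02, IFX = 0.15,
                             SCK = 0.02, UST = 0.02),
    seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @param config a `simulation_config`.
#' @export
validate_simulation_config <- function(config) {
  if (length(config$n_patients) != 1L || is.na(config$n_patients) ||
      config$n_patients < 0 || config$n_patients != round(config$n_patients))
    stop_("invalid simulation config: 'n_patients' must be a non-negative integer")
  drugs <- names(config$drug_mix)
  if (is.null(drugs) || !setequal(drugs, names(config$dosing_interval_days)) ||
      !setequal(drugs, names(config$monthly_discontinuation_hazard)))
    stop_(paste("invalid simulation config: 'drug_mix',",
                "'monthly_discontinuation_hazard' and 'dosing_interval_days'",
                "must be named consistently"))
  if (abs(sum(config$drug_mix) - 1) > 1e-9)
    stop_("invalid simulation config: 'drug_mix' must sum to 1")
  check_prob(config$drug_mix, "drug_mix")
  check_prob(config$monthly_discontinuation_hazard,
             "monthly_discontinuation_hazard")
  check_prob(config$switch_probability, "switch_probability")
  check_prob(config$naive_fraction, "naive_fraction")
  check_prob(config$female_fraction, "female_fraction")
  check_prob(config$comorbidity_prevalence, "comorbidity_prevalence")
  check_prob(config$exclusion_prevalence, "exclusion_prevalence")
  check_prob(config$l40_fraction, "l40_fraction")
  check_prob(config$bt_fraction, "bt_fraction")
  check_prob(config$inpatient_claim_prob, "inpatient_claim_prob")
  if (any(config$dosing_interval_days <= 0))
    stop_("invalid simulation config: 'dosing_interval_days' must be positive")
  for (side in c("pre_cost_params", "post_cost_params")) {
    p <- config[[side]]
    if (!setequal(names(p), c("IP", "OP", "RX")))
      stop_("invalid simulation config: '%s' needs entries IP, OP, RX", side)
    for (cat in names(p)) {
      if (p[[cat]][["mean"]] < 0 || p[[cat]][["dispersion"]] < 0)
        stop_("invalid simulation config: '%s' %s mean/dispersion must be >= 0",
              side, cat)
    }
  }
  if (any(config$bt_cost_per_claim < 0))
    stop_("invalid simulation config: 'bt_cost_per_claim' must be >= 0")
  if (config$enrollment_span_days <= 0)
    stop_("invalid simulation config: 'enrollment_span_days' must be positive")
  rng <- config$index_day_range %||%
    c(365L, config$enrollment_span_days - 365L)
  if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 0 ||
      rng[2] > config$enrollment_span_days)
    stop_("invalid simulation config: 'index_day_range' must lie within the enrollment span")
  invisible(config)
}

# Gamma draws with given means and squared CV; dispersion 0 (or zero
# mean) is deterministic. Vectorised over `mean`.
rcost <- function(mean, dispersion) {
  n <- length(mean)
  if (n == 0L) return(numeric())
  if (dispersion <= 0) return(round(mean))
  out <- numeric(n)
  pos <- mean > 0
  out[pos] <- round(stats::rgamma(sum(pos), shape = 1 / dispersion,
                                  scale = mean[pos] * dispersion))
  out
}

# Diagnosis codes drawn from a prefix set, sometimes with an extra digit
# (still matching the prefix).
draw_code <- function(n, prefixes) {
  if (n == 0L) return(character())
  pick <- prefixes[sample.int(length(prefixes), n, replace = TRUE)]
  suffix <- sample(c("", as.character(0:9)), n, replace = TRUE)
  paste0(pick, suffix)
}

#' Generate a synthetic claims bundle with ground truth
#'
#' Simulates the four claims tables plus one ground-truth record per
#' simulated patient-unit (a patient x biologic pair): the true
#' discontinuation day if one occurs inside the observation window, its
#' cause (`"stop"` or `"switch"`, else `"none"`), whether the unit is
#' biologic-naive, and the true 12-month persistence flag (NA when
#' follow-up is shorter than 365 days).
#'
#' Ground-truth convention: the true discontinuation day is the first day
#' of the first 30-day cycle not entered (day `30 * C` after index with
#' `C` geometric), claims stop strictly before it, and a detected
#' gap-discontinuation therefore lands exactly on the true day whenever
#' the dosing interval equals the policy's treatment interval.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `bundle` (a [claims_bundle()]) and
#'   `truth` (a data frame with one row per patient-unit: `patient_id`,
#'   `drug`, `unit_kind` in index/prior/destination, `index_day`,
#'   `true_disc_day`, `true_cause`, `naive`, `true_persistent_12m`).
#' @export
generate_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  with_preserved_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- as.integer(config$n_patients)
  span <- as.integer(config$enrollment_span_days)
  if (n == 0L)
    return(list(bundle = empty_bundle(), truth = empty_truth()))
  drugs <- names(config$drug_mix)
  ivl <- vapply(config$dosing_interval_days, as.integer, integer(1))
  haz <- config$monthly_discontinuation_hazard

  ids <- sprintf("P%05d", seq_len(n))
  age <- as.integer(pmin(74, pmax(18, round(stats::rnorm(n, 47, 12)))))
  sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
  enrollment <- data.frame(patient_id = ids, obs_start = 0L,
                           obs_end = span, age = age, sex = sex,
                           stringsAsFactors = FALSE)

  has_l40 <- stats::runif(n) < config$l40_fraction
  has_bt <- stats::runif(n) < config$bt_fraction
  has_excl <- stats::runif(n) < config$exclusion_prevalence
  prev <- config$comorbidity_prevalence
  comorb <- matrix(stats::runif(n * length(prev)), n) <
    matrix(prev, n, length(prev), byrow = TRUE)
  colnames(comorb) <- names(prev)

  rng <- as.integer(config$index_day_range %||% c(365L, span - 365L))
  drug <- drugs[sample.int(length(drugs), n, replace = TRUE,
                           prob = config$drug_mix)]
  index <- rng[1] + sample.int(rng[2] - rng[1] + 1L, n,
                               replace = TRUE) - 1L
  # experienced units need room for a 300-day prior treatment sequence
  naive <- stats::runif(n) < config$naive_fraction | index < 330L
  h <- unname(haz[drug])
  cycles <- rep(Inf, n)                              # zero hazard: never
  if (any(h > 0))
    cycles[h > 0] <- stats::rgeom(sum(h > 0), h[h > 0]) + 1
  disc_rel <- 30 * cycles                            # true stop day, rel.
  wants_switch <- stats::runif(n) < config$switch_probability

  # prior drug (experienced) and switch destination, all three distinct
  om <- do.call(rbind, lapply(drug, function(d) setdiff(drugs, d)))
  prior_drug <- om[cbind(seq_len(n), sample.int(ncol(om), n, TRUE))]
  prior_drug[naive] <- NA_character_
  dest_drug <- om[cbind(seq_len(n), sample.int(ncol(om), n, TRUE))]
  for (i in which(!naive & dest_drug == prior_drug)) {
    pool <- setdiff(om[i, ], prior_drug[i])
    dest_drug[i] <- pool[sample.int(length(pool), 1L)]
  }
  dest_drug[!wants_switch] <- NA_character_

  bt <- which(has_bt)
  d_iv <- ivl[drug]
  last_sched <- d_iv * (ceiling(disc_rel / d_iv) - 1)   # Inf-safe
  n_claims <- as.integer(pmin(last_sched %/% d_iv,
                              (span - index) %/% d_iv) + 1)

  # index-drug claims
  idx_pid <- rep(ids[bt], n_claims[bt])
  idx_day <- rep(index[bt], n_claims[bt]) +
    rep(d_iv[bt], n_claims[bt]) * (sequence(n_claims[bt]) - 1L)
  idx_class <- rep(drug[bt], n_claims[bt])

  # switches: only when the full pre-discontinuation schedule fits
  last_rel <- d_iv * (n_claims - 1L)
  switch_day <- index + last_rel + d_iv
  switched <- has_bt & wants_switch & last_rel == last_sched &
    switch_day <= span
  sw <- which(switched)
  nd <- integer(n)
  nd[sw] <- (span - switch_day[sw]) %/% ivl[dest_drug[sw]] + 1L
  dst_pid <- rep(ids[sw], nd[sw])
  dst_day <- rep(switch_day[sw], nd[sw]) +
    rep(ivl[dest_drug[sw]], nd[sw]) * (sequence(nd[sw]) - 1L)
  dst_class <- rep(dest_drug[sw], nd[sw])

  # prior sequences for experienced units: 300 days of another biologic
  # ending in a switch into the index drug
  pr <- which(has_bt & !naive)
  np <- integer(n)
  np[pr] <- 299L %/% ivl[prior_drug[pr]] + 1L
  pri_pid <- rep(ids[pr], np[pr])
  pri_day <- rep(index[pr] - 300L, np[pr]) +
    rep(ivl[prior_drug[pr]], np[pr]) * (sequence(np[pr]) - 1L)
  pri_class <- rep(prior_drug[pr], np[pr])

  drug_claims <- data.frame(
    patient_id = c(idx_pid, dst_pid, pri_pid),
    date = c(idx_day, dst_day, pri_day),
    bt_class = c(idx_class, dst_class, pri_class),
    stringsAsFactors = FALSE)
  if (nrow(drug_claims)) {
    inpat <- stats::runif(nrow(drug_claims)) <
      config$inpatient_claim_prob[drug_claims$bt_class]
    drug_claims$setting <- ifelse(inpat, "inpatient", "outpatient")
    drug_claims$drug_code <- paste0(drug_claims$bt_class, "-INJ")
    bt_costs <- data.frame(
      patient_id = drug_claims$patient_id,
      date = drug_claims$date,
      amount_jpy = rcost(unname(
        config$bt_cost_per_claim[drug_claims$bt_class]), 0.25),
      category = ifelse(inpat, "IP", "OP"),
      is_bt_drug_cost = TRUE, stringsAsFactors = FALSE)
  } else {
    drug_claims$setting <- character()
    drug_claims$drug_code <- character()
    bt_costs <- NULL
  }
  drug_claims <- drug_claims[c("patient_id", "date", "drug_code",
                               "bt_class", "setting")]

  # monthly background costs on a 30-day grid anchored at the index date
  # (enrollment start for patients without biologics)
  anchor <- ifelse(has_bt, index, 0L)
  k_min <- as.integer(ceiling((0L - anchor - 15L) / 30))
  k_max <- (span - anchor - 15L) %/% 30L
  m <- k_max - k_min + 1L
  mc_pid <- rep(ids, m)
  mc_day <- rep(anchor, m) + 15L +
    30L * (rep(k_min, m) + sequence(m) - 1L)
  mc_post <- rep(has_bt, m) & mc_day >= rep(anchor, m)
  bg <- lapply(c("IP", "OP", "RX"), function(cat) {
    pre_p <- config$pre_cost_params[[cat]]
    post_p <- config$post_cost_params[[cat]]
    amt <- numeric(length(mc_day))
    amt[!mc_post] <- rcost(rep(pre_p[["mean"]], sum(!mc_post)),
                           pre_p[["dispersion"]])
    amt[mc_post] <- rcost(rep(post_p[["mean"]], sum(mc_post)),
                          post_p[["dispersion"]])
    keep <- which(amt > 0)
    if (!length(keep)) return(NULL)
    data.frame(patient_id = mc_pid[keep], date = mc_day[keep],
               amount_jpy = amt[keep], category = cat,
               is_bt_drug_cost = FALSE, stringsAsFactors = FALSE)
  })
  costs_df <- do.call(rbind, c(list(bt_costs), bg))
  if (is.null(costs_df))
    costs_df <- empty_bundle()$costs
  else if (!nrow(costs_df)) costs_df <- empty_bundle()$costs

  # diagnoses: psoriasis (or decoy dermatitis), exclusion diseases,
  # comorbidities
  excl_prefixes <- c("M05", "M06", "K50", "K51", "M45", "M08")
  cmap <- default_comorbidity_map()
  rand_day <- function(k) sample.int(span + 1L, k, replace = TRUE) - 1L
  dx <- list(data.frame(
    patient_id = ids,
    date = ifelse(has_bt, index, rand_day(n)),
    icd10 = ifelse(has_l40, "L40", "L20"), stringsAsFactors = FALSE))
  ne <- sum(has_excl)
  if (ne)
    dx[[length(dx) + 1L]] <- data.frame(
      patient_id = ids[has_excl], date = rand_day(ne),
      icd10 = draw_code(ne, excl_prefixes), stringsAsFactors = FALSE)
  for (cond in names(prev)) {
    w <- which(comorb[, cond])
    if (!length(w)) next
    prefixes <- cmap[[cond]] %||% cond
    dx[[length(dx) + 1L]] <- data.frame(
      patient_id = ids[w], date = rand_day(length(w)),
      icd10 = draw_code(length(w), prefixes), stringsAsFactors = FALSE)
  }
  diagnoses <- do.call(rbind, dx)

  tidy <- function(df) {
    df <- df[order(df$patient_id, df$date), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  bundle <- claims_bundle(enrollment, tidy(diagnoses), tidy(drug_claims),
                          tidy(costs_df))

  # ground truth, one row per patient-unit
  stop_obs <- !switched & has_bt & (index + disc_rel) <= span
  truth <- rbind(
    truth_rows(ids[bt], drug[bt], "index", index[bt],
               ifelse(switched[bt], switch_day[bt],
                      ifelse(stop_obs[bt], index[bt] + disc_rel[bt],
                             NA_integer_)),
               ifelse(switched[bt], "switch",
                      ifelse(stop_obs[bt], "stop", "none")),
               naive[bt], span),
    truth_rows(ids[sw], dest_drug[sw], "destination", switch_day[sw],
               NA_integer_, "none", FALSE, span),
    truth_rows(ids[pr], prior_drug[pr], "prior", index[pr] - 300L,
               index[pr], "switch", TRUE, span)
  )
  if (is.null(truth) || !nrow(truth)) truth <- empty_truth()
  truth <- truth[order(truth$patient_id, truth$index_day), , drop = FALSE]
  rownames(truth) <- NULL
  list(bundle = bundle, truth = truth)
}

truth_rows <- function(id, drug, kind, index_day, disc_day, cause,
                       naive, span) {
  k <- length(id)
  if (!k) return(NULL)
  index_day <- as.integer(index_day)
  disc_day <- as.integer(disc_day)
  fu <- span - index_day
  persistent <- ifelse(fu < 365L, NA,
                       is.na(disc_day) | (disc_day - index_day) >= 365L)
  data.frame(patient_id = id, drug = drug, unit_kind = kind,
             index_day = index_day, true_disc_day = disc_day,
             true_cause = cause, naive = rep_len(naive, k),
             true_persistent_12m = persistent, stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(patient_id = character(), drug = character(),
             unit_kind = character(), index_day = integer(),
             true_disc_day = integer(), true_cause = character(),
             naive = logical(), true_persistent_12m = logical(),
             stringsAsFactors = FALSE)
}
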
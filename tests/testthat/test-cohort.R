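# Hand-built four-table bundle for targeted cohort-rule checks.
tiny_bundle <- function(diagnoses, drug_claims,
                        patients = unique(c(diagnoses$patient_id,
                                            drug_claims$patient_id))) {
  claims_bundle(
    enrollment = data.frame(patient_id = patients, obs_start = 0L,
                            obs_end = 1500L, age = 50L, sex = "F",
                            stringsAsFactors = FALSE),
    diagnoses = diagnoses,
    drug_claims = drug_claims,
    costs = empty_bundle()$costs)
}

dx <- function(id, day, code)
  data.frame(patient_id = id, date = as.integer(day), icd10 = code,
             stringsAsFactors = FALSE)

claim <- function(id, day, drug)
  data.frame(patient_id = id, date = as.integer(day),
             drug_code = paste0(drug, "-INJ"), bt_class = drug,
             setting = "outpatient", stringsAsFactors = FALSE)

test_that("selection requires both the inclusion diagnosis and a biologic claim", {
  b <- tiny_bundle(
    rbind(dx("A", 10, "L40"),          # L40 but no biologic
          dx("B", 10, "L20"),          # biologic but no L40
          dx("C", 10, "L405")),        # prefix match + biologic
    rbind(claim("B", 400, "UST"), claim("C", 400, "ADL")))
  got <- select_psoriasis_bt_patients(b)
  expect_identical(as.character(got), "C")
  casc <- attr(got, "cascade")
  expect_identical(casc$count[casc$stage == "dx_and_bt_patients"], 1L)
})

test_that("exclusion diagnoses remove patients; none present is the identity", {
  b <- tiny_bundle(
    rbind(dx("A", 10, "L40"), dx("A", 900, "M05"),   # RA at any time
          dx("B", 10, "L40")),
    rbind(claim("A", 400, "UST"), claim("B", 400, "UST")))
  kept <- apply_exclusions(c("A", "B"), b)
  expect_identical(as.character(kept), "B")
  b2 <- tiny_bundle(dx("B", 10, "L40"), claim("B", 400, "UST"))
  expect_identical(as.character(apply_exclusions("B", b2)), "B")
})

test_that("selection and exclusion counts match direct recounts on synthetic data", {
  sim <- generate_cohort(simulation_config(n_patients = 200, seed = 17))
  b <- sim$bundle
  got <- select_psoriasis_bt_patients(b)
  want <- intersect(
    unique(b$diagnoses$patient_id[startsWith(b$diagnoses$icd10, "L40")]),
    unique(b$drug_claims$patient_id))
  expect_setequal(as.character(got), want)

  kept <- apply_exclusions(got, b)
  excl <- unique(b$diagnoses$patient_id[
    grepl("^(M05|M06|K50|K51|M45|M08)", b$diagnoses$icd10)])
  expect_setequal(as.character(kept), setdiff(want, excl))
})

test_that("one unit per (patient, drug), indexed at that drug's first claim", {
  b <- tiny_bundle(
    dx("A", 10, "L40"),
    rbind(claim("A", 400, "ADL"), claim("A", 430, "ADL"),
          claim("A", 500, "UST")))
  units <- build_patient_units("A", b)
  expect_identical(nrow(units), 2L)
  expect_setequal(units$drug, c("ADL", "UST"))
  expect_identical(units$index_day[units$drug == "ADL"], 400L)
  expect_identical(units$index_day[units$drug == "UST"], 500L)

  # synthetic recount: units = distinct (patient, drug) pairs
  sim <- generate_cohort(simulation_config(n_patients = 150, seed = 23))
  pts <- unique(sim$bundle$drug_claims$patient_id)
  units2 <- build_patient_units(pts, sim$bundle)
  pairs <- unique(sim$bundle$drug_claims[c("patient_id", "bt_class")])
  expect_identical(nrow(units2), nrow(pairs))
  expect_gt(nrow(units2), length(pts))  # switching creates extra units

  bad <- b
  bad$drug_claims$bt_class[1] <- "XYZ"
  expect_error(build_patient_units("A", bad), "XYZ")
})

test_that("naive classification uses the closed 365-day look-back window", {
  mk <- function(prior_day) tiny_bundle(
    dx("A", 10, "L40"),
    rbind(claim("A", prior_day, "ADL"), claim("A", 800, "UST")))
  naive_flag <- function(b) {
    u <- build_patient_units("A", b)
    u <- classify_naive(u, b)
    u$naive[u$drug == "UST"]
  }
  expect_false(naive_flag(mk(700)))        # claim 100 days before index
  expect_false(naive_flag(mk(800 - 365)))  # boundary day inside window
  expect_true(naive_flag(mk(800 - 366)))   # one day outside
})

test_that("naive status needs an observable look-back year", {
  b <- tiny_bundle(dx("A", 10, "L40"), claim("A", 100, "UST"))
  u <- build_patient_units("A", b)
  expect_false(classify_naive(u, b)$naive)  # index too close to obs_start
  expect_true(classify_naive(u, b, unknown_as = "naive")$naive)
})

test_that("cost-population selection keeps exactly the 24-month-window units", {
  b <- tiny_bundle(dx("A", 10, "L40"),
                   rbind(claim("A", 100, "UST"),    # index at day 100
                         claim("A", 800, "ADL")))   # index +- 400 inside
  u <- build_patient_units("A", b)
  kept <- select_cost_population(u)
  expect_identical(kept$drug, "ADL")

  sim <- generate_cohort(simulation_config(
    n_patients = 200, index_day_range = c(90L, 1300L), seed = 41))
  units <- build_patient_units(unique(sim$bundle$drug_claims$patient_id),
                               sim$bundle)
  kept2 <- select_cost_population(units)
  want <- units$index_day - units$obs_start >= 365 &
    units$obs_end - units$index_day >= 365
  expect_identical(kept2$unit_id, units$unit_id[want])
})

test_that("comorbidity flags match their codes and configured prevalence", {
  b <- tiny_bundle(rbind(dx("A", 10, "L40"), dx("A", 20, "I10"),
                         dx("B", 10, "L40")),
                   rbind(claim("A", 400, "UST"), claim("B", 400, "UST")))
  u <- build_patient_units(c("A", "B"), b)
  fl <- comorbidity_flags(u, b)
  expect_true(fl$hypertension[fl$unit_id == "A:UST"])
  expect_false(any(unlist(fl[fl$unit_id == "B:UST",
                             setdiff(names(fl), "unit_id")])))

  prev <- 0.25
  cfg <- simulation_config(
    n_patients = 2000, seed = 12,
    comorbidity_prevalence = c(obesity = 0, diabetes_uncomplicated = 0,
                               diabetes_complicated = 0,
                               hypertension = prev, hyperlipidemia = 0,
                               old_mi = 0, heart_failure = 0),
    pre_cost_params = zero_costs, post_cost_params = zero_costs,
    bt_cost_per_claim = c(ADL = 0, IFX = 0, SCK = 0, UST = 0))
  sim <- generate_cohort(cfg)
  units <- build_patient_units(unique(sim$bundle$drug_claims$patient_id),
                               sim$bundle)
  fl2 <- comorbidity_flags(units, sim$bundle)
  # one flag per patient to keep draws independent
  first <- !duplicated(units$patient_id)
  p_hat <- mean(fl2$hypertension[first])
  expect_lt(abs(p_hat - prev), 3 * sqrt(prev * (1 - prev) / sum(first)))
})

test_that("each cascade stage is a subset of its predecessor", {
  sim <- generate_cohort(simulation_config(n_patients = 300, seed = 55))
  pts <- select_psoriasis_bt_patients(sim$bundle)
  kept <- apply_exclusions(pts, sim$bundle)
  expect_true(all(kept %in% pts))
  units <- classify_naive(build_patient_units(kept, sim$bundle),
                          sim$bundle)
  expect_true(all(units$patient_id %in% kept))
  cost_units <- select_cost_population(units)
  expect_true(all(cost_units$unit_id %in% units$unit_id))
  # units partition into naive + experienced
  expect_identical(sum(units$naive) + sum(!units$naive), nrow(units))
  # every unit's index is <= all claims of its drug for that patient
  dc <- sim$bundle$drug_claims
  for (k in sample(nrow(units), min(50, nrow(units))))
    expect_true(all(dc$date[dc$patient_id == units$patient_id[k] &
                              dc$bt_class == units$drug[k]] >=
                      units$index_day[k]))
})
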
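# Independent oracles and fixture builders shared across test files.

# Day-by-day treatment-episode oracle: walk every observed day, keep the
# date of the most recent index-drug claim, and stop at the first day the
# claim-free span exceeds the non-refill period (gap) or at the first
# other-biologic claim that precedes a completed gap (switch).
oracle_episode <- function(index_day, obs_end, idx_days, other_days,
                           ti, gap, switch_on_tie = TRUE) {
  non_refill <- ti + gap
  idx <- sort(unique(idx_days[idx_days >= index_day &
                                idx_days <= obs_end]))
  others <- other_days[other_days >= index_day & other_days <= obs_end]
  if (!switch_on_tie) others <- setdiff(others, idx)
  is_idx <- logical(obs_end - index_day + 1L)
  is_idx[idx - index_day + 1L] <- TRUE
  is_other <- logical(obs_end - index_day + 1L)
  is_other[unique(others) - index_day + 1L] <- TRUE
  last <- index_day
  for (d in index_day:obs_end) {
    # a claim-free run longer than the non-refill period has completed
    # by yesterday: today's claims arrive too late to mend it
    if (d - last > non_refill)
      return(list(status = "gap_discontinued",
                  end_day = last + ti - index_day))
    if (is_other[d - index_day + 1L])
      return(list(status = "switch_discontinued",
                  end_day = d - index_day))
    if (is_idx[d - index_day + 1L]) last <- d
  }
  list(status = "censored", end_day = obs_end - index_day)
}

# Brute-force weighted hypergeometric sums over the pooled event times,
# written as explicit 2x2-table counting (independent code path from
# two_sample_test's risk-set arithmetic).
oracle_two_sample <- function(a, b, weight = c("log-rank", "wilcoxon")) {
  weight <- match.arg(weight)
  df <- rbind(data.frame(time = a$time, event = as.logical(a$event), g = 1L),
              data.frame(time = b$time, event = as.logical(b$event), g = 2L))
  tev <- sort(unique(df$time[df$event]))
  U <- 0; V <- 0
  for (t in tev) {
    risk <- df[df$time >= t, , drop = FALSE]
    n <- nrow(risk); n1 <- sum(risk$g == 1L)
    dd <- df[df$time == t & df$event, , drop = FALSE]
    d <- nrow(dd); d1 <- sum(dd$g == 1L)
    E <- d * n1 / n
    Vt <- if (n > 1) d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1)) else 0
    w <- if (weight == "wilcoxon") n else 1
    U <- U + w * (d1 - E)
    V <- V + w^2 * Vt
  }
  stat <- if (V > 0) U^2 / V else 0
  list(statistic = stat,
       p.value = if (V > 0) stats::pchisq(stat, 1, lower.tail = FALSE)
                 else 1)
}

# Randomised small claim sequence for episode-oracle equivalence tests.
rand_claim_case <- function(ti) {
  obs_end <- sample(120:500, 1)
  n_claims <- sample(1:8, 1)
  gaps <- sample(c(ti, ti, ti + sample(0:40, 3, TRUE),
                   ti + sample(60:250, 2, TRUE)), n_claims - 1,
                 replace = TRUE)
  idx <- cumsum(c(0, gaps))
  idx <- idx[idx <= obs_end]
  others <- if (stats::runif(1) < 0.5)
    sample(0:obs_end, sample(1:3, 1)) else numeric(0)
  list(obs_end = obs_end, idx = idx, others = others)
}

# Cost-free simulation settings for statistical checks where monetary
# records are irrelevant.
zero_costs <- list(IP = c(mean = 0, dispersion = 0),
                   OP = c(mean = 0, dispersion = 0),
                   RX = c(mean = 0, dispersion = 0))

one_drug_mix <- function(drug) {
  m <- c(ADL = 0, IFX = 0, SCK = 0, UST = 0)
  m[drug] <- 1
  m
}

flat_hazard <- function(h) c(ADL = h, IFX = h, SCK = h, UST = h)

# Minimal single-drug cohort config with clean follow-up, used by the
# survival-recovery and calibration tests.
clean_cohort_config <- function(n, drug, hazard, seed,
                                switch_probability = 0,
                                drug_mix = one_drug_mix(drug)) {
  simulation_config(
    n_patients = n, drug_mix = drug_mix,
    monthly_discontinuation_hazard = flat_hazard(hazard),
    switch_probability = switch_probability,
    naive_fraction = 1, exclusion_prevalence = 0,
    l40_fraction = 1, bt_fraction = 1,
    index_day_range = c(365L, 900L),
    pre_cost_params = zero_costs, post_cost_params = zero_costs,
    bt_cost_per_claim = c(ADL = 0, IFX = 0, SCK = 0, UST = 0),
    seed = seed)
}

# Units + episodes straight from a generated bundle (no diagnosis-based
# filtering), for tests that target the episode/survival machinery.
units_and_episodes <- function(sim, policy = default_gap_policy()) {
  units <- build_patient_units(unique(sim$bundle$drug_claims$patient_id),
                               sim$bundle)
  units <- classify_naive(units, sim$bundle)
  list(units = units,
       episodes = build_episodes(units, sim$bundle$drug_claims, policy))
}

truth_key <- function(truth) paste(truth$patient_id, truth$drug, sep = ":")
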
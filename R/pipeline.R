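#' Demographics table by drug and naive status
#'
#' Unit counts, mean age and percent female per drug (plus a cross-drug
#' subtotal), for the total population and the naive / experienced
#' strata. Naive and experienced counts partition the total.
#'
#' @param units unit table carrying a `naive` column.
#' @return Data frame: `population` (`total` / `naive` /
#'   `experienced`), `drug`, `n`, `mean_age`, `pct_female`.
#' @export
demographics_table <- function(units) {
  if (is.null(units$naive))
    stop_("units must carry a 'naive' column; run classify_naive() first")
  drugs <- c(sort(unique(units$drug)), "subtotal")
  rows <- list()
  for (population in c("total", "naive", "experienced")) {
    base <- switch(population,
                   total = units,
                   naive = units[units$naive, , drop = FALSE],
                   experienced = units[!units$naive, , drop = FALSE])
    for (d in drugs) {
      dd <- if (d == "subtotal") base else
        base[base$drug == d, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        population = population, drug = d, n = nrow(dd),
        mean_age = if (nrow(dd)) mean(dd$age) else NA_real_,
        pct_female = if (nrow(dd)) 100 * mean(dd$sex == "F")
                     else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Comorbidity prevalence table by drug
#'
#' Counts and percentages of units whose patient carries each
#' comorbidity, per drug plus a cross-drug subtotal.
#'
#' @inheritParams comorbidity_flags
#' @return Data frame: `condition`, `drug`, `n`, `n_flagged`, `pct`.
#' @export
comorbidity_table <- function(units, bundle,
                              codes = default_code_policy()) {
  flags <- comorbidity_flags(units, bundle, codes)
  drugs <- c(sort(unique(units$drug)), "subtotal")
  conds <- setdiff(names(flags), "unit_id")
  rows <- list()
  for (cond in conds) {
    for (d in drugs) {
      sel <- if (d == "subtotal") rep(TRUE, nrow(units)) else
        units$drug == d
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, drug = d, n = sum(sel),
        n_flagged = sum(flags[[cond]][sel]),
        pct = if (sum(sel)) 100 * mean(flags[[cond]][sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Persistence rate table with confidence bands and pairwise tests
#'
#' Kaplan-Meier persistence rates at the requested horizons per drug and
#' population (total and naive), with Greenwood 95% intervals (or an
#' explicit unavailability marker) and unadjusted pairwise log-rank /
#' Wilcoxon p-values against a reference drug. Every (drug, horizon)
#' cell carries either an interval or `ci_available = FALSE`, never
#' silence.
#'
#' @param units unit table carrying a `naive` column.
#' @param episodes episodes for those units from [build_episodes()].
#' @param horizons read-out times in days.
#' @param reference reference drug for the pairwise tests.
#' @return Data frame: `population`, `drug`, `horizon_days`, `n`,
#'   `rate_pct`, `ci_halfwidth_pct`, `ci_available`, `logrank_p`,
#'   `wilcoxon_p` (p-values NA for the reference drug itself).
#' @export
persistence_table <- function(units, episodes,
                              horizons = c(365L, 730L),
                              reference = "UST") {
  if (is.null(units$naive))
    stop_("units must carry a 'naive' column; run classify_naive() first")
  ep <- episodes[match(units$unit_id, episodes$unit_id), , drop = FALSE]
  samples_all <- data.frame(time = ep$end_day,
                            event = ep$status != "censored",
                            group = ep$drug, stringsAsFactors = FALSE)
  rows <- list()
  for (population in c("total", "naive")) {
    sel <- if (population == "naive") units$naive else
      rep(TRUE, nrow(units))
    samples <- samples_all[sel, , drop = FALSE]
    if (!nrow(samples)) next
    pw <- if (reference %in% samples$group &&
              length(unique(samples$group)) > 1L)
      pairwise_vs_reference(samples, reference) else NULL
    for (d in sort(unique(samples$group))) {
      s <- samples[samples$group == d, , drop = FALSE]
      fit <- km_estimate(s$time, s$event)
      at <- survival_at(fit, horizons)
      j <- if (!is.null(pw)) match(d, pw$group) else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        population = population, drug = d, horizon_days = horizons,
        n = nrow(s),
        rate_pct = 100 * at$estimate,
        ci_halfwidth_pct = ifelse(at$ci_available,
                                  100 * (at$estimate - at$lower), NA_real_),
        ci_available = at$ci_available,
        logrank_p = if (!is.na(j)) pw$logrank_p[j] else NA_real_,
        wilcoxon_p = if (!is.na(j)) pw$wilcoxon_p[j] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(), drug = character(),
               horizon_days = integer(), n = integer(),
               rate_pct = numeric(), ci_halfwidth_pct = numeric(),
               ci_available = logical(), logrank_p = numeric(),
               wilcoxon_p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the input mode (synthetic
#' generation or four CSV files on disk), the code and gap policies, the
#' sensitivity gaps, the analysis horizons and the output directory.
#'
#' @param input either a [simulation_config()] (synthetic mode) or a
#'   directory path holding a bundle written by [write_bundle()] (file
#'   mode).
#' @param codes a [code_policy()].
#' @param policy the base-case [gap_policy()].
#' @param sensitivity_gaps named integer vector of medication gaps for
#'   the sensitivity grid.
#' @param horizons persistence read-out times in days, ascending.
#' @param reference reference drug for pairwise tests.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed controlling every random draw (synthetic
#'   mode).
#' @param make_plots write persistence-curve PNGs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = simulation_config(),
                            codes = default_code_policy(),
                            policy = default_gap_policy(),
                            sensitivity_gaps = c(base = 60L, SA1 = 30L,
                                                 SA2 = 90L),
                            horizons = c(365L, 730L),
                            reference = "UST",
                            out_dir = tempfile("persistkit-report-"),
                            seed = 1L,
                            make_plots = TRUE) {
  if (any(horizons <= 0) || is.unsorted(horizons, strictly = TRUE))
    stop_("horizons must be positive and strictly ascending")
  mode <- if (inherits(input, "simulation_config")) "synthetic"
          else if (is.character(input) && length(input) == 1L) "files"
          else stop_("input must be a simulation_config or a directory path")
  structure(list(mode = mode, input = input, codes = codes,
                 policy = policy, sensitivity_gaps = sensitivity_gaps,
                 horizons = horizons, reference = reference,
                 out_dir = out_dir, seed = seed,
                 make_plots = make_plots),
            class = "pipeline_config")
}

#' Run the full claims-to-report pipeline
#'
#' Obtains a claims bundle (generating it in synthetic mode, reading it
#' in file mode), runs cohort selection, episode construction,
#' persistence estimation, the gap-sensitivity grid and the cost
#' analysis, and writes the report bundle: `cascade.csv`,
#' `table1_demographics.csv`, `table2_comorbidities.csv`,
#' `table3_persistence.csv`, `table4_costs_all.csv`,
#' `table5_costs_persistent.csv`, `table6_costs_nonpersistent.csv`,
#' `table7_cost_contrast.csv`, `sensitivity_grid.csv`,
#' `episodes.csv`, persistence-curve PNGs and `run_log.txt` (seed and
#' config hash). Outputs are deterministic given config and seed. Cost
#' tables are reported in thousand JPY, rounded at report time.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the computed tables (`cascade`,
#'   `units`, `episodes`, `demographics`, `comorbidities`,
#'   `persistence`, `costs_all`, `costs_persistent`,
#'   `costs_non_persistent`, `cost_contrast`, `sensitivity`) and the
#'   output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop_("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (config$mode == "synthetic") {
    sim_cfg <- config$input
    sim_cfg$seed <- config$seed
    bundle <- generate_cohort(sim_cfg)$bundle
  } else {
    bundle <- read_bundle(config$input)
  }

  patients <- select_psoriasis_bt_patients(bundle, config$codes)
  patients <- apply_exclusions(patients, bundle, config$codes)
  units <- build_patient_units(patients, bundle,
                               drugs = config$policy$drug)
  units <- classify_naive(units, bundle)
  cost_units <- select_cost_population(units)
  cascade <- rbind(
    attr(patients, "cascade"),
    data.frame(stage = c("patient_units", "naive_units",
                         "cost_population_units"),
               count = c(nrow(units), sum(units$naive),
                         nrow(cost_units)), stringsAsFactors = FALSE))

  episodes <- build_episodes(units, bundle$drug_claims, config$policy)
  demographics <- demographics_table(units)
  comorbidities <- comorbidity_table(units, bundle, config$codes)
  persistence <- persistence_table(units, episodes, config$horizons,
                                   config$reference)
  sensitivity <- if (nrow(cost_units))
    sensitivity_grid(cost_units, bundle$drug_claims,
                     sensitivity_policies(
                       config$sensitivity_gaps,
                       stats::setNames(config$policy$treatment_interval_days,
                                       config$policy$drug)))
  else data.frame(policy = character(), medication_gap_days = integer(),
                  drug = character(), n = integer(),
                  n_persistent = integer(), proportion = numeric(),
                  stringsAsFactors = FALSE)

  empty_costs <- data.frame(
    population = character(), drug = character(), group = character(),
    n = integer(), stringsAsFactors = FALSE)
  if (nrow(cost_units)) {
    summaries <- window_costs(cost_units, bundle$costs)
    cost_eps <- episodes[match(cost_units$unit_id, episodes$unit_id), ,
                         drop = FALSE]
    costs_all <- cost_summary_by_drug(cost_units, summaries)
    contrast <- contrast_by_persistence(cost_units, cost_eps, summaries)
    costs_p <- contrast[contrast$group == "persistent", , drop = FALSE]
    costs_np <- contrast[contrast$group == "non_persistent", ,
                         drop = FALSE]
  } else {
    summaries <- NULL
    costs_all <- contrast <- costs_p <- costs_np <- empty_costs
  }

  in_thousands <- function(df) {
    for (cm in grep("^(pre|inc|post)_", names(df), value = TRUE))
      df[[cm]] <- to_thousand_jpy(df[[cm]])
    df
  }
  outputs <- list(
    cascade.csv = cascade,
    table1_demographics.csv = demographics,
    table2_comorbidities.csv = comorbidities,
    table3_persistence.csv = persistence,
    table4_costs_all.csv = in_thousands(costs_all),
    table5_costs_persistent.csv = in_thousands(costs_p),
    table6_costs_nonpersistent.csv = in_thousands(costs_np),
    table7_cost_contrast.csv = in_thousands(contrast),
    sensitivity_grid.csv = sensitivity,
    episodes.csv = episodes)
  paths <- character()
  for (nm in names(outputs)) {
    p <- file.path(config$out_dir, nm)
    utils::write.csv(outputs[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }

  if (config$make_plots && nrow(episodes)) {
    for (population in c("total", "naive")) {
      sel <- if (population == "naive") units$naive else
        rep(TRUE, nrow(units))
      ep <- episodes[sel, , drop = FALSE]
      if (!nrow(ep)) next
      p <- file.path(config$out_dir,
                     sprintf("km_%s.png", population))
      grDevices::png(p, width = 800, height = 600)
      plot_km_curves(data.frame(time = ep$end_day,
                                event = ep$status != "censored",
                                group = ep$drug),
                     main = sprintf("Persistence, %s population",
                                    population))
      grDevices::dev.off()
      paths[basename(p)] <- p
    }
  }

  log_path <- file.path(config$out_dir, "run_log.txt")
  hashable <- config[setdiff(names(config), "out_dir")]
  writeLines(c(
    sprintf("seed: %d", config$seed),
    sprintf("mode: %s", config$mode),
    sprintf("config_hash: %s", rlang::hash(hashable)),
    sprintf("stages: %s",
            paste(sprintf("%s=%d", cascade$stage, cascade$count),
                  collapse = ", "))),
    log_path)
  paths["run_log.txt"] <- log_path

  invisible(list(cascade = cascade, units = units, episodes = episodes,
                 demographics = demographics,
                 comorbidities = comorbidities,
                 persistence = persistence, costs_all = costs_all,
                 costs_persistent = costs_p,
                 costs_non_persistent = costs_np,
                 cost_contrast = contrast, sensitivity = sensitivity,
                 summaries = summaries, cost_units = cost_units,
                 paths = paths))
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts a file with optional blocks `simulation` (fields of
#' [simulation_config()]), `codes` (fields of [code_policy()]),
#' `policy` (`treatment_interval_days`, `medication_gap_days`) and the
#' scalar fields `input_dir`, `sensitivity_gaps`, `horizons`,
#' `reference`, `out_dir`, `seed`, `make_plots`. `input_dir` selects
#' file mode; otherwise the `simulation` block (or its defaults)
#' selects synthetic mode.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$input_dir)) y$input_dir else {
    sim <- y$simulation %||% list()
    if (!is.null(sim$drug_mix)) sim$drug_mix <- unlist(sim$drug_mix)
    if (!is.null(sim$monthly_discontinuation_hazard))
      sim$monthly_discontinuation_hazard <-
        unlist(sim$monthly_discontinuation_hazard)
    if (!is.null(sim$dosing_interval_days))
      sim$dosing_interval_days <- unlist(sim$dosing_interval_days)
    if (!is.null(sim$comorbidity_prevalence))
      sim$comorbidity_prevalence <- unlist(sim$comorbidity_prevalence)
    do.call(simulation_config, sim)
  }
  codes <- if (is.null(y$codes)) default_code_policy() else {
    ca <- list()
    if (!is.null(y$codes$inclusion_codes))
      ca$inclusion_codes <- unlist(y$codes$inclusion_codes)
    if (!is.null(y$codes$exclusion_codes))
      ca$exclusion_codes <- unlist(y$codes$exclusion_codes)
    if (!is.null(y$codes$comorbidity_code_map))
      ca$comorbidity_code_map <- lapply(y$codes$comorbidity_code_map,
                                        unlist)
    do.call(code_policy, ca)
  }
  policy <- if (is.null(y$policy)) default_gap_policy() else
    gap_policy(unlist(y$policy$treatment_interval_days),
               y$policy$medication_gap_days %||% 60L)
  args <- list(input = input, codes = codes, policy = policy)
  if (!is.null(y$sensitivity_gaps))
    args$sensitivity_gaps <- unlist(y$sensitivity_gaps)
  for (f in c("horizons", "reference", "out_dir", "seed", "make_plots"))
    if (!is.null(y[[f]])) args[[f]] <- if (f == "horizons")
      as.integer(unlist(y[[f]])) else y[[f]]
  do.call(pipeline_config, args)
}
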
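cost_row <- function(id, day, amount, category, is_bt = FALSE)
  data.frame(patient_id = id, date = as.integer(day),
             amount_jpy = amount, category = category,
             is_bt_drug_cost = is_bt, stringsAsFactors = FALSE)

unit_row <- function(id = "A", drug = "UST", index = 500L,
                     obs_end = 1500L, naive = TRUE)
  data.frame(unit_id = paste(id, drug, sep = ":"), patient_id = id,
             drug = drug, index_day = index, obs_start = 0L,
             obs_end = obs_end, age = 50L, sex = "F", naive = naive,
             stringsAsFactors = FALSE)

test_that("windows split at the index day and categorise amounts correctly", {
  u <- unit_row()
  costs <- rbind(
    cost_row("A", 500, 200000, "OP", is_bt = TRUE),  # index day -> post
    cost_row("A", 499, 1000, "OP"),                  # last pre day
    cost_row("A", 135, 500, "IP"),                   # first pre day
    cost_row("A", 134, 99999, "IP"),                 # outside both windows
    cost_row("A", 864, 700, "RX"),                   # last post day
    cost_row("A", 865, 88888, "RX"),                 # outside
    cost_row("A", 600, 300, "RX", is_bt = TRUE))     # biologic RX excluded
  wc <- window_costs(u, costs)
  pre <- wc[wc$window == "pre", ]
  post <- wc[wc$window == "post", ]
  expect_equal(pre$ip, 500)
  expect_equal(pre$op, 1000)
  expect_equal(pre$rx_nonbt, 0)
  expect_equal(pre$total, 1500)
  expect_equal(post$op, 200000)
  expect_equal(post$rx_nonbt, 700)
  expect_equal(post$total, 200700)
})

test_that("a unit without cost records sums to zero in both windows", {
  wc <- window_costs(unit_row(), empty_bundle()$costs)
  expect_equal(wc$total, c(0, 0))
  expect_equal(wc$ip + wc$op + wc$rx_nonbt, wc$total)
})

test_that("a unit without the 24-month window is a precondition error", {
  expect_error(window_costs(unit_row(index = 100L), empty_bundle()$costs),
               "24-month")
})

test_that("window sums equal an independent recount on synthetic data", {
  sim <- generate_cohort(simulation_config(n_patients = 80, seed = 44))
  units <- classify_naive(
    build_patient_units(unique(sim$bundle$drug_claims$patient_id),
                        sim$bundle), sim$bundle)
  units <- select_cost_population(units)
  wc <- window_costs(units, sim$bundle$costs)
  cs <- sim$bundle$costs
  for (k in sample(nrow(units), min(25, nrow(units)))) {
    u <- units[k, ]
    for (w in c("pre", "post")) {
      lo <- if (w == "pre") u$index_day - 365 else u$index_day
      hi <- if (w == "pre") u$index_day - 1 else u$index_day + 364
      sel <- cs$patient_id == u$patient_id & cs$date >= lo & cs$date <= hi
      row <- wc[wc$unit_id == u$unit_id & wc$window == w, ]
      expect_equal(row$ip, sum(cs$amount_jpy[sel & cs$category == "IP"]))
      expect_equal(row$op, sum(cs$amount_jpy[sel & cs$category == "OP"]))
      expect_equal(row$rx_nonbt,
                   sum(cs$amount_jpy[sel & cs$category == "RX" &
                                       !cs$is_bt_drug_cost]))
      expect_equal(row$total, row$ip + row$op + row$rx_nonbt)
    }
  }
  # deterministic monthly emissions: 12 records per category per window
  cfg0 <- simulation_config(
    n_patients = 20, seed = 9, switch_probability = 0,
    naive_fraction = 1, bt_fraction = 1, exclusion_prevalence = 0,
    pre_cost_params = list(IP = c(mean = 1000, dispersion = 0),
                           OP = c(mean = 2000, dispersion = 0),
                           RX = c(mean = 3000, dispersion = 0)),
    post_cost_params = list(IP = c(mean = 1500, dispersion = 0),
                            OP = c(mean = 2500, dispersion = 0),
                            RX = c(mean = 3500, dispersion = 0)),
    bt_cost_per_claim = c(ADL = 0, IFX = 0, SCK = 0, UST = 0))
  sim0 <- generate_cohort(cfg0)
  units0 <- select_cost_population(classify_naive(
    build_patient_units(unique(sim0$bundle$drug_claims$patient_id),
                        sim0$bundle), sim0$bundle))
  wc0 <- window_costs(units0, sim0$bundle$costs)
  expect_true(all(wc0$ip[wc0$window == "pre"] == 12 * 1000))
  expect_true(all(wc0$op[wc0$window == "post"] == 12 * 2500))
  expect_true(all(wc0$rx_nonbt[wc0$window == "pre"] == 12 * 3000))
})

test_that("cost increases subtract componentwise and police unit mismatches", {
  u <- unit_row()
  wc <- window_costs(u, rbind(cost_row("A", 400, 100, "OP"),
                              cost_row("A", 600, 250, "OP")))
  pre <- wc[wc$window == "pre", ]
  post <- wc[wc$window == "post", ]
  inc <- cost_increase(pre, post)
  expect_equal(inc$op, 150)
  expect_equal(inc$total, 150)
  same <- cost_increase(pre, pre)
  expect_true(all(same[c("ip", "op", "rx_nonbt", "total")] == 0))
  post_bad <- post
  post_bad$unit_id <- "B:UST"
  expect_error(cost_increase(pre, post_bad), "same units")
})

test_that("persistence contrasts stratify, subtotal and difference correctly", {
  units <- rbind(unit_row("A", "UST"), unit_row("B", "UST"),
                 unit_row("C", "ADL", naive = FALSE))
  episodes <- data.frame(
    unit_id = units$unit_id, drug = units$drug, index_day = 500L,
    status = c("censored", "gap_discontinued", "censored"),
    end_day = c(1000L, 90L, 1000L),
    persistent_12m = c(TRUE, FALSE, TRUE),
    persistent_24m = NA, stringsAsFactors = FALSE)
  costs <- rbind(cost_row("A", 400, 1000, "OP"),
                 cost_row("A", 600, 3000, "OP"),
                 cost_row("B", 400, 2000, "OP"),
                 cost_row("B", 600, 1000, "OP"),
                 cost_row("C", 600, 5000, "IP"))
  summaries <- window_costs(units, costs)
  con <- contrast_by_persistence(units, episodes, summaries)

  pick <- function(population, drug, group)
    con[con$population == population & con$drug == drug &
          con$group == group, ]
  expect_equal(pick("total", "UST", "persistent")$inc_op, 2000)
  expect_equal(pick("total", "UST", "non_persistent")$inc_op, -1000)
  expect_equal(pick("total", "UST", "difference")$inc_op, -3000)
  # naive population excludes the experienced ADL unit
  expect_identical(pick("naive", "ADL", "persistent")$n, 0L)
  expect_true(is.na(pick("naive", "ADL", "persistent")$inc_ip))
  expect_equal(pick("total", "subtotal", "persistent")$inc_ip,
               mean(c(0, 5000)))
  # group counts partition the population
  expect_identical(pick("total", "subtotal", "persistent")$n +
                     pick("total", "subtotal", "non_persistent")$n,
                   nrow(units))
})

test_that("persistence-independent costs give a near-zero cost-increase difference", {
  cfg <- simulation_config(
    n_patients = 1200, seed = 71, switch_probability = 0,
    naive_fraction = 1, bt_fraction = 1, exclusion_prevalence = 0,
    l40_fraction = 1, index_day_range = c(365L, 900L),
    monthly_discontinuation_hazard = flat_hazard(0.05),
    pre_cost_params = list(IP = c(mean = 20000, dispersion = 1),
                           OP = c(mean = 20000, dispersion = 1),
                           RX = c(mean = 20000, dispersion = 1)),
    post_cost_params = list(IP = c(mean = 60000, dispersion = 1),
                            OP = c(mean = 60000, dispersion = 1),
                            RX = c(mean = 60000, dispersion = 1)),
    bt_cost_per_claim = c(ADL = 0, IFX = 0, SCK = 0, UST = 0))
  sim <- generate_cohort(cfg)
  units <- select_cost_population(classify_naive(
    build_patient_units(unique(sim$bundle$drug_claims$patient_id),
                        sim$bundle), sim$bundle))
  episodes <- build_episodes(units, sim$bundle$drug_claims)
  summaries <- window_costs(units, sim$bundle$costs)
  con <- contrast_by_persistence(units, episodes, summaries)
  diff_total <- con$inc_total[con$population == "total" &
                                con$drug == "subtotal" &
                                con$group == "difference"]
  # Monte-Carlo scale: yearly total sd ~ sqrt(3*12)*60000; two groups
  mc_se <- sqrt(36) * 60000 * sqrt(4 / nrow(units))
  expect_lt(abs(diff_total), 3 * mc_se)
})

test_that("published reference tables are internally additive to the printed unit", {
  rcs <- reference_cost_summaries()
  expect_true(check_component_additivity(rcs, tol = 1))
  rcc <- reference_cost_contrasts()
  expect_true(check_component_additivity(rcc, tol = 2))
})
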
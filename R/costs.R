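#' 12-month pre/post cost windows per patient-unit
#'
#' Sums cost records over the year before and the year after treatment
#' initiation: pre window `[index - 365, index - 1]`, post window
#' `[index, index + 364]` (the index day itself belongs to the post
#' window, so the first biologic administration is a post-initiation
#' cost). Components:
#' \describe{
#'   \item{ip}{inpatient amounts, biologic drug costs billed inpatient
#'     included;}
#'   \item{op}{outpatient amounts, biologic drug costs billed outpatient
#'     included;}
#'   \item{rx_nonbt}{drug (RX category) amounts not flagged as biologic
#'     drug costs;}
#'   \item{total}{ip + op + rx_nonbt, exact at record precision.}
#' }
#'
#' @param units data frame of units that passed
#'   [select_cost_population()]; a unit lacking the 24-month window is a
#'   precondition error.
#' @param costs the cost table of a [claims_bundle()].
#' @return Data frame with two rows per unit (`window` = `"pre"`,
#'   `"post"`): `unit_id`, `window`, `ip`, `op`, `rx_nonbt`, `total`,
#'   amounts in JPY.
#' @export
window_costs <- function(units, costs) {
  eligible <- units$obs_start <= units$index_day - DAYS_12M &
    units$obs_end >= units$index_day + DAYS_12M
  if (any(!eligible))
    stop_("unit '%s' lacks the 24-month window around its index date",
          units$unit_id[which(!eligible)[1]])
  by_patient <- split(costs, costs$patient_id)
  one_window <- function(cc, from, to) {
    w <- cc[cc$date >= from & cc$date <= to, , drop = FALSE]
    ip <- sum(w$amount_jpy[w$category == "IP"])
    op <- sum(w$amount_jpy[w$category == "OP"])
    rx <- sum(w$amount_jpy[w$category == "RX" & !w$is_bt_drug_cost])
    c(ip = ip, op = op, rx_nonbt = rx, total = ip + op + rx)
  }
  rows <- lapply(seq_len(nrow(units)), function(k) {
    cc <- by_patient[[units$patient_id[k]]]
    if (is.null(cc)) cc <- costs[0, , drop = FALSE]
    idx <- units$index_day[k]
    pre <- one_window(cc, idx - DAYS_12M, idx - 1L)
    post <- one_window(cc, idx, idx + DAYS_12M - 1L)
    data.frame(unit_id = units$unit_id[k], window = c("pre", "post"),
               rbind(pre, post), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(), window = character(),
               ip = numeric(), op = numeric(), rx_nonbt = numeric(),
               total = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Componentwise cost increase from the pre to the post window
#'
#' `post - pre` per component; negative values are legitimate (costs may
#' fall after initiation).
#'
#' @param pre,post data frames of matching `pre`/`post` rows from
#'   [window_costs()] (same units, same order not required).
#' @return Data frame: `unit_id`, `ip`, `op`, `rx_nonbt`, `total`.
#' @export
cost_increase <- function(pre, post) {
  if (!setequal(pre$unit_id, post$unit_id) ||
      anyDuplicated(pre$unit_id) || anyDuplicated(post$unit_id))
    stop_("pre and post summaries must cover the same units exactly once")
  i <- match(pre$unit_id, post$unit_id)
  comp <- c("ip", "op", "rx_nonbt", "total")
  out <- data.frame(unit_id = pre$unit_id, stringsAsFactors = FALSE)
  for (cm in comp) out[[cm]] <- post[[cm]][i] - pre[[cm]]
  out
}

#' Mean pre-costs and cost increases by persistence stratum
#'
#' Stratifies cost-eligible units by drug (plus a cross-drug subtotal),
#' population (biologic-naive and total) and 12-month persistence group,
#' and reports per-stratum unit counts, mean pre-window component costs
#' and mean component cost increases. A third `difference` row per
#' stratum gives non-persistent minus persistent means (the direction in
#' which higher values mean discontinuation was the more expensive
#' path). Empty strata keep their row with `n = 0` and NA means.
#'
#' @param units cost-population units carrying a `naive` column (from
#'   [classify_naive()] and [select_cost_population()]).
#' @param episodes episodes for those units from [build_episodes()];
#'   `persistent_12m` must be defined (the cost population guarantees
#'   12 months of follow-up).
#' @param summaries window summaries from [window_costs()].
#' @return Data frame: `population`, `drug`, `group`
#'   (`persistent` / `non_persistent` / `difference`), `n`, mean
#'   `pre_ip`, `pre_op`, `pre_rx`, `pre_total`, `inc_ip`, `inc_op`,
#'   `inc_rx`, `inc_total` (JPY).
#' @export
contrast_by_persistence <- function(units, episodes, summaries) {
  if (is.null(units$naive))
    stop_("units must carry a 'naive' column; run classify_naive() first")
  persistent <- classify_12m_persistence(
    episodes[match(units$unit_id, episodes$unit_id), , drop = FALSE])
  pre <- summaries[summaries$window == "pre", , drop = FALSE]
  post <- summaries[summaries$window == "post", , drop = FALSE]
  inc <- cost_increase(pre, post)
  i_pre <- match(units$unit_id, pre$unit_id)
  i_inc <- match(units$unit_id, inc$unit_id)
  per_unit <- data.frame(
    drug = units$drug, naive = units$naive, persistent = persistent,
    pre_ip = pre$ip[i_pre], pre_op = pre$op[i_pre],
    pre_rx = pre$rx_nonbt[i_pre], pre_total = pre$total[i_pre],
    inc_ip = inc$ip[i_inc], inc_op = inc$op[i_inc],
    inc_rx = inc$rx_nonbt[i_inc], inc_total = inc$total[i_inc],
    stringsAsFactors = FALSE)

  comp <- c("pre_ip", "pre_op", "pre_rx", "pre_total",
            "inc_ip", "inc_op", "inc_rx", "inc_total")
  stratum_mean <- function(rows, population, drug, group) {
    out <- data.frame(population = population, drug = drug,
                      group = group, n = nrow(rows),
                      stringsAsFactors = FALSE)
    for (cm in comp)
      out[[cm]] <- if (nrow(rows)) mean(rows[[cm]]) else NA_real_
    out
  }
  drugs <- c(sort(unique(per_unit$drug)), "subtotal")
  blocks <- list()
  for (population in c("total", "naive")) {
    base <- if (population == "naive")
      per_unit[per_unit$naive, , drop = FALSE] else per_unit
    for (d in drugs) {
      dd <- if (d == "subtotal") base else
        base[base$drug == d, , drop = FALSE]
      p <- stratum_mean(dd[dd$persistent, , drop = FALSE],
                        population, d, "persistent")
      np <- stratum_mean(dd[!dd$persistent, , drop = FALSE],
                         population, d, "non_persistent")
      diff <- data.frame(population = population, drug = d,
                         group = "difference", n = nrow(dd),
                         stringsAsFactors = FALSE)
      for (cm in comp) diff[[cm]] <- np[[cm]] - p[[cm]]
      blocks[[length(blocks) + 1L]] <- rbind(p, np, diff)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Overall (pooled) cost summary by drug
#'
#' Companion to [contrast_by_persistence()]: per-stratum means over all
#' cost-eligible units regardless of persistence, by drug and
#' population, with a cross-drug subtotal.
#'
#' @inheritParams contrast_by_persistence
#' @return Data frame like [contrast_by_persistence()] with
#'   `group = "all"`.
#' @export
cost_summary_by_drug <- function(units, summaries) {
  if (is.null(units$naive))
    stop_("units must carry a 'naive' column; run classify_naive() first")
  pre <- summaries[summaries$window == "pre", , drop = FALSE]
  post <- summaries[summaries$window == "post", , drop = FALSE]
  inc <- cost_increase(pre, post)
  i_pre <- match(units$unit_id, pre$unit_id)
  i_inc <- match(units$unit_id, inc$unit_id)
  per_unit <- data.frame(
    drug = units$drug, naive = units$naive,
    pre_ip = pre$ip[i_pre], pre_op = pre$op[i_pre],
    pre_rx = pre$rx_nonbt[i_pre], pre_total = pre$total[i_pre],
    inc_ip = inc$ip[i_inc], inc_op = inc$op[i_inc],
    inc_rx = inc$rx_nonbt[i_inc], inc_total = inc$total[i_inc],
    stringsAsFactors = FALSE)
  comp <- c("pre_ip", "pre_op", "pre_rx", "pre_total",
            "inc_ip", "inc_op", "inc_rx", "inc_total")
  drugs <- c(sort(unique(per_unit$drug)), "subtotal")
  blocks <- list()
  for (population in c("total", "naive")) {
    base <- if (population == "naive")
      per_unit[per_unit$naive, , drop = FALSE] else per_unit
    for (d in drugs) {
      dd <- if (d == "subtotal") base else
        base[base$drug == d, , drop = FALSE]
      row <- data.frame(population = population, drug = d,
                        group = "all", n = nrow(dd),
                        stringsAsFactors = FALSE)
      for (cm in comp)
        row[[cm]] <- if (nrow(dd)) mean(dd[[cm]]) else NA_real_
      blocks[[length(blocks) + 1L]] <- row
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Round JPY amounts to the thousand-JPY reporting unit
#'
#' Costs are computed and stored in JPY; published-style tables report
#' integers in thousand-JPY units, rounded only at report time.
#'
#' @param x numeric JPY amounts.
#' @return `round(x / 1000)`.
#' @export
to_thousand_jpy <- function(x) round(x / 1000)
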
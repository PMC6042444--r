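#' Published reference aggregates (synthetic-free fixture data)
#'
#' Per-stratum cost summaries, persistent-vs-non-persistent contrasts
#' and 12-month persistence counts as printed by a published Japanese
#' claims-database study of biologic therapy in psoriasis. Amounts are
#' in thousand JPY as printed; `pre_*` columns are 12-month pre-index
#' means, `inc_*` columns mean increases from the pre to the post year.
#' These tables are reference inputs for arithmetic-consistency checks
#' (reconstructing post-initiation totals, group differences and
#' persistence proportions from the printed figures); they are not
#' produced by the package's own pipeline.
#'
#' @return Data frames mirroring the printed tables.
#' @seealso [reconstruct_post_costs()], [check_component_additivity()]
#' @export
reference_cost_summaries <- function() {
  utils::read.csv(system.file("extdata", "reference_cost_summaries.csv",
                              package = "persistkit"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_cost_summaries
#' @export
reference_cost_contrasts <- function() {
  utils::read.csv(system.file("extdata", "reference_cost_contrasts.csv",
                              package = "persistkit"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_cost_summaries
#' @export
reference_persistence_counts <- function() {
  utils::read.csv(system.file("extdata",
                              "reference_persistence_counts.csv",
                              package = "persistkit"),
                  stringsAsFactors = FALSE)
}

#' Reconstruct post-window costs as pre + increase
#'
#' Adds `post_ip`, `post_op`, `post_rx`, `post_total` columns to a cost
#' summary carrying `pre_*` and `inc_*` components, the identity through
#' which a pre/increase table determines the post-initiation costs.
#'
#' @param summary a data frame with `pre_*` and `inc_*` columns, e.g.
#'   from [reference_cost_summaries()] or [contrast_by_persistence()].
#' @return `summary` with the four `post_*` columns appended.
#' @export
reconstruct_post_costs <- function(summary) {
  for (cm in c("ip", "op", "rx", "total")) {
    pre <- summary[[paste0("pre_", cm)]]
    inc <- summary[[paste0("inc_", cm)]]
    if (is.null(pre) || is.null(inc))
      stop_("summary lacks pre_%s / inc_%s columns", cm, cm)
    summary[[paste0("post_", cm)]] <- pre + inc
  }
  summary
}

#' Check that cost components add up to the printed totals
#'
#' Verifies `|ip + op + rx - total| <= tol` for the `pre_` and `inc_`
#' blocks of a cost summary. Printed tables round each component
#' independently, so totals are only reproducible to within the rounding
#' unit.
#'
#' @inheritParams reconstruct_post_costs
#' @param tol permitted absolute discrepancy (1, i.e. one thousand JPY,
#'   for printed tables; 0 for exact record-level summaries).
#' @return TRUE invisibly, or an error naming the first failing row.
#' @export
check_component_additivity <- function(summary, tol = 1) {
  for (block in c("pre_", "inc_")) {
    s <- summary[[paste0(block, "ip")]] + summary[[paste0(block, "op")]] +
      summary[[paste0(block, "rx")]]
    gap <- abs(s - summary[[paste0(block, "total")]])
    bad <- which(!is.na(gap) & gap > tol)
    if (length(bad))
      stop_("components of block '%s' miss the total by %g in row %d",
            block, gap[bad[1]], bad[1])
  }
  invisible(TRUE)
}

#' Persistence proportion as a printed percentage
#'
#' @param n_persistent,n_total counts.
#' @param digits decimal places of the printed percentage.
#' @return `100 * n_persistent / n_total`, rounded.
#' @export
persistence_proportion_pct <- function(n_persistent, n_total,
                                       digits = 1) {
  round(100 * n_persistent / n_total, digits)
}
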
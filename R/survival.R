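#' Kaplan-Meier product-limit estimate with Greenwood variance
#'
#' Estimates the persistence (survival) function
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct event
#' times, with Greenwood's variance
#' `S(t)^2 * sum d_i / (n_i (n_i - d_i))` and a symmetric 95% interval
#' `S +/- 1.96 SE` on the plain scale, clipped to \[0, 1\] (a
#' complementary log-log interval is available via `conf_type`).
#' Events and censorings tied on the same day are resolved by the
#' standard convention: events first, so same-day censored units still
#' count as at risk.
#'
#' When the at-risk set is exhausted by events at some time
#' (`n_i == d_i`), the Greenwood term is undefined and the confidence
#' interval is flagged unavailable from that time on, while the point
#' estimate (0) is still returned.
#'
#' @param time non-negative event/censoring times in days.
#' @param event logical (or 0/1): TRUE for a discontinuation event,
#'   FALSE for censoring.
#' @param conf_level confidence level of the band.
#' @param conf_type `"plain"` (symmetric, the default) or `"loglog"`.
#' @return A `km_curve`: list with the per-event-time `table` (`time`,
#'   `n_risk`, `n_event`, `survival`, `se`, `lower`, `upper`,
#'   `ci_available`) plus counts `n`, `n_events`, `n_censored`.
#' @examples
#' fit <- km_estimate(c(5, 8, 12, 16, 20),
#'                    c(FALSE, TRUE, TRUE, FALSE, TRUE))
#' fit$table$survival   # 0.75, 0.50, 0.00
#' survival_at(fit, 10)
#' @export
km_estimate <- function(time, event, conf_level = 0.95,
                        conf_type = c("plain", "loglog")) {
  conf_type <- match.arg(conf_type)
  if (!length(time)) stop_("empty survival sample")
  if (length(event) != length(time))
    stop_("'time' and 'event' lengths differ")
  if (any(time < 0)) stop_("negative survival times")
  event <- as.logical(event)

  tev <- sort(unique(time[event]))
  n_risk <- vapply(tev, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(tev, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), Inf))
  se <- ifelse(is.finite(gw), surv * sqrt(gw), NA_real_)
  ci_available <- is.finite(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (conf_type == "plain") {
    lower <- pmax(0, surv - z * se)
    upper <- pmin(1, surv + z * se)
  } else {
    # interval on log(-log S), undefined at S in {0, 1}
    ok <- ci_available & surv > 0 & surv < 1
    se_cll <- ifelse(ok, sqrt(gw) / abs(log(surv)), NA_real_)
    lower <- ifelse(ok, surv^exp(z * se_cll), NA_real_)
    upper <- ifelse(ok, surv^exp(-z * se_cll), NA_real_)
    ci_available <- ok
  }
  structure(
    list(table = data.frame(time = tev, n_risk = n_risk,
                            n_event = n_event, survival = surv, se = se,
                            lower = lower, upper = upper,
                            ci_available = ci_available),
         n = length(time), n_events = sum(event),
         n_censored = sum(!event),
         conf_level = conf_level, conf_type = conf_type),
    class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, censored = %d\n",
              x$n, x$n_events, x$n_censored))
  print(utils::head(x$table, 10), row.names = FALSE)
  if (nrow(x$table) > 10) cat(sprintf("  ... %d more rows\n",
                                      nrow(x$table) - 10))
  invisible(x)
}

#' Read a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function read-out: the estimate at the largest
#' event time not exceeding `t`, or 1 (with a zero-width interval)
#' before the first event.
#'
#' @param curve a [km_estimate()] result.
#' @param t non-negative time(s) in days.
#' @return Data frame: `time`, `estimate`, `lower`, `upper`,
#'   `ci_available` (FALSE marks an unavailable interval; the estimate
#'   itself is always returned).
#' @export
survival_at <- function(curve, t) {
  if (any(t < 0)) stop_("negative time")
  tab <- curve$table
  i <- findInterval(t, tab$time)
  out <- data.frame(
    time = t,
    estimate = ifelse(i == 0, 1, tab$survival[pmax(i, 1)]),
    lower = ifelse(i == 0, 1, tab$lower[pmax(i, 1)]),
    upper = ifelse(i == 0, 1, tab$upper[pmax(i, 1)]),
    ci_available = ifelse(i == 0, TRUE, tab$ci_available[pmax(i, 1)]))
  rownames(out) <- NULL
  out
}

#' Two-sample survival test (log-rank or Gehan-Breslow Wilcoxon)
#'
#' At each distinct event time of the pooled sample, the observed events
#' in group `a` are compared with their hypergeometric expectation given
#' the margins, with variance
#' `d (n_a/n) (n_b/n) (n - d) / (n - 1)`. The weighted statistic
#' `(sum w (O - E))^2 / (sum w^2 V)` is referred to chi-squared with 1
#' degree of freedom. Weights are 1 for the log-rank test and the total
#' at-risk count `n_i` for the generalized (Gehan-Breslow) Wilcoxon
#' test, the standard reading of a "Wilcoxon rank sum test" for censored
#' persistence data.
#'
#' With no events in either sample the statistic is 0 and p = 1.
#'
#' @param a,b data frames with columns `time` and `event`.
#' @param weight `"log-rank"` or `"wilcoxon"`.
#' @return An object of class `htest`: `statistic` (chi-squared), df 1,
#'   `p.value`.
#' @examples
#' a <- data.frame(time = c(2, 4), event = TRUE)
#' b <- data.frame(time = c(6, 8), event = TRUE)
#' two_sample_test(a, b, "log-rank")
#' @export
two_sample_test <- function(a, b, weight = c("log-rank", "wilcoxon")) {
  weight <- match.arg(weight)
  if (!nrow(a) || !nrow(b)) stop_("both samples must be nonempty")
  time <- c(a$time, b$time)
  event <- as.logical(c(a$event, b$event))
  in_a <- rep(c(TRUE, FALSE), c(nrow(a), nrow(b)))
  if (any(time < 0)) stop_("negative survival times")

  tev <- sort(unique(time[event]))
  u <- 0; v <- 0
  for (t in tev) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_a)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & in_a)
    e1 <- d * n1 / n
    vt <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    w <- if (weight == "log-rank") 1 else n
    u <- u + w * (d1 - e1)
    v <- v + w^2 * vt
  }
  stat <- if (v > 0) u^2 / v else 0
  p <- if (v > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
  structure(
    list(statistic = c("chi-squared" = stat),
         parameter = c(df = 1),
         p.value = p,
         method = if (weight == "log-rank") "Log-rank test"
                  else "Gehan-Breslow generalized Wilcoxon test",
         data.name = sprintf("%d vs %d units", nrow(a), nrow(b))),
    class = "htest")
}

#' Pairwise survival tests of every group against a reference
#'
#' Runs the log-rank and Gehan-Breslow Wilcoxon tests of each
#' non-reference group versus the reference, unadjusted for multiple
#' comparisons.
#'
#' @param samples data frame with columns `time`, `event`, `group`.
#' @param reference the reference group label (e.g. `"UST"`).
#' @return Data frame: `group`, `reference`, `n`, `logrank_chisq`,
#'   `logrank_p`, `wilcoxon_chisq`, `wilcoxon_p`.
#' @export
pairwise_vs_reference <- function(samples, reference = "UST") {
  groups <- unique(samples$group)
  if (!reference %in% groups)
    stop_("reference group '%s' not present in the sample", reference)
  ref <- samples[samples$group == reference, , drop = FALSE]
  others <- setdiff(sort(groups), reference)
  rows <- lapply(others, function(g) {
    gg <- samples[samples$group == g, , drop = FALSE]
    lr <- two_sample_test(gg, ref, "log-rank")
    wx <- two_sample_test(gg, ref, "wilcoxon")
    data.frame(group = g, reference = reference, n = nrow(gg),
               logrank_chisq = unname(lr$statistic),
               logrank_p = lr$p.value,
               wilcoxon_chisq = unname(wx$statistic),
               wilcoxon_p = wx$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Step-function plot of Kaplan-Meier persistence curves
#'
#' Draws one right-continuous step curve per group.
#'
#' @param samples data frame with columns `time`, `event`, `group`.
#' @param main plot title.
#' @param xlab,ylab axis labels.
#' @param col colours, recycled across groups.
#' @return Invisibly, the list of per-group [km_estimate()] fits.
#' @export
plot_km_curves <- function(samples, main = "Treatment persistence",
                           xlab = "Days since initiation",
                           ylab = "Proportion persistent",
                           col = c("#1b9e77", "#d95f02", "#7570b3",
                                   "#e7298a")) {
  groups <- sort(unique(samples$group))
  fits <- lapply(groups, function(g) {
    s <- samples[samples$group == g, , drop = FALSE]
    km_estimate(s$time, s$event)
  })
  names(fits) <- groups
  xmax <- max(samples$time)
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, main = main)
  col <- rep_len(col, length(groups))
  for (i in seq_along(groups)) {
    tab <- fits[[i]]$table
    x <- c(0, rep(tab$time, each = 2), xmax)
    y <- c(1, 1, rep(tab$survival, each = 2))[seq_along(x)]
    graphics::lines(x, y, col = col[i], lwd = 2)
  }
  graphics::legend("bottomleft", legend = groups, col = col, lwd = 2,
                   bty = "n")
  invisible(fits)
}
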
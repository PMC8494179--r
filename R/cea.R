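# Cost-effectiveness statistics and decision rules for the two-strategy
# comparison: ICER with dominance classification, net monetary benefit, and
# the willingness-to-pay threshold decision.

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Compares strategy 1 against strategy 0. When the increments share a sign
#' the ICER is their ratio; when strategy 1 is cheaper and more effective it
#' is dominant (no ratio); cheaper-and-less-effective-strategy-0 means
#' strategy 1 is dominated. Equal effectiveness reduces to a cost
#' comparison; equal cost and effectiveness is classed as equivalent.
#'
#' @param cost1,qaly1 Totals for strategy 1.
#' @param cost0,qaly0 Totals for strategy 0 (the comparator).
#' @return An object of class `icer_result` with elements `dcost`, `dqaly`,
#'   `icer` (NA unless classified `"icer"`) and `classification` in
#'   `"icer"`, `"dominant"`, `"dominated"`, `"equal_effect"`, `"equivalent"`.
#' @examples
#' icer(20000, 10, 15000, 8) # $2,500 per QALY
#' @export
icer <- function(cost1, qaly1, cost0, qaly0) {
  dcost <- cost1 - cost0
  dqaly <- qaly1 - qaly0
  cls <- if (dqaly == 0 && dcost == 0) {
    "equivalent"
  } else if (dqaly == 0) {
    "equal_effect"
  } else if (dcost < 0 && dqaly > 0) {
    "dominant"
  } else if (dcost > 0 && dqaly < 0) {
    "dominated"
  } else {
    "icer"
  }
  structure(
    list(dcost = dcost, dqaly = dqaly,
         icer = if (cls == "icer") dcost / dqaly else NA_real_,
         classification = cls),
    class = "icer_result"
  )
}

#' Net monetary benefit
#'
#' `NMB = wtp * qaly - cost`: effectiveness monetized at the willingness to
#' pay, less cost. The incremental NMB of a costlier strategy changes sign
#' exactly at a willingness to pay equal to the ICER.
#'
#' @param cost Total cost (USD).
#' @param qaly Total effectiveness (QALY).
#' @param wtp Willingness to pay (USD/QALY), `>= 0`.
#' @return NMB in USD. Vectorized.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be >= 0", call. = FALSE)
  wtp * qaly - cost
}

#' Compare the screening and non-screening strategies
#'
#' Runs the cohort model for both strategies and assembles the
#' cost-effectiveness summary: per-strategy totals and cost-effectiveness
#' ratios, increments (screening minus non-screening), the ICER or dominance
#' classification, and the recommended strategy at the willingness-to-pay
#' threshold.
#'
#' @param spec A valid [model_spec()].
#' @param wtp Willingness-to-pay threshold; defaults to the spec setting.
#' @return An object of class `cea_result` with elements `summary` (one row
#'   per strategy), `incremental` (an `icer_result`), `wtp` and `decision`.
#' @export
compare_strategies <- function(spec, wtp = spec$settings$wtp_threshold) {
  sg <- run_cohort(spec, "SG")
  nsg <- run_cohort(spec, "NSG")
  cea_from_outcomes(sg$total_cost, sg$total_qaly,
                    nsg$total_cost, nsg$total_qaly, wtp)
}

# assemble a cea_result from precomputed totals (shared with the sensitivity
# analyses, which rerun the engine themselves)
cea_from_outcomes <- function(cost_sg, qaly_sg, cost_nsg, qaly_nsg, wtp) {
  inc <- icer(cost_sg, qaly_sg, cost_nsg, qaly_nsg)
  summary <- data.frame(
    strategy = c("screening", "non-screening"),
    cost = c(cost_sg, cost_nsg),
    qaly = c(qaly_sg, qaly_nsg),
    cer = c(cost_sg / qaly_sg, cost_nsg / qaly_nsg)
  )
  res <- structure(
    list(summary = summary, incremental = inc, wtp = wtp, decision = NA_character_),
    class = "cea_result"
  )
  res$decision <- threshold_decision(res, wtp)
  res
}

#' Recommended strategy at a willingness-to-pay threshold
#'
#' The costlier strategy is recommended when it dominates or when the ICER
#' falls below the threshold; otherwise the cheaper strategy is recommended.
#' With exactly equal effectiveness the cheaper strategy wins
#' (cost minimization).
#'
#' @param cea A `cea_result` from [compare_strategies()] or an `icer_result`
#'   from [icer()].
#' @param wtp_threshold Willingness to pay in USD/QALY.
#' @return `"screening"` or `"non-screening"` for a `cea_result`;
#'   `"strategy1"` or `"strategy0"` for a bare `icer_result`.
#' @export
threshold_decision <- function(cea, wtp_threshold) {
  if (inherits(cea, "cea_result")) {
    inc <- cea$incremental
    labels <- c(strategy1 = "screening", strategy0 = "non-screening")
  } else if (inherits(cea, "icer_result")) {
    inc <- cea
    labels <- c(strategy1 = "strategy1", strategy0 = "strategy0")
  } else {
    stop("`cea` must be a cea_result or icer_result", call. = FALSE)
  }
  pick <- switch(inc$classification,
    dominant = "strategy1",
    dominated = "strategy0",
    equivalent = "strategy0",
    equal_effect = if (inc$dcost < 0) "strategy1" else "strategy0",
    icer = {
      costlier <- if (inc$dcost > 0) "strategy1" else "strategy0"
      cheaper <- setdiff(c("strategy1", "strategy0"), costlier)
      # with dcost and dqaly sharing a sign, the ICER is the price per QALY
      # of moving to the costlier (also more effective) strategy
      if (inc$icer < wtp_threshold) costlier else cheaper
    }
  )
  unname(labels[pick])
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> screening vs non-screening\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s cost $%12.2f   QALY %8.4f   CER %9.2f\n",
                s$strategy[i], s$cost[i], s$qaly[i], s$cer[i]))
  }
  inc <- x$incremental
  cat(sprintf("  incremental: cost $%.2f, QALY %.5f (%s)\n",
              inc$dcost, inc$dqaly, inc$classification))
  if (!is.na(inc$icer)) cat(sprintf("  ICER: $%.2f/QALY\n", inc$icer))
  cat(sprintf("  decision at $%s/QALY: %s\n",
              format(x$wtp, big.mark = ","), x$decision))
  invisible(x)
}

#' Export the CEA summary as CSV (one row per strategy)
#'
#' @param cea A `cea_result`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_cea_csv <- function(cea, path) {
  s <- cea$summary
  inc <- cea$incremental
  s$incremental_cost <- c(inc$dcost, NA)
  s$incremental_qaly <- c(inc$dqaly, NA)
  s$icer <- c(inc$icer, NA)
  s$classification <- c(inc$classification, NA)
  s$decision <- c(cea$decision, NA)
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}
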
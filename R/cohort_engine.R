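# Annual-cycle Markov cohort simulation with discounted cost and QALY
# accumulation, plus a microsimulation oracle used to validate the cohort
# recursion.

# Precompute everything the per-cycle loop needs for a given spec/strategy.
engine_context <- function(spec, strategy) {
  se <- spec$settings
  H <- se$horizon_cycles
  ages <- se$start_age + 0:(H - 1L)
  q <- lookup_mortality(spec$life_table, ages)
  tp <- spec$transitions[[strategy]]
  exam_cost <- if (strategy == "SG") spec$costs[["c_n"]] else spec$costs[["c_o"]]
  charge_tf <- se$tf_arms == "both" || se$tf_arms == strategy
  disc <- (1 + se$discount_rate)^-(0:(H - 1L) + se$discount_cycle_offset)
  exam_on <- (0:(H - 1L)) %% se$exam_interval == 0L
  list(H = H, q = q, tp = tp, exam_cost = exam_cost, charge_tf = charge_tf,
       disc = disc, exam_on = exam_on, se = se, costs = spec$costs,
       u = spec$utilities[health_states()])
}

# Per-cycle cost of one unit of occupancy in each state (excluding the
# one-time treatment cost, handled separately).
state_cost_rates <- function(ctx, cycle) {
  se <- ctx$se
  rates <- numeric(6L)
  if (ctx$exam_on[cycle] && se$exam_states != "none") {
    idx <- switch(se$exam_states,
                  alive = 1:5, health = 1L, health_btn = 1:2)
    rates[idx] <- rates[idx] + ctx$exam_cost
  }
  if (se$nf_states != "none") {
    idx <- switch(se$nf_states, btn = 2L, health_btn = 1:2)
    rates[idx] <- rates[idx] + ctx$costs[["c_nf"]]
  }
  if (ctx$charge_tf) rates[4L] <- rates[4L] + ctx$costs[["c_tf"]]
  rates[5L] <- rates[5L] + ctx$costs[["c_recurrence"]]
  if (se$ct_timing == "percycle") rates[3L] <- rates[3L] + ctx$costs[["c_t"]]
  rates
}

#' Run the Markov cohort simulation for one strategy
#'
#' Propagates the full cohort (cycle-0 occupancy concentrated in `health`)
#' through the age-dependent transition matrices over the analysis horizon,
#' accumulating discounted per-cycle costs and quality-adjusted life years.
#' Rewards for cycle `k` are computed on start-of-cycle occupancy (or the
#' start/end average under the half-cycle correction) and discounted by
#' `(1 + r)^-k`; the one-time treatment cost is charged on the cohort mass
#' entering the cancer state during the cycle.
#'
#' @param spec A valid [model_spec()].
#' @param strategy `"SG"` (ultrasound screening) or `"NSG"` (non-screening).
#' @return An object of class `strategy_outcome` with elements `total_cost`,
#'   `total_qaly` (discounted), `per_cycle_cost`, `per_cycle_qaly`
#'   (discounted contributions), `cost_undiscounted`, `qaly_undiscounted`,
#'   `trace` (a `(horizon + 1) x 6` occupancy matrix), `strategy` and
#'   `start_age`.
#' @export
run_cohort <- function(spec, strategy = c("SG", "NSG")) {
  strategy <- match.arg(strategy)
  bad <- validate_model(spec)
  if (length(bad)) {
    stop("invalid model specification:\n", paste("-", bad, collapse = "\n"),
         call. = FALSE)
  }
  run_cohort_core(spec, strategy)
}

# engine core without the validation pass; used directly by the PSA, where
# the base spec is validated once and per-draw feasibility is checked
# separately (sampled costs may legitimately cross the base-case ordering)
run_cohort_core <- function(spec, strategy) {
  ctx <- engine_context(spec, strategy)
  se <- ctx$se
  H <- ctx$H
  trace <- matrix(0, H + 1L, 6L, dimnames = list(0:H, health_states()))
  occ <- c(1, 0, 0, 0, 0, 0)
  trace[1L, ] <- occ
  cost_cycle <- numeric(H)
  qaly_cycle <- numeric(H)
  for (k in seq_len(H)) {
    P <- transition_matrix_at(ctx$tp, ctx$q[k])
    if (any(P < 0)) {
      stop(sprintf("competing probabilities exceed 1 at cycle %d (%s)", k - 1L,
                   strategy), call. = FALSE)
    }
    Peff <- P
    if (se$mtn_instant) {
      # detection and surgery within the cycle: entrants resolve to postop
      # or death before cycle end, cancer-state residence is zero
      Peff[, 4L] <- Peff[, 4L] + Peff[, 3L] * P[3L, 4L]
      Peff[, 6L] <- Peff[, 6L] + Peff[, 3L] * P[3L, 6L]
      Peff[, 3L] <- 0
    }
    occ_next <- as.vector(occ %*% Peff)
    basis <- if (se$half_cycle_correction) (occ + occ_next) / 2 else occ
    rates <- state_cost_rates(ctx, k)
    cyc_cost <- sum(basis * rates)
    if (se$ct_timing == "entry") {
      cyc_cost <- cyc_cost + sum(occ * P[, 3L]) * ctx$costs[["c_t"]]
    }
    cost_cycle[k] <- ctx$disc[k] * cyc_cost
    qaly_cycle[k] <- ctx$disc[k] * sum(basis * ctx$u) * se$cycle_length
    occ <- occ_next
    trace[k + 1L, ] <- occ
  }
  structure(
    list(strategy = strategy,
         total_cost = sum(cost_cycle),
         total_qaly = sum(qaly_cycle),
         per_cycle_cost = cost_cycle,
         per_cycle_qaly = qaly_cycle,
         cost_undiscounted = cost_cycle / ctx$disc,
         qaly_undiscounted = qaly_cycle / ctx$disc,
         trace = trace,
         start_age = se$start_age),
    class = "strategy_outcome"
  )
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s: discounted cost $%.2f, %.4f QALYs over %d cycles\n",
              x$strategy, x$total_cost, x$total_qaly, length(x$per_cycle_cost)))
  invisible(x)
}

#' Microsimulation oracle for the cohort engine
#'
#' Simulates `n_individuals` independent random walks through the same
#' age-dependent transition matrices and reward mappings as [run_cohort()].
#' Per-individual discounted totals are averaged; their standard errors
#' quantify Monte Carlo noise. The estimates are unbiased for the cohort
#' values, which is the basis of the engine cross-validation tests.
#'
#' @param spec A valid [model_spec()].
#' @param strategy `"SG"` or `"NSG"`.
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed for the random walks.
#' @return A list with `total_cost`, `total_qaly` (means over individuals),
#'   `se_cost`, `se_qaly`, and `n`.
#' @export
microsim_oracle <- function(spec, strategy = c("SG", "NSG"),
                            n_individuals = 10000L, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(n_individuals >= 1L)
  bad <- validate_model(spec)
  if (length(bad)) {
    stop("invalid model specification:\n", paste("-", bad, collapse = "\n"),
         call. = FALSE)
  }
  se <- spec$settings
  if (se$half_cycle_correction) {
    stop("microsim_oracle does not support the half-cycle correction",
         call. = FALSE)
  }
  ctx <- engine_context(spec, strategy)
  n <- as.integer(n_individuals)
  state <- rep(1L, n)
  cost_i <- numeric(n)
  qaly_i <- numeric(n)
  u <- ctx$u
  ct <- ctx$costs[["c_t"]]
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  for (k in seq_len(ctx$H)) {
    d <- ctx$disc[k]
    rates <- state_cost_rates(ctx, k)
    qaly_i <- qaly_i + d * u[state] * se$cycle_length
    cost_i <- cost_i + d * rates[state]
    P <- transition_matrix_at(ctx$tp, ctx$q[k])
    nxt <- state
    for (s in 1:5) {
      idx <- which(state == s)
      if (!length(idx)) next
      nxt[idx] <- sample.int(6L, length(idx), replace = TRUE, prob = P[s, ])
    }
    entered <- which(nxt == 3L)
    if (length(entered)) {
      if (se$ct_timing == "entry") cost_i[entered] <- cost_i[entered] + d * ct
      if (se$mtn_instant) {
        # resolve surgery within the cycle, as the cohort engine does
        die <- stats::runif(length(entered)) < P[3L, 6L]
        nxt[entered] <- ifelse(die, 6L, 4L)
      }
    }
    state <- nxt
  }
  list(total_cost = mean(cost_i), total_qaly = mean(qaly_i),
       se_cost = stats::sd(cost_i) / sqrt(n),
       se_qaly = stats::sd(qaly_i) / sqrt(n),
       n = n)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Export a cohort trace with per-cycle rewards as CSV
#'
#' @param outcome A `strategy_outcome` from [run_cohort()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_trace_csv <- function(outcome, path) {
  H <- length(outcome$per_cycle_cost)
  df <- data.frame(cycle = 0:H, age = outcome$start_age + 0:H,
                   outcome$trace, check.names = FALSE)
  df$cost <- c(outcome$cost_undiscounted, NA)
  df$qaly <- c(outcome$qaly_undiscounted, NA)
  df$discounted_cost <- c(outcome$per_cycle_cost, NA)
  df$discounted_qaly <- c(outcome$per_cycle_qaly, NA)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
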
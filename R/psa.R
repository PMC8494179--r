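# Probabilistic sensitivity analysis: joint sampling of all uncertain
# parameters, repeated evaluation of both strategies per draw, incremental
# scatter, and cost-effectiveness acceptability curves.

#' Draw one joint sample of all uncertain parameters
#'
#' One value per distributed parameter, drawn independently in declaration
#' order from the resolved distributions (so a run is reproducible across
#' versions given the same seed). `fixed` parameters return their base
#' value. Utilities are clamped to `[0, 1]`. Parameters shared across
#' strategies carry a single name and are drawn once; [set_parameter()]
#' applies them to both arms.
#'
#' Uses the current RNG state; seed with `set.seed()` or through
#' [run_psa()].
#'
#' @param spec A [model_spec()].
#' @param resolved Optional precomputed list of resolved distributions (a
#'   performance convenience for repeated calls).
#' @return Named numeric vector of class `psa_sample`.
#' @export
sample_parameters <- function(spec, resolved = NULL) {
  if (is.null(resolved)) resolved <- lapply(spec$distributions, resolve_distribution)
  draws <- vapply(resolved, sample_resolved, numeric(1))
  is_u <- grepl("^u_", names(draws))
  draws[is_u] <- pmin(pmax(draws[is_u], 0), 1)
  structure(draws, class = c("psa_sample", "numeric"))
}

apply_sample <- function(spec, sample) {
  for (nm in names(sample)) spec <- set_parameter(spec, nm, sample[[nm]])
  spec
}

# feasibility of one sampled parameter set: no competing-risk row may exceed
# probability 1 at any age in the horizon
sample_feasible <- function(spec) {
  se <- spec$settings
  ages <- se$start_age + seq_len(se$horizon_cycles) - 1L
  qmax <- max(lookup_mortality(spec$life_table, ages))
  for (arm in c("SG", "NSG")) {
    v <- spec$transitions[[arm]]
    if (v[["p_health_btn"]] + v[["p_health_mtn"]] + qmax > 1) return(FALSE)
    if (v[["p_btn_mtn"]] + qmax > 1) return(FALSE)
    if (v[["p_mtn_death"]] + qmax > 1) return(FALSE)
    if (v[["p_postop_recurrence"]] + qmax > 1) return(FALSE)
  }
  TRUE
}

#' Run the probabilistic sensitivity analysis
#'
#' For each Monte Carlo draw, every uncertain parameter is sampled from its
#' distribution, both strategies are run with the same sampled set, and the
#' incremental (QALY, cost) pair of screening versus non-screening is
#' recorded. A draw whose sampled probabilities leave no room for a
#' non-negative self-loop (row sum above 1) is redrawn; the redraw count is
#' recorded. A fixed seed makes the scatter bit-identical across runs.
#'
#' @param spec A valid [model_spec()].
#' @param n_draws Number of Monte Carlo draws (default: spec setting, 1000).
#' @param seed Integer seed (default: spec setting).
#' @return A data frame of class `psa_scatter` with columns `draw`,
#'   `dqaly`, `dcost`, `cost_sg`, `qaly_sg`, `cost_nsg`, `qaly_nsg`, and
#'   attributes `seed`, `n_draws`, `redraws`, `wtp`.
#' @export
run_psa <- function(spec, n_draws = spec$settings$psa_draws,
                    seed = spec$settings$rng_seed) {
  stopifnot(n_draws >= 1L)
  bad <- validate_model(spec)
  if (length(bad)) {
    stop("invalid model specification:\n", paste("-", bad, collapse = "\n"),
         call. = FALSE)
  }
  resolved <- lapply(spec$distributions, resolve_distribution)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  n <- as.integer(n_draws)
  out <- matrix(NA_real_, n, 6L)
  redraws <- 0L
  for (i in seq_len(n)) {
    repeat {
      sp <- apply_sample(spec, sample_parameters(spec, resolved))
      if (sample_feasible(sp)) break
      redraws <- redraws + 1L
      if (redraws > 100L * n) {
        stop("PSA redraw limit exceeded: sampled parameter sets are almost never feasible",
             call. = FALSE)
      }
    }
    sg <- run_cohort_core(sp, "SG")
    nsg <- run_cohort_core(sp, "NSG")
    out[i, ] <- c(sg$total_qaly - nsg$total_qaly,
                  sg$total_cost - nsg$total_cost,
                  sg$total_cost, sg$total_qaly,
                  nsg$total_cost, nsg$total_qaly)
  }
  df <- data.frame(draw = seq_len(n), dqaly = out[, 1], dcost = out[, 2],
                   cost_sg = out[, 3], qaly_sg = out[, 4],
                   cost_nsg = out[, 5], qaly_nsg = out[, 6])
  attr(df, "seed") <- seed
  attr(df, "n_draws") <- n
  attr(df, "redraws") <- redraws
  attr(df, "wtp") <- spec$settings$wtp_threshold
  class(df) <- c("psa_scatter", class(df))
  df
}

#' Probability that screening is cost-effective at a willingness to pay
#'
#' The fraction of scatter points whose incremental net monetary benefit
#' `wtp * dQALY - dCost` favors screening. An exact tie is awarded to the
#' cheaper strategy of that draw, and with equal costs to the more effective
#' one (measure-zero events, fixed for determinism); the complement is the
#' probability that non-screening is cost-effective.
#'
#' @param scatter A `psa_scatter` from [run_psa()].
#' @param wtp Willingness to pay in USD/QALY.
#' @return Fraction in `[0, 1]`. Vectorized over `wtp`.
#' @export
prob_cost_effective <- function(scatter, wtp) {
  stopifnot(nrow(scatter) >= 1L)
  vapply(wtp, function(w) {
    nmbd <- w * scatter$dqaly - scatter$dcost
    tie_sg <- scatter$dcost < 0 | (scatter$dcost == 0 & scatter$dqaly > 0)
    mean(nmbd > 0 | (nmbd == 0 & tie_sg))
  }, numeric(1))
}

#' Cost-effectiveness acceptability curve
#'
#' Evaluates [prob_cost_effective()] across a willingness-to-pay grid and
#' reports the crossover: the smallest grid value at which screening is more
#' likely cost-effective than non-screening.
#'
#' @param scatter A `psa_scatter` from [run_psa()].
#' @param wtp_grid Strictly increasing willingness-to-pay grid; the default
#'   covers 0 to 200,000 USD/QALY in steps of 5,000.
#' @return A data frame of class `ceac_curve` with columns `wtp`,
#'   `p_screening`, `p_nonscreening` and attribute `crossover_wtp` (NA when
#'   screening never reaches probability one half on the grid).
#' @export
ceac <- function(scatter, wtp_grid = seq(0, 200000, by = 5000)) {
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("`wtp_grid` must be strictly increasing", call. = FALSE)
  }
  p <- prob_cost_effective(scatter, wtp_grid)
  df <- data.frame(wtp = wtp_grid, p_screening = p, p_nonscreening = 1 - p)
  hit <- which(p > 0.5)
  attr(df, "crossover_wtp") <- if (length(hit)) wtp_grid[hit[1L]] else NA_real_
  class(df) <- c("ceac_curve", class(df))
  df
}

#' @export
print.psa_scatter <- function(x, ...) {
  cat(sprintf("<psa_scatter> %d draws (seed %s, %d redraws)\n",
              attr(x, "n_draws"), attr(x, "seed"), attr(x, "redraws")))
  q1 <- mean(x$dqaly > 0 & x$dcost > 0)
  cat(sprintf("  mean dQALY %.5f, mean dCost $%.2f, %.0f%% of points in the first quadrant\n",
              mean(x$dqaly), mean(x$dcost), 100 * q1))
  invisible(x)
}

#' Export the PSA scatter as CSV
#' @param scatter A `psa_scatter`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_scatter_csv <- function(scatter, path) {
  utils::write.csv(as.data.frame(scatter), path, row.names = FALSE)
  invisible(path)
}

#' Export a CEAC as CSV
#' @param curve A `ceac_curve`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_ceac_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Plot the incremental cost-effectiveness scatter
#'
#' Quadrant scatter of (incremental QALY, incremental cost) with the
#' willingness-to-pay line through the origin.
#'
#' @param scatter A `psa_scatter`.
#' @param wtp Willingness to pay for the reference line; defaults to the
#'   value stored on the scatter.
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(scatter, wtp = attr(scatter, "wtp")) {
  df <- as.data.frame(scatter)
  ggplot2::ggplot(df, ggplot2::aes(dqaly, dcost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "Incremental QALYs (screening - non-screening)",
                  y = "Incremental cost (USD)",
                  title = sprintf("Monte Carlo incremental scatter (WTP $%s/QALY)",
                                  format(wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves for both strategies
#'
#' @param curve A `ceac_curve`.
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  df <- as.data.frame(curve)
  long <- data.frame(
    wtp = rep(df$wtp, 2L),
    p = c(df$p_screening, df$p_nonscreening),
    strategy = rep(c("screening", "non-screening"), each = nrow(df))
  )
  ggplot2::ggplot(long, ggplot2::aes(wtp, p, colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
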
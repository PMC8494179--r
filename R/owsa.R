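# One-way deterministic sensitivity analysis: vary each parameter across its
# range with everything else at base, track the incremental net monetary
# benefit (and ICER) of screening, and order the results for a tornado
# diagram.

#' Vary one parameter across a range and record the outcome at both bounds
#'
#' Reruns both strategies with the parameter at its lower and upper bound
#' (all other parameters at base). The primary metric is the incremental net
#' monetary benefit of screening at the willingness-to-pay threshold, which
#' stays well defined through dominance regions; the ICER is reported
#' alongside. Strategy-shared parameters (`p_btn_mtn`,
#' `p_postop_recurrence`) are varied in both arms simultaneously.
#'
#' @param spec A valid [model_spec()].
#' @param parameter Parameter name (see [set_parameter()]).
#' @param low,high Bounds; default to the parameter's sensitivity range, or
#'   base plus/minus 10 percent when no distribution entry exists.
#' @param wtp Willingness to pay; defaults to the spec threshold.
#' @return A one-row data frame with the parameter name, bounds, base value,
#'   incremental NMB and ICER at each bound, the absolute bar width
#'   `|inmb_high - inmb_low|`, and whether the recommended strategy differs
#'   anywhere within the range (`flip`).
#' @export
one_way_sensitivity <- function(spec, parameter, low = NULL, high = NULL,
                                wtp = spec$settings$wtp_threshold) {
  base_val <- get_parameter(spec, parameter)
  d <- spec$distributions[[parameter]]
  if (is.null(low)) low <- if (!is.null(d)) d$range_low else base_val * 0.9
  if (is.null(high)) high <- if (!is.null(d)) d$range_high else base_val * 1.1
  if (low > high) stop("`low` must not exceed `high`", call. = FALSE)
  eval_at <- function(value) {
    sp <- set_parameter(spec, parameter, value)
    bad <- validate_model(sp)
    if (length(bad)) {
      stop(sprintf("bound %g for '%s' leaves the model invalid: %s",
                   value, parameter, bad[[1L]]), call. = FALSE)
    }
    cea <- compare_strategies(sp, wtp)
    inc <- cea$incremental
    list(inmb = net_monetary_benefit(inc$dcost, inc$dqaly, wtp),
         icer = inc$icer, decision = cea$decision)
  }
  at_low <- eval_at(low)
  at_high <- eval_at(high)
  at_base <- eval_at(base_val)
  flips <- unique(c(at_low$decision, at_high$decision, at_base$decision))
  data.frame(
    parameter = parameter,
    base = base_val, low = low, high = high,
    inmb_low = at_low$inmb, inmb_high = at_high$inmb,
    icer_low = at_low$icer, icer_high = at_high$icer,
    width = abs(at_high$inmb - at_low$inmb),
    decision_low = at_low$decision, decision_high = at_high$decision,
    flip = length(flips) > 1L,
    stringsAsFactors = FALSE
  )
}

#' Tornado analysis over every uncertain parameter
#'
#' Runs [one_way_sensitivity()] for each parameter carrying a sensitivity
#' range and sorts the entries by descending influence (bar width of the
#' incremental net monetary benefit of screening).
#'
#' @param spec A valid [model_spec()].
#' @param parameters Parameter names to vary; defaults to every distribution
#'   entry whose range has positive width.
#' @param wtp Willingness to pay; defaults to the spec threshold.
#' @return A data frame of class `tornado`, one row per parameter, sorted by
#'   descending `width`.
#' @export
tornado <- function(spec, parameters = NULL,
                    wtp = spec$settings$wtp_threshold) {
  if (is.null(parameters)) {
    keep <- vapply(spec$distributions,
                   function(d) d$range_high > d$range_low, logical(1))
    parameters <- names(spec$distributions)[keep]
  }
  if (!length(parameters)) stop("no parameters to vary", call. = FALSE)
  rows <- lapply(parameters, function(p) one_way_sensitivity(spec, p, wtp = wtp))
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", class(out))
  out
}

#' Export tornado data as CSV
#'
#' @param tor A `tornado` data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_tornado_csv <- function(tor, path) {
  utils::write.csv(as.data.frame(tor), path, row.names = FALSE)
  invisible(path)
}

#' Plot a tornado diagram
#'
#' Horizontal bars span the incremental net monetary benefit of screening
#' between each parameter's bounds, widest on top; the dashed line marks the
#' base-case value.
#'
#' @param tor A `tornado` data frame.
#' @param base_inmb Optional base-case incremental NMB for the reference
#'   line; when missing the midpoint of the widest bar is used.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tor, base_inmb = NULL) {
  df <- as.data.frame(tor)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  df$bar_min <- pmin(df$inmb_low, df$inmb_high)
  df$bar_max <- pmax(df$inmb_low, df$inmb_high)
  if (is.null(base_inmb)) base_inmb <- (df$inmb_low[1] + df$inmb_high[1]) / 2
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = bar_min, xend = bar_max,
      y = parameter, yend = parameter),
      linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_inmb, linetype = "dashed") +
    ggplot2::labs(x = "Incremental net monetary benefit of screening (USD)",
                  y = NULL, title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}
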
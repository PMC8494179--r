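# Domain types and parameter handling for the two-strategy thyroid screening
# decision problem: health states, utilities, costs, transition parameters,
# parameter distributions, analysis settings, and the bundled base-case
# parameterization.

#' Health states of the thyroid screening model
#'
#' The model tracks six mutually exclusive health states: disease-free
#' (`health`), benign thyroid nodules under follow-up (`btn`), malignant
#' thyroid nodules, i.e. thyroid cancer at detection (`mtn`), post-operative
#' stability after cancer surgery (`postop`), cancer recurrence
#' (`recurrence`, absorbing for disease transitions) and `death` (absorbing).
#'
#' @return Character vector of the six state labels, in canonical order.
#' @export
health_states <- function() {
  c("health", "btn", "mtn", "postop", "recurrence", "death")
}

#' Convert a multi-year cumulative probability to an annual probability
#'
#' Implements the standard constant-rate conversion
#' `p_annual = 1 - (1 - p_cum)^(1/t)`, the inverse of compounding an annual
#' probability over `t` years.
#'
#' @param p_cum Cumulative probability observed over `t` years, in `[0, 1]`.
#' @param t Duration in years over which `p_cum` was observed; must be `> 0`.
#' @return The equivalent annual probability, in `[0, 1]`. Vectorized over
#'   `p_cum`.
#' @examples
#' annualize_probability(0.75, 2) # 0.5
#' annualize_probability(0.19, 1) # 0.19
#' @export
annualize_probability <- function(p_cum, t) {
  if (!is.numeric(p_cum) || anyNA(p_cum) || any(p_cum < 0) || any(p_cum > 1)) {
    stop("`p_cum` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0) {
    stop("`t` must be a positive duration in years", call. = FALSE)
  }
  1 - (1 - p_cum)^(1 / t)
}

#' Describe the uncertainty of a single model parameter
#'
#' A parameter carries a deterministic base value, a plausible range used for
#' one-way sensitivity analysis, and a sampling distribution (`beta` for
#' probabilities and utilities, `gamma` for costs, `fixed` for parameters held
#' constant) used for probabilistic sensitivity analysis.
#'
#' @param family One of `"beta"`, `"gamma"`, `"fixed"`.
#' @param base_value Deterministic base-case value.
#' @param shape_a,shape_b Distribution shapes: for `beta` the two shape
#'   parameters; for `gamma` the shape and the scale. Ignored for `fixed`.
#' @param range_low,range_high Bounds for one-way sensitivity analysis.
#'   Default to `base_value` plus/minus 10 percent (clamped to `[0, 1]` for
#'   beta-distributed parameters).
#' @return An object of class `param_dist`.
#' @export
param_dist <- function(family, base_value, shape_a = NA_real_,
                       shape_b = NA_real_, range_low = NULL,
                       range_high = NULL) {
  family <- match.arg(family, c("beta", "gamma", "fixed"))
  stopifnot(is.numeric(base_value), length(base_value) == 1L, !is.na(base_value))
  if (is.null(range_low)) {
    range_low <- if (family == "beta") max(0, base_value * 0.9) else base_value * 0.9
  }
  if (is.null(range_high)) {
    range_high <- if (family == "beta") min(1, base_value * 1.1) else base_value * 1.1
  }
  if (!(range_low <= base_value && base_value <= range_high)) {
    stop("range must bracket the base value: low <= base <= high", call. = FALSE)
  }
  structure(
    list(family = family, shape_a = shape_a, shape_b = shape_b,
         base_value = base_value, range_low = range_low,
         range_high = range_high),
    class = "param_dist"
  )
}

#' Moment-matched beta distribution
#'
#' Returns the shape parameters of the beta distribution with the requested
#' mean and standard deviation.
#'
#' @param mean Target mean, strictly inside `(0, 1)`.
#' @param sd Target standard deviation; must satisfy `sd^2 < mean (1 - mean)`.
#' @return Named numeric vector with elements `shape1` and `shape2`.
#' @examples
#' beta_moment_match(0.5, 0.1) # Beta(12, 12)
#' @export
beta_moment_match <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("infeasible beta moments: sd^2 must be < mean * (1 - mean)",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# sd for repairing an unusable printed beta: the largest sd whose symmetric
# 2-sd interval around the base fits inside both the printed range and [0, 1]
repair_sd <- function(base, low, high) {
  min((high - low) / 4, (high - base) / 2, (base - low) / 2,
      (1 - base) / 2, base / 2)
}

#' Resolve a parameter distribution into a sampling-ready form
#'
#' Gamma distributions are interpreted as shape/scale (mean = shape * scale).
#' A beta distribution whose printed shapes are unusable (non-positive or
#' missing) is replaced by a moment-matched beta centred on the base value
#' whose symmetric two-standard-deviation interval fits inside the printed
#' range and the unit interval. `fixed` parameters always return the base
#' value.
#'
#' @param dist A [param_dist()].
#' @return An object of class `resolved_dist` with elements `family`,
#'   `shape_a`, `shape_b`, `mean`, `base_value`, `repaired`, and a sampler
#'   accessible through [sample_resolved()].
#' @export
resolve_distribution <- function(dist) {
  stopifnot(inherits(dist, "param_dist"))
  fam <- dist$family
  repaired <- FALSE
  a <- dist$shape_a
  b <- dist$shape_b
  if (fam == "beta") {
    ok <- is.finite(a) && is.finite(b) && a > 0 && b > 0
    if (!ok) {
      base <- dist$base_value
      if (base <= 0 || base >= 1 || dist$range_high <= dist$range_low) {
        fam <- "fixed"
      } else {
        sd <- repair_sd(base, dist$range_low, dist$range_high)
        sh <- beta_moment_match(base, sd)
        a <- sh[["shape1"]]
        b <- sh[["shape2"]]
        repaired <- TRUE
      }
    }
  } else if (fam == "gamma") {
    if (!(is.finite(a) && is.finite(b) && a > 0 && b > 0)) {
      stop("gamma distribution requires positive shape and scale", call. = FALSE)
    }
  }
  m <- switch(fam,
    beta = a / (a + b),
    gamma = a * b,
    fixed = dist$base_value
  )
  structure(
    list(family = fam, shape_a = a, shape_b = b, mean = m,
         base_value = dist$base_value, repaired = repaired),
    class = "resolved_dist"
  )
}

#' Draw from a resolved distribution
#'
#' Uses the current state of the R random number generator; seeding is the
#' caller's responsibility (see [run_psa()]).
#'
#' @param rd A `resolved_dist` from [resolve_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_resolved <- function(rd, n = 1L) {
  stopifnot(inherits(rd, "resolved_dist"))
  switch(rd$family,
    beta = stats::rbeta(n, rd$shape_a, rd$shape_b),
    gamma = stats::rgamma(n, shape = rd$shape_a, scale = rd$shape_b),
    fixed = rep(rd$base_value, n)
  )
}

#' Assemble a complete model specification
#'
#' @param utilities Named numeric vector of per-state utilities over
#'   [health_states()].
#' @param costs Named numeric vector with elements `c_t` (one-time cancer
#'   treatment), `c_n` (ultrasound examination, per cycle, screening arm),
#'   `c_o` (routine physical examination, per cycle, non-screening arm),
#'   `c_tf` (post-cancer follow-up, per cycle), `c_nf` (benign-nodule
#'   follow-up, per cycle), `c_recurrence` (recurrence care, per cycle). USD.
#' @param transitions List with elements `SG` and `NSG`, each a named numeric
#'   vector of annual probabilities `p_health_btn`, `p_health_mtn`,
#'   `p_btn_mtn`, `p_mtn_death` (excess, disease-specific), and
#'   `p_postop_recurrence`.
#' @param distributions Named list of [param_dist()] objects, one per
#'   uncertain parameter (see [thyroid_screening_spec()] for the canonical
#'   names).
#' @param settings List of analysis settings; see [analysis_settings()].
#' @param life_table Data frame with columns `age` and `q` giving annual
#'   background mortality; see [synthetic_life_table()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(utilities, costs, transitions, distributions,
                       settings, life_table) {
  spec <- structure(
    list(utilities = utilities, costs = costs, transitions = transitions,
         distributions = distributions, settings = settings,
         life_table = life_table),
    class = "model_spec"
  )
  spec
}

#' Analysis settings
#'
#' Collects cycle structure, discounting, decision threshold, probabilistic
#' analysis size, and the structural switches of the cost/state mapping.
#'
#' @param horizon_cycles Number of annual cycles (default 55).
#' @param cycle_length Cycle length in years (default 1).
#' @param start_age Cohort age at cycle 0 (default 20).
#' @param discount_rate Annual discount rate applied to both costs and QALYs
#'   (default 0.05).
#' @param wtp_threshold Willingness-to-pay threshold in USD per QALY
#'   (default 50000).
#' @param psa_draws Default number of Monte Carlo draws for the probabilistic
#'   sensitivity analysis (default 1000).
#' @param rng_seed Default seed for reproducible sampling.
#' @param mtn_instant If `TRUE` (default), cancer detected in a cycle is
#'   treated within that cycle: survivors of surgery occupy the post-operative
#'   state at cycle end and the cancer state has zero residence time. If
#'   `FALSE`, detected cancer occupies its state for one full cycle.
#' @param exam_states Which occupancy is charged the per-cycle examination
#'   cost (`c_n` in the screening arm, `c_o` otherwise): `"alive"` (default),
#'   `"health"`, `"health_btn"` or `"none"`.
#' @param nf_states Which occupancy is charged the benign-nodule follow-up
#'   cost `c_nf`: `"btn"` (default), `"health_btn"` or `"none"`.
#' @param tf_arms Which strategy arms charge the post-cancer follow-up cost
#'   `c_tf` on post-operative occupancy: `"SG"` (default; surveillance imaging
#'   is part of the screening programme, while follow-up in the non-screening
#'   arm happens through the routine examination already charged), `"NSG"`,
#'   `"both"` or `"none"`.
#' @param ct_timing `"entry"` (default): the one-time treatment cost `c_t` is
#'   charged on the cohort mass entering the cancer state each cycle;
#'   `"percycle"`: charged on prevalent cancer occupancy.
#' @param exam_interval Examination cost charged every this many cycles
#'   (default 1, annual).
#' @param discount_cycle_offset Discount factor for cycle `k` is
#'   `(1 + r)^-(k + offset)`; the default 0 leaves cycle 0 undiscounted.
#' @param half_cycle_correction If `TRUE`, per-cycle rewards use the average
#'   of start-of-cycle and end-of-cycle occupancy. Default `FALSE`.
#' @return A list of settings.
#' @export
analysis_settings <- function(horizon_cycles = 55L, cycle_length = 1,
                              start_age = 20L, discount_rate = 0.05,
                              wtp_threshold = 50000, psa_draws = 1000L,
                              rng_seed = 1L, mtn_instant = TRUE,
                              exam_states = c("alive", "health", "health_btn", "none"),
                              nf_states = c("btn", "health_btn", "none"),
                              tf_arms = c("SG", "NSG", "both", "none"),
                              ct_timing = c("entry", "percycle"),
                              exam_interval = 1L,
                              discount_cycle_offset = 0,
                              half_cycle_correction = FALSE) {
  list(
    horizon_cycles = as.integer(horizon_cycles),
    cycle_length = cycle_length,
    start_age = as.integer(start_age),
    discount_rate = discount_rate,
    wtp_threshold = wtp_threshold,
    psa_draws = as.integer(psa_draws),
    rng_seed = as.integer(rng_seed),
    mtn_instant = isTRUE(mtn_instant),
    exam_states = match.arg(exam_states),
    nf_states = match.arg(nf_states),
    tf_arms = match.arg(tf_arms),
    ct_timing = match.arg(ct_timing),
    exam_interval = as.integer(exam_interval),
    discount_cycle_offset = discount_cycle_offset,
    half_cycle_correction = isTRUE(half_cycle_correction)
  )
}

#' Validate a model specification
#'
#' Checks structural invariants: six states; utilities in `[0, 1]` with
#' health 1 and death 0; non-negative costs with ultrasound examination
#' costing more than the routine physical; transition probabilities in
#' `[0, 1]`; benign-to-malignant progression and post-operative recurrence
#' identical across strategies; competing per-row probabilities never
#' exceeding 1 at any age within the horizon; a usable life table; and
#' coherent sensitivity ranges.
#'
#' @param spec A [model_spec()].
#' @return Character vector of violations; empty when the spec is valid.
#' @export
validate_model <- function(spec) {
  bad <- character()
  say <- function(...) bad[[length(bad) + 1L]] <<- sprintf(...)
  if (!inherits(spec, "model_spec")) {
    return("not a model_spec object")
  }
  st <- health_states()
  u <- spec$utilities
  if (!all(st %in% names(u)) || length(u) != 6L) {
    say("utilities must be named over exactly the six health states")
  } else {
    for (s in st) {
      if (!is.finite(u[[s]]) || u[[s]] < 0 || u[[s]] > 1) {
        say("utility '%s' = %g outside [0, 1]", s, u[[s]])
      }
    }
    if (is.finite(u[["death"]]) && u[["death"]] != 0) say("death utility must be 0")
    if (is.finite(u[["health"]]) && u[["health"]] != 1) say("health utility must be 1")
  }
  cost_names <- c("c_t", "c_n", "c_o", "c_tf", "c_nf", "c_recurrence")
  co <- spec$costs
  if (!all(cost_names %in% names(co))) {
    say("costs must contain %s", paste(cost_names, collapse = ", "))
  } else {
    for (nm in cost_names) {
      if (!is.finite(co[[nm]]) || co[[nm]] < 0) say("cost '%s' must be >= 0", nm)
    }
    if (is.finite(co[["c_n"]]) && is.finite(co[["c_o"]]) && co[["c_n"]] <= co[["c_o"]]) {
      say("ultrasound examination cost c_n = %g must exceed routine examination cost c_o = %g",
          co[["c_n"]], co[["c_o"]])
    }
  }
  tp_names <- c("p_health_btn", "p_health_mtn", "p_btn_mtn", "p_mtn_death",
                "p_postop_recurrence")
  tr <- spec$transitions
  if (!all(c("SG", "NSG") %in% names(tr))) {
    say("transitions must contain strategies SG and NSG")
  } else {
    for (arm in c("SG", "NSG")) {
      v <- tr[[arm]]
      if (!all(tp_names %in% names(v))) {
        say("%s transitions must contain %s", arm, paste(tp_names, collapse = ", "))
        next
      }
      for (nm in tp_names) {
        if (!is.finite(v[[nm]]) || v[[nm]] < 0 || v[[nm]] > 1) {
          say("%s probability '%s' = %g outside [0, 1]", arm, nm, v[[nm]])
        }
      }
    }
    if (all(tp_names %in% names(tr$SG)) && all(tp_names %in% names(tr$NSG))) {
      for (nm in c("p_btn_mtn", "p_postop_recurrence")) {
        if (isTRUE(tr$SG[[nm]] != tr$NSG[[nm]])) {
          say("'%s' must be identical across strategies (same surgery, same recurrence)", nm)
        }
      }
    }
  }
  lt <- spec$life_table
  if (!is.data.frame(lt) || !all(c("age", "q") %in% names(lt)) || nrow(lt) < 1L) {
    say("life_table must be a data frame with columns age and q")
  } else if (any(!is.finite(lt$q)) || any(lt$q < 0) || any(lt$q > 1)) {
    say("life-table mortality q must lie in [0, 1]")
  } else if (all(c("SG", "NSG") %in% names(tr))) {
    # competing risks must leave room for a non-negative self-loop at every age
    se <- spec$settings
    ages <- se$start_age + seq_len(se$horizon_cycles) - 1L
    qs <- lookup_mortality(lt, ages)
    for (arm in c("SG", "NSG")) {
      v <- tr[[arm]]
      if (!all(tp_names %in% names(v)) || any(!is.finite(unlist(v[tp_names])))) next
      rows <- c(
        health = max(v[["p_health_btn"]] + v[["p_health_mtn"]] + qs),
        btn = max(v[["p_btn_mtn"]] + qs),
        mtn = max(v[["p_mtn_death"]] + qs),
        postop = max(v[["p_postop_recurrence"]] + qs)
      )
      for (nm in names(rows)) {
        if (rows[[nm]] > 1) {
          say("%s: competing probabilities leaving '%s' sum to %g > 1 within the horizon",
              arm, nm, rows[[nm]])
        }
      }
    }
  }
  if (length(spec$distributions)) {
    for (nm in names(spec$distributions)) {
      d <- spec$distributions[[nm]]
      if (!inherits(d, "param_dist")) {
        say("distribution '%s' is not a param_dist", nm)
      } else if (!(d$range_low <= d$base_value && d$base_value <= d$range_high)) {
        say("distribution '%s': range does not bracket base value", nm)
      }
    }
  }
  se <- spec$settings
  if (!is.list(se) || is.null(se$horizon_cycles) || se$horizon_cycles < 1L) {
    say("settings horizon_cycles must be >= 1")
  } else if (se$discount_rate < 0 || se$discount_rate >= 1) {
    say("settings discount_rate must lie in [0, 1)")
  }
  bad
}

# last-row carry-forward for ages beyond the table
lookup_mortality <- function(life_table, ages) {
  idx <- findInterval(ages, life_table$age)
  idx[idx < 1L] <- 1L
  life_table$q[idx]
}

#' Build the per-cycle transition matrix for one strategy at one age
#'
#' Rows follow [health_states()]. The health row allocates nodule incidence,
#' cancer incidence and background mortality `q(age)`, remainder to itself;
#' the benign-nodule row allocates progression and `q`; the cancer row sends
#' excess cancer mortality plus `q` to death and the full remaining
#' probability to post-operative stability; the post-operative row allocates
#' recurrence and `q`; recurrence is absorbing apart from background
#' mortality; death is absorbing.
#'
#' @param spec A valid [model_spec()].
#' @param strategy `"SG"` (screening) or `"NSG"` (non-screening).
#' @param age Age in years of the cohort during the cycle.
#' @return A 6 x 6 row-stochastic matrix.
#' @export
build_transition_matrix <- function(spec, strategy = c("SG", "NSG"), age) {
  strategy <- match.arg(strategy)
  tp <- spec$transitions[[strategy]]
  q <- lookup_mortality(spec$life_table, age)
  P <- transition_matrix_at(tp, q)
  rs <- rowSums(P)
  if (any(P < 0) || any(abs(rs - 1) > 1e-12)) {
    stop(sprintf(
      "competing probabilities exceed 1 for strategy %s at age %s", strategy, age
    ), call. = FALSE)
  }
  P
}

# core matrix assembly, no validation (hot path for the engines)
transition_matrix_at <- function(tp, q) {
  st <- health_states()
  P <- matrix(0, 6L, 6L, dimnames = list(st, st))
  hb <- tp[["p_health_btn"]]; hm <- tp[["p_health_mtn"]]
  bm <- tp[["p_btn_mtn"]]; md <- tp[["p_mtn_death"]]
  pr <- tp[["p_postop_recurrence"]]
  P[1L, 2L] <- hb; P[1L, 3L] <- hm; P[1L, 6L] <- q
  P[1L, 1L] <- 1 - hb - hm - q
  P[2L, 3L] <- bm; P[2L, 6L] <- q; P[2L, 2L] <- 1 - bm - q
  P[3L, 6L] <- md + q; P[3L, 4L] <- 1 - md - q
  P[4L, 5L] <- pr; P[4L, 6L] <- q; P[4L, 4L] <- 1 - pr - q
  P[5L, 6L] <- q; P[5L, 5L] <- 1 - q
  P[6L, 6L] <- 1
  P
}

#' The bundled thyroid-screening model specification
#'
#' The full base-case parameterization of the ultrasound screening versus
#' non-screening comparison: per-state utilities with beta uncertainty,
#' cost components in 2017 USD with gamma uncertainty, annual transition
#' probabilities per strategy with beta uncertainty, a 55-cycle horizon from
#' age 20 with 5 percent annual discounting and a 50,000 USD/QALY threshold.
#' Background mortality defaults to a synthetic Gompertz-Makeham life table
#' calibrated to a life expectancy of 80 years (see [synthetic_life_table()]).
#'
#' The printed range for recurrence care cost is garbled in the source
#' tables; its upper bound is repaired as 1.5 times the base value.
#'
#' @param life_table Optional replacement life table (data frame with columns
#'   `age`, `q`).
#' @param ... Overrides passed to [analysis_settings()].
#' @return A validated `model_spec`.
#' @export
thyroid_screening_spec <- function(life_table = NULL, ...) {
  if (is.null(life_table)) {
    life_table <- synthetic_life_table(80)
  }
  utilities <- c(health = 1, btn = 0.99, mtn = 0.60, postop = 0.99,
                 recurrence = 0.54, death = 0)
  costs <- c(c_t = 20174.5786, c_n = 251.46, c_tf = 1264.9032,
             c_nf = 798.6, c_recurrence = 6050.22, c_o = 50.16)
  transitions <- list(
    SG = c(p_health_btn = 0.19, p_health_mtn = 0.000039,
           p_btn_mtn = 0.00854478, p_mtn_death = 0.000003,
           p_postop_recurrence = 0.001029),
    NSG = c(p_health_btn = 0.68, p_health_mtn = 0.000583,
            p_btn_mtn = 0.00854478, p_mtn_death = 0.000005,
            p_postop_recurrence = 0.001029)
  )
  distributions <- list(
    u_recurrence = param_dist("beta", 0.54, 176, 150, 0.49, 0.59),
    u_postop = param_dist("beta", 0.99, 1, 0, 0.74, 1.00),
    u_mtn = param_dist("beta", 0.60, 153, 102, 0.54, 0.66),
    u_btn = param_dist("beta", 0.99, 100, 1, 0.89, 1.00),
    c_t = param_dist("gamma", 20174.5786, 29, 706, 16737.47, 24283.81),
    c_n = param_dist("gamma", 251.46, 7, 34, 126.06, 311.52),
    c_tf = param_dist("gamma", 1264.9032, 3, 492, 731.99, 2309.31),
    c_nf = param_dist("gamma", 798.6, 2, 449, 399.30, 1597.20),
    c_recurrence = param_dist("gamma", 6050.22, 4, 1513, 3024.78, 9075.33),
    c_o = param_dist("gamma", 50.16, 4, 13, 25.08, 75.24),
    p_health_btn_sg = param_dist("beta", 0.19, 50, 211, 0.14, 0.24),
    p_health_btn_nsg = param_dist("beta", 0.68, 19, 9, 0.51, 0.85),
    p_health_mtn_sg = param_dist("beta", 0.000039, 62, 1575948, 0.000029, 0.000049),
    p_health_mtn_nsg = param_dist("beta", 0.000583, 61, 105337, 0.000437, 0.000729),
    p_btn_mtn = param_dist("beta", 0.00854478, 61, 7070, 0.00640859, 0.01068098),
    p_mtn_death_sg = param_dist("beta", 0.000003, 62, 23640522, 0.00000195, 0.00000325),
    p_mtn_death_nsg = param_dist("beta", 0.000005, 62, 11175470, 0.000004, 0.000007),
    p_postop_recurrence = param_dist("beta", 0.001029, 61, 59621, 0.000772, 0.001286)
  )
  spec <- model_spec(utilities, costs, transitions, distributions,
                     analysis_settings(...), life_table)
  bad <- validate_model(spec)
  if (length(bad)) {
    stop("bundled specification failed validation:\n",
         paste("-", bad, collapse = "\n"), call. = FALSE)
  }
  spec
}

# Where each named uncertain parameter lives in the spec. Shared transition
# parameters (progression, recurrence) are applied to both arms together.
param_target <- function(name) {
  if (name %in% c("u_recurrence", "u_postop", "u_mtn", "u_btn", "u_health")) {
    return(list(slot = "utilities",
                key = sub("^u_", "", name)))
  }
  if (grepl("^c_", name)) {
    return(list(slot = "costs", key = name))
  }
  arm <- if (grepl("_sg$", name)) "SG" else if (grepl("_nsg$", name)) "NSG" else "both"
  key <- sub("_(sg|nsg)$", "", name)
  key <- switch(key,
    p_health_btn = "p_health_btn", p_health_mtn = "p_health_mtn",
    p_btn_mtn = "p_btn_mtn", p_mtn_death = "p_mtn_death",
    p_postop_recurrence = "p_postop_recurrence",
    stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
  )
  list(slot = "transitions", key = key, arm = arm)
}

#' Set a named parameter in a model specification
#'
#' Utilities are addressed as `u_btn`, `u_postop`, `u_mtn`, `u_recurrence`;
#' costs by their component name (`c_t`, `c_n`, ...); transition
#' probabilities as e.g. `p_health_btn_sg` / `p_health_btn_nsg` for
#' strategy-specific rates or `p_btn_mtn` / `p_postop_recurrence` for rates
#' shared across strategies (set in both arms together).
#'
#' @param spec A [model_spec()].
#' @param name Parameter name.
#' @param value New value.
#' @return The modified `model_spec` (the distribution metadata is left
#'   untouched; only the deterministic value changes).
#' @export
set_parameter <- function(spec, name, value) {
  tg <- param_target(name)
  if (tg$slot == "utilities") {
    if (!tg$key %in% names(spec$utilities)) {
      stop(sprintf("unknown utility '%s'", name), call. = FALSE)
    }
    spec$utilities[[tg$key]] <- value
  } else if (tg$slot == "costs") {
    if (!tg$key %in% names(spec$costs)) {
      stop(sprintf("unknown cost '%s'", name), call. = FALSE)
    }
    spec$costs[[tg$key]] <- value
  } else {
    arms <- if (tg$arm == "both") c("SG", "NSG") else tg$arm
    for (arm in arms) spec$transitions[[arm]][[tg$key]] <- value
  }
  spec
}

# read the current deterministic value of a named parameter
get_parameter <- function(spec, name) {
  tg <- param_target(name)
  if (tg$slot == "utilities") return(spec$utilities[[tg$key]])
  if (tg$slot == "costs") return(spec$costs[[tg$key]])
  arm <- if (tg$arm == "both") "SG" else tg$arm
  spec$transitions[[arm]][[tg$key]]
}

#' @export
print.model_spec <- function(x, ...) {
  se <- x$settings
  cat("<model_spec> 6-state Markov cohort decision model\n")
  cat(sprintf("  horizon: %d annual cycles from age %d, discount %.1f%%/yr\n",
              se$horizon_cycles, se$start_age, 100 * se$discount_rate))
  cat(sprintf("  WTP threshold: $%s/QALY; %d uncertain parameters\n",
              format(se$wtp_threshold, big.mark = ","),
              length(x$distributions)))
  cat(sprintf("  switches: mtn_instant=%s exam=%s nf=%s tf=%s ct=%s\n",
              se$mtn_instant, se$exam_states, se$nf_states, se$tf_arms,
              se$ct_timing))
  nv <- length(validate_model(x))
  cat(if (nv == 0L) "  valid\n" else sprintf("  INVALID: %d violation(s)\n", nv))
  invisible(x)
}
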
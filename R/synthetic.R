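# Synthetic inputs: a parametric Gompertz-Makeham life-table generator,
# analytically solvable toy models, and random valid model specifications for
# property testing. Everything here is generated in code; no external data.

#' Synthetic Gompertz-Makeham life table
#'
#' Annual background mortality follows the Gompertz-Makeham hazard
#' `mu(age) = A + B exp(theta * age)`: an age-independent accident floor `A`
#' plus exponentially increasing senescent mortality. The Gompertz level `B`
#' is calibrated by root finding so that period life expectancy at birth
#' matches the target within 0.5 years. Annual death probabilities are
#' `q(age) = 1 - exp(-mu(age))`, which are nondecreasing in age.
#'
#' @param target_life_expectancy Target period life expectancy at birth in
#'   years; must lie in `(40, max_age)`.
#' @param max_age Last tabulated age (default 110); older ages reuse the
#'   last row.
#' @param makeham_a Accident floor `A` (default 6e-4, about the young-adult
#'   mortality of a high-income population).
#' @param gompertz_theta Senescence slope `theta` (default 0.095, a doubling
#'   of mortality roughly every 7 years).
#' @return A data frame of class `life_table` with columns `age` (0 to
#'   `max_age`) and `q`, and attribute `life_expectancy` (the achieved
#'   value).
#' @export
synthetic_life_table <- function(target_life_expectancy = 80, max_age = 110L,
                                 makeham_a = 6e-4, gompertz_theta = 0.095) {
  if (!(target_life_expectancy > 40 && target_life_expectancy < max_age)) {
    stop("`target_life_expectancy` must lie in (40, max_age)", call. = FALSE)
  }
  ages <- 0:max_age
  le_given_b <- function(B) {
    q <- 1 - exp(-(makeham_a + B * exp(gompertz_theta * ages)))
    S <- cumprod(1 - q)
    # person-years: survivors contribute a full year, deaths half a year
    sum(S) + 0.5
  }
  obj <- function(logB) le_given_b(exp(logB)) - target_life_expectancy
  lo <- log(1e-12)
  hi <- log(0.5)
  if (obj(lo) < 0 || obj(hi) > 0) {
    stop("life-table calibration failure: target life expectancy unattainable with these hazard parameters",
         call. = FALSE)
  }
  root <- stats::uniroot(obj, c(lo, hi), tol = 1e-13)
  B <- exp(root$root)
  q <- 1 - exp(-(makeham_a + B * exp(gompertz_theta * ages)))
  achieved <- le_given_b(B)
  if (abs(achieved - target_life_expectancy) > 0.5) {
    stop(sprintf(
      "life-table calibration failure: achieved life expectancy %.2f vs target %.2f",
      achieved, target_life_expectancy), call. = FALSE)
  }
  structure(data.frame(age = ages, q = q),
            life_expectancy = achieved,
            gompertz_b = B,
            makeham_a = makeham_a,
            gompertz_theta = gompertz_theta,
            class = c("life_table", "data.frame"))
}

#' Read or write a life table as a two-column CSV
#'
#' @param path CSV file with columns `age` and `q`.
#' @return For `read_life_table`, a `life_table` data frame.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "q") %in% names(df))) {
    stop("life-table CSV must have columns 'age' and 'q'", call. = FALSE)
  }
  structure(df[, c("age", "q")], class = c("life_table", "data.frame"))
}

#' @rdname read_life_table
#' @param life_table A life table data frame.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table)[, c("age", "q")], path,
                   row.names = FALSE)
  invisible(path)
}

# a spec skeleton with all disease dynamics switched off; toys build on this
blank_spec <- function(horizon, discount_rate, q_const,
                       utilities = c(health = 1, btn = 1, mtn = 1, postop = 1,
                                     recurrence = 1, death = 0),
                       costs = c(c_t = 0, c_n = 1, c_tf = 0, c_nf = 0,
                                 c_recurrence = 0, c_o = 0),
                       exam_states = "none", ...) {
  zero <- c(p_health_btn = 0, p_health_mtn = 0, p_btn_mtn = 0,
            p_mtn_death = 0, p_postop_recurrence = 0)
  lt <- data.frame(age = 0:110, q = q_const)
  model_spec(
    utilities = utilities, costs = costs,
    transitions = list(SG = zero, NSG = zero),
    distributions = list(),
    settings = analysis_settings(horizon_cycles = horizon,
                                 discount_rate = discount_rate,
                                 exam_states = exam_states, ...),
    life_table = lt
  )
}

#' Two-state alive/dead toy model with closed-form discounted QALYs
#'
#' The cohort starts healthy, dies with constant annual probability
#' `p_death`, accrues utility 1 while alive and no costs. The exact
#' discounted QALY total over horizon `H` is the geometric sum
#' `sum_{k=0}^{H-1} ((1 - p_death) / (1 + r))^k`, the oracle against which
#' the cohort engine is validated to numerical precision.
#'
#' @param p_death Constant annual death probability in `[0, 1]`.
#' @param r Annual discount rate (default 0).
#' @param horizon Number of cycles (default 55).
#' @return A list with elements `spec` (a valid `model_spec`) and
#'   `expected_qaly` (the closed form).
#' @export
toy_geometric_model <- function(p_death, r = 0, horizon = 55L) {
  stopifnot(p_death >= 0, p_death <= 1)
  spec <- blank_spec(horizon, r, q_const = p_death)
  k <- 0:(horizon - 1L)
  structure(
    list(spec = spec,
         expected_qaly = sum(((1 - p_death) / (1 + r))^k)),
    class = "toy_model"
  )
}

#' Catalog of analytically solvable toy models
#'
#' Named toy scenarios whose discounted costs and QALYs have closed forms,
#' stored alongside the model so the cohort engine can be checked against
#' exact values: an immortal discounted cohort, geometric survival with and
#' without discounting, and a costed variant in which every survivor pays a
#' constant per-cycle examination fee.
#'
#' @return A named list; each entry has `spec`, `expected_qaly`,
#'   `expected_cost` and a `note` describing the closed form.
#' @export
toy_model_catalog <- function() {
  geom <- function(a, H) sum(a^(0:(H - 1L)))
  out <- list()
  out$immortal_discounted <- {
    tm <- toy_geometric_model(0, r = 0.05, horizon = 3L)
    list(spec = tm$spec, expected_qaly = geom(1 / 1.05, 3L), expected_cost = 0,
         note = "no mortality, r = 5%, H = 3: 1 + 1/1.05 + 1/1.05^2")
  }
  out$geometric_undiscounted <- {
    tm <- toy_geometric_model(0.1, r = 0, horizon = 3L)
    list(spec = tm$spec, expected_qaly = geom(0.9, 3L), expected_cost = 0,
         note = "p_death = 0.1, r = 0, H = 3: 1 + 0.9 + 0.81")
  }
  out$geometric_discounted <- {
    tm <- toy_geometric_model(0.1, r = 0.05, horizon = 55L)
    list(spec = tm$spec, expected_qaly = geom(0.9 / 1.05, 55L),
         expected_cost = 0,
         note = "p_death = 0.1, r = 5%, H = 55: geometric sum")
  }
  out$costed_survival <- {
    tm <- toy_geometric_model(0.2, r = 0.03, horizon = 20L)
    sp <- tm$spec
    sp$settings$exam_states <- "alive"
    sp$costs[["c_n"]] <- 120
    list(spec = sp, expected_qaly = geom(0.8 / 1.03, 20L),
         expected_cost = 120 * geom(0.8 / 1.03, 20L),
         note = "survivors pay $120/cycle (screening arm): cost = 120 x QALY sum")
  }
  out
}

#' Recipe for random model generation
#'
#' Bounds are chosen so that any spec drawn from them is valid by
#' construction: probabilities leave room for background mortality in every
#' competing-risk row, the ultrasound examination always costs more than the
#' routine physical, and utilities respect the dead-healthy anchors.
#'
#' @param seed Integer seed.
#' @param horizon_range,discount_range,utility_range,prob_scale,cost_scale
#'   Ranges controlling the magnitudes of drawn quantities.
#' @param life_expectancy_range Range of the synthetic life-table target.
#' @return An object of class `scenario_recipe`.
#' @export
scenario_recipe <- function(seed = 1L,
                            horizon_range = c(10L, 55L),
                            discount_range = c(0, 0.07),
                            utility_range = c(0.3, 1),
                            prob_scale = c(1e-5, 0.3),
                            cost_scale = c(10, 30000),
                            life_expectancy_range = c(65, 90)) {
  stopifnot(horizon_range[1] >= 1L, prob_scale[2] <= 0.5,
            cost_scale[1] > 0, utility_range[1] >= 0, utility_range[2] <= 1)
  structure(
    list(seed = as.integer(seed), horizon_range = horizon_range,
         discount_range = discount_range, utility_range = utility_range,
         prob_scale = prob_scale, cost_scale = cost_scale,
         life_expectancy_range = life_expectancy_range),
    class = "scenario_recipe"
  )
}

#' Generate a random valid model specification
#'
#' Draws utilities, costs, transition probabilities, matching parameter
#' distributions (moment-matched betas for probabilities and utilities,
#' gammas for costs) and a synthetic life table from a [scenario_recipe()].
#' The output always passes [validate_model()]; the same recipe yields the
#' identical spec.
#'
#' @param recipe A [scenario_recipe()].
#' @return A valid `model_spec`.
#' @export
generate_random_model <- function(recipe = scenario_recipe()) {
  stopifnot(inherits(recipe, "scenario_recipe"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(recipe$seed)
  runif1 <- function(rg) stats::runif(1, rg[1], rg[2])
  ur <- recipe$utility_range
  utilities <- c(health = 1,
                 btn = runif1(c(mean(ur), 1)),
                 mtn = runif1(ur),
                 postop = runif1(c(mean(ur), 1)),
                 recurrence = runif1(ur),
                 death = 0)
  cs <- recipe$cost_scale
  c_o <- runif1(c(cs[1], cs[1] * 5))
  costs <- c(c_t = runif1(c(cs[2] / 4, cs[2])),
             c_n = c_o + runif1(c(cs[1], cs[1] * 20)),
             c_tf = runif1(c(cs[1], cs[2] / 10)),
             c_nf = runif1(c(cs[1], cs[2] / 10)),
             c_recurrence = runif1(c(cs[1], cs[2] / 3)),
             c_o = c_o)
  ps <- recipe$prob_scale
  draw_p <- function(hi = ps[2]) runif1(c(ps[1], hi))
  shared_bm <- draw_p(0.05)
  shared_pr <- draw_p(0.02)
  mk_arm <- function() c(p_health_btn = draw_p(),
                         p_health_mtn = draw_p(0.002),
                         p_btn_mtn = shared_bm,
                         p_mtn_death = draw_p(0.01),
                         p_postop_recurrence = shared_pr)
  transitions <- list(SG = mk_arm(), NSG = mk_arm())
  le <- runif1(recipe$life_expectancy_range)
  lt <- synthetic_life_table(le)
  horizon <- sample(seq(recipe$horizon_range[1], recipe$horizon_range[2]), 1L)
  r <- runif1(recipe$discount_range)
  dist_for <- function(name, value, kind) {
    if (kind == "cost") {
      param_dist("gamma", value, shape_a = 16, shape_b = value / 16)
    } else {
      sd <- repair_sd(value, max(0, value * 0.9), min(1, value * 1.1))
      if (value <= 0 || value >= 1 || sd <= 0) {
        param_dist("fixed", value, range_low = value, range_high = value)
      } else {
        sh <- beta_moment_match(value, sd)
        param_dist("beta", value, sh[["shape1"]], sh[["shape2"]])
      }
    }
  }
  distributions <- list(
    u_btn = dist_for("u_btn", utilities[["btn"]], "prob"),
    u_mtn = dist_for("u_mtn", utilities[["mtn"]], "prob"),
    u_postop = dist_for("u_postop", utilities[["postop"]], "prob"),
    u_recurrence = dist_for("u_recurrence", utilities[["recurrence"]], "prob"),
    c_t = dist_for("c_t", costs[["c_t"]], "cost"),
    c_n = dist_for("c_n", costs[["c_n"]], "cost"),
    c_tf = dist_for("c_tf", costs[["c_tf"]], "cost"),
    c_nf = dist_for("c_nf", costs[["c_nf"]], "cost"),
    c_recurrence = dist_for("c_recurrence", costs[["c_recurrence"]], "cost"),
    c_o = dist_for("c_o", costs[["c_o"]], "cost"),
    p_health_btn_sg = dist_for("p", transitions$SG[["p_health_btn"]], "prob"),
    p_health_btn_nsg = dist_for("p", transitions$NSG[["p_health_btn"]], "prob"),
    p_health_mtn_sg = dist_for("p", transitions$SG[["p_health_mtn"]], "prob"),
    p_health_mtn_nsg = dist_for("p", transitions$NSG[["p_health_mtn"]], "prob"),
    p_btn_mtn = dist_for("p", shared_bm, "prob"),
    p_mtn_death_sg = dist_for("p", transitions$SG[["p_mtn_death"]], "prob"),
    p_mtn_death_nsg = dist_for("p", transitions$NSG[["p_mtn_death"]], "prob"),
    p_postop_recurrence = dist_for("p", shared_pr, "prob")
  )
  spec <- model_spec(
    utilities, costs, transitions, distributions,
    analysis_settings(horizon_cycles = horizon, discount_rate = r,
                      start_age = 20L,
                      mtn_instant = stats::runif(1) < 0.5),
    lt
  )
  bad <- validate_model(spec)
  if (length(bad)) {
    stop("internal error: generated spec failed validation:\n",
         paste("-", bad, collapse = "\n"), call. = FALSE)
  }
  spec
}
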
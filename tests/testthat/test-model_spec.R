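# Domain types: probability conversion, validation, transition matrices and
# distribution handling.

test_that("annualize_probability matches hand arithmetic and rejects bad input", {
  expect_equal(annualize_probability(0.75, 2), 0.5)
  expect_equal(annualize_probability(0.19, 1), 0.19)
  expect_equal(annualize_probability(0, 20), 0)
  expect_equal(annualize_probability(1, 5), 1)
  expect_error(annualize_probability(-0.1, 2), "probability")
  expect_error(annualize_probability(1.1, 2), "probability")
  expect_error(annualize_probability(0.5, 0), "duration")
})

test_that("annualize_probability inverts multi-year compounding", {
  # algebraic inverse: compound an annual probability over t years, then
  # annualize the cumulative value back
  for (p_annual in c(0.00854478, 0.001029, 0.19, 0.5)) {
    for (t in c(2, 5, 20)) {
      p_cum <- 1 - (1 - p_annual)^t
      expect_equal(annualize_probability(p_cum, t), p_annual,
                   tolerance = 1e-12)
    }
  }
})

test_that("annualize_probability is monotone in p_cum and in 1/t", {
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(annualize_probability(p, 7)) > 0))
  ts <- c(1, 2, 4, 8, 16)
  vals <- vapply(ts, function(t) annualize_probability(0.4, t), numeric(1))
  expect_true(all(diff(vals) < 0)) # longer exposure window, smaller annual rate
})

test_that("the bundled specification is valid and fully parameterized", {
  spec <- paper_spec()
  expect_no_violations(spec)
  expect_identical(sort(names(spec$utilities)), sort(health_states()))
  expect_length(spec$distributions, 18L)
  expect_equal(spec$costs[["c_t"]], 20174.5786)
  expect_equal(spec$settings$horizon_cycles, 55L)
  expect_equal(spec$settings$discount_rate, 0.05)
})

test_that("validation names the offending quantity", {
  spec <- paper_spec()
  bad_u <- spec
  bad_u$utilities[["btn"]] <- 1.2
  v <- validate_model(bad_u)
  expect_length(v, 1L)
  expect_match(v, "btn")
  bad_p <- spec
  bad_p$transitions$SG[["p_health_btn"]] <- -0.1
  v <- validate_model(bad_p)
  expect_length(v, 1L)
  expect_match(v, "p_health_btn")
  bad_cost <- spec
  bad_cost$costs[["c_n"]] <- 10 # below the routine examination cost
  expect_match(validate_model(bad_cost), "c_n")
  bad_shared <- spec
  bad_shared$transitions$NSG[["p_btn_mtn"]] <- 0.02
  expect_match(validate_model(bad_shared), "p_btn_mtn")
})

test_that("transition matrices carry the printed incidences and are row-stochastic", {
  spec <- paper_spec()
  P_sg <- build_transition_matrix(spec, "SG", 20)
  expect_equal(P_sg["health", "btn"], 0.19)
  expect_equal(P_sg["health", "mtn"], 0.000039)
  P_nsg <- build_transition_matrix(spec, "NSG", 20)
  expect_equal(P_nsg["health", "mtn"], 0.000583)
  for (age in seq(20, 75, by = 5)) {
    for (arm in c("SG", "NSG")) {
      P <- build_transition_matrix(spec, arm, age)
      expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_true(all(P >= 0))
    }
  }
  # death and recurrence leave only through background mortality / not at all
  expect_equal(P_sg["death", "death"], 1)
  expect_equal(sum(P_sg["recurrence", c("recurrence", "death")]), 1)
})

test_that("competing probabilities above one are rejected", {
  spec <- paper_spec()
  spec$transitions$SG[["p_health_btn"]] <- 0.7
  spec$transitions$SG[["p_health_mtn"]] <- 0.4
  expect_error(build_transition_matrix(spec, "SG", 20), "exceed 1")
  expect_match(validate_model(spec), "health", all = FALSE)
})

test_that("row-stochasticity holds across random specifications", {
  for (s in 1:20) {
    spec <- generate_random_model(scenario_recipe(seed = s))
    ages <- spec$settings$start_age +
      c(0L, spec$settings$horizon_cycles - 1L)
    for (arm in c("SG", "NSG")) {
      for (age in ages) {
        P <- build_transition_matrix(spec, arm, age)
        expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("gamma distributions resolve as shape times scale", {
  spec <- paper_spec()
  rd <- resolve_distribution(spec$distributions$c_t)
  expect_equal(rd$mean, 29 * 706) # 20,474: 1.5% above the printed base
  expect_equal(rd$mean / rd$base_value, 1.0148, tolerance = 1e-3)
  # the recurrence-care and routine-exam scales reproduce their bases closely
  expect_equal(resolve_distribution(spec$distributions$c_recurrence)$mean,
               6050.22, tolerance = 0.001)
  expect_equal(resolve_distribution(spec$distributions$c_o)$mean,
               50.16, tolerance = 0.04)
  expect_error(resolve_distribution(param_dist("gamma", 10, -1, 5)),
               "positive")
})

test_that("beta distributions resolve to their printed means", {
  spec <- paper_spec()
  rd <- resolve_distribution(spec$distributions$u_recurrence)
  expect_equal(rd$mean, 176 / 326)
  expect_equal(rd$mean, 0.54, tolerance = 1e-3)
  expect_false(rd$repaired)
  rd <- resolve_distribution(spec$distributions$p_health_btn_nsg)
  expect_equal(rd$mean, 19 / 28)
})

test_that("moment matching reproduces textbook shapes", {
  sh <- beta_moment_match(0.5, 0.1)
  expect_equal(unname(sh), c(12, 12))
  expect_error(beta_moment_match(0.5, 0.6), "infeasible")
})

test_that("an unusable printed beta is repaired to a mean-preserving beta", {
  # method-of-moments oracle: mean a/(a+b) must equal the base value and the
  # implied sd must keep the symmetric 2-sd interval inside range and [0,1]
  d <- param_dist("beta", 0.99, 1, 0, 0.74, 1.00)
  rd <- resolve_distribution(d)
  expect_true(rd$repaired)
  expect_equal(rd$shape_a / (rd$shape_a + rd$shape_b), 0.99, tolerance = 1e-9)
  sd_implied <- sqrt(rd$shape_a * rd$shape_b /
                       ((rd$shape_a + rd$shape_b)^2 * (rd$shape_a + rd$shape_b + 1)))
  expect_lte(0.99 + 2 * sd_implied, 1 + 1e-9)
  expect_gte(0.99 - 2 * sd_implied, 0.74 - 1e-9)
  # a centred base keeps the plain quarter-range rule
  d2 <- param_dist("beta", 0.5, NA, NA, 0.3, 0.7)
  rd2 <- resolve_distribution(d2)
  sh <- beta_moment_match(0.5, 0.1)
  expect_equal(rd2$shape_a, sh[["shape1"]], tolerance = 1e-9)
})

test_that("fixed parameters always return the base value", {
  rd <- resolve_distribution(param_dist("fixed", 3.25))
  expect_identical(sample_resolved(rd, 5L), rep(3.25, 5L))
})

test_that("set_parameter writes shared transitions into both arms", {
  spec <- paper_spec()
  sp <- set_parameter(spec, "p_btn_mtn", 0.01)
  expect_equal(sp$transitions$SG[["p_btn_mtn"]], 0.01)
  expect_equal(sp$transitions$NSG[["p_btn_mtn"]], 0.01)
  sp <- set_parameter(spec, "p_health_btn_nsg", 0.5)
  expect_equal(sp$transitions$NSG[["p_health_btn"]], 0.5)
  expect_equal(sp$transitions$SG[["p_health_btn"]], 0.19)
  expect_error(set_parameter(spec, "p_nonsense", 1), "unknown")
})
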
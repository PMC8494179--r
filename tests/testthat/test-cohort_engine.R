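# Cohort engine: closed-form oracles, conservation, monotonicity, and the
# microsimulation cross-check.

test_that("a cost-free immortal cohort accrues the discounted annuity", {
  tm <- toy_geometric_model(0, r = 0.05, horizon = 3L)
  out <- run_cohort(tm$spec, "SG")
  expect_equal(out$total_qaly, 1 + 1 / 1.05 + 1 / 1.05^2, tolerance = 1e-12)
  expect_equal(out$total_cost, 0)
})

test_that("zero utilities yield zero QALYs", {
  sp <- toy_geometric_model(0.05, r = 0.03, horizon = 10L)$spec
  sp$utilities[health_states()] <- 0
  # the engine core honours whatever utilities it is given (the public
  # entry point would veto the broken dead-healthy anchors)
  out <- thyrocea:::run_cohort_core(sp, "SG")
  expect_identical(out$total_qaly, 0)
})

test_that("every catalog toy matches its closed form to 1e-9", {
  for (nm in names(toy_model_catalog())) {
    entry <- toy_model_catalog()[[nm]]
    out <- run_cohort(entry$spec, "SG")
    expect_equal(out$total_qaly, entry$expected_qaly, tolerance = 1e-9,
                 label = sprintf("%s QALY", nm))
    expect_equal(out$total_cost, entry$expected_cost, tolerance = 1e-9,
                 label = sprintf("%s cost", nm))
  }
})

test_that("with no discounting and no mortality the QALY total is the horizon", {
  tm <- toy_geometric_model(0, r = 0, horizon = 41L)
  out <- run_cohort(tm$spec, "SG")
  expect_identical(out$total_qaly, 41)
})

test_that("cohort mass is conserved and traces start healthy", {
  spec <- paper_spec()
  for (arm in c("SG", "NSG")) {
    out <- run_cohort(spec, arm)
    expect_equal(rowSums(out$trace), rep(1, nrow(out$trace)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_true(all(out$trace >= 0))
    expect_equal(out$trace[1L, ], c(health = 1, btn = 0, mtn = 0, postop = 0,
                                    recurrence = 0, death = 0))
  }
})

test_that("totals are consistent sums of the per-cycle vectors", {
  out <- run_cohort(paper_spec(), "SG")
  expect_equal(out$total_cost, sum(out$per_cycle_cost))
  expect_equal(out$total_qaly, sum(out$per_cycle_qaly))
  expect_lte(out$total_qaly, paper_spec()$settings$horizon_cycles)
  expect_gte(out$total_cost, 0)
})

test_that("raising a utility or a cost never lowers the corresponding total", {
  for (s in c(3, 17, 42)) {
    spec <- generate_random_model(scenario_recipe(seed = s))
    base_sg <- run_cohort(spec, "SG")
    up_u <- set_parameter(spec, "u_recurrence",
                          min(1, spec$utilities[["recurrence"]] + 0.2))
    expect_gte(run_cohort(up_u, "SG")$total_qaly, base_sg$total_qaly)
    up_c <- set_parameter(spec, "c_nf", spec$costs[["c_nf"]] * 2)
    expect_gte(run_cohort(up_c, "SG")$total_cost, base_sg$total_cost)
    up_exam <- set_parameter(spec, "c_n", spec$costs[["c_n"]] * 1.5)
    expect_gte(run_cohort(up_exam, "SG")$total_cost, base_sg$total_cost)
  }
})

test_that("an invalid spec is rejected with its violations", {
  spec <- paper_spec()
  spec$utilities[["btn"]] <- 2
  expect_error(run_cohort(spec, "SG"), "btn")
})

test_that("microsimulation agrees with the cohort engine on a toy model", {
  tm <- toy_geometric_model(0.1, r = 0.05, horizon = 30L)
  co <- run_cohort(tm$spec, "SG")
  ms <- microsim_oracle(tm$spec, "SG", n_individuals = 100000L, seed = 7L)
  expect_lt(abs(ms$total_qaly - co$total_qaly), 3 * ms$se_qaly)
  expect_equal(co$total_qaly, tm$expected_qaly, tolerance = 1e-9)
})

test_that("a degenerate model without transitions is matched exactly", {
  tm <- toy_geometric_model(0, r = 0, horizon = 12L)
  ms <- microsim_oracle(tm$spec, "SG", n_individuals = 500L, seed = 1L)
  expect_identical(ms$se_qaly, 0) # no randomness left
  expect_equal(ms$total_qaly, 12)
})

test_that("microsimulation agrees with the cohort engine on the full model", {
  spec <- paper_spec()
  co <- run_cohort(spec, "SG")
  ms <- microsim_oracle(spec, "SG", n_individuals = 200000L, seed = 11L)
  expect_lt(abs(ms$total_qaly - co$total_qaly), 3 * ms$se_qaly)
  expect_lt(abs(ms$total_cost - co$total_cost), 3 * ms$se_cost)
})

test_that("microsimulation agrees with the cohort engine on random specs", {
  for (s in c(5, 23)) {
    spec <- generate_random_model(scenario_recipe(seed = s))
    for (arm in c("SG", "NSG")) {
      co <- run_cohort(spec, arm)
      ms <- microsim_oracle(spec, arm, n_individuals = 40000L, seed = s + 1L)
      expect_lt(abs(ms$total_qaly - co$total_qaly),
                3 * ms$se_qaly + 1e-12)
      expect_lt(abs(ms$total_cost - co$total_cost),
                3 * ms$se_cost + 1e-9)
    }
  }
})

test_that("the trace exports with per-cycle rewards", {
  out <- run_cohort(paper_spec(), "NSG")
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  export_trace_csv(out, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 56L)
  expect_equal(df$health[1], 1)
  expect_equal(sum(df$discounted_cost, na.rm = TRUE), out$total_cost,
               tolerance = 1e-8)
})
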
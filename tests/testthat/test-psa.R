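# Probabilistic sensitivity analysis: sampling, scatter, acceptability.

test_that("all-fixed distributions collapse the sample to the base case", {
  spec <- paper_spec()
  spec$distributions <- lapply(spec$distributions, function(d) {
    param_dist("fixed", d$base_value, range_low = d$base_value,
               range_high = d$base_value)
  })
  set.seed(1)
  s <- sample_parameters(spec)
  for (nm in names(s)) {
    expect_identical(unname(s[[nm]]),
                     spec$distributions[[nm]]$base_value)
  }
  sc <- run_psa(spec, n_draws = 4L, seed = 9L)
  base <- compare_strategies(spec)
  expect_equal(sc$dcost, rep(base$incremental$dcost, 4L))
  expect_equal(sc$dqaly, rep(base$incremental$dqaly, 4L))
})

test_that("sampled distributions reproduce their analytic means", {
  spec <- paper_spec()
  set.seed(42)
  rec <- sample_resolved(resolve_distribution(spec$distributions$u_recurrence),
                         10000L)
  expect_equal(mean(rec), 0.54, tolerance = 0.01)
  ct <- sample_resolved(resolve_distribution(spec$distributions$c_t), 10000L)
  expect_equal(mean(ct), 29 * 706, tolerance = 0.02 * 29 * 706)
})

test_that("each scatter point is the forward computation of its drawn sample", {
  spec <- paper_spec()
  sc <- run_psa(spec, n_draws = 2L, seed = 31L)
  # replay the identical draw stream by hand and run the engine directly
  resolved <- lapply(spec$distributions, resolve_distribution)
  set.seed(31L)
  for (i in 1:2) {
    smp <- sample_parameters(spec, resolved)
    sp <- thyrocea:::apply_sample(spec, smp)
    sg <- thyrocea:::run_cohort_core(sp, "SG")
    nsg <- thyrocea:::run_cohort_core(sp, "NSG")
    expect_equal(sc$dcost[i], sg$total_cost - nsg$total_cost)
    expect_equal(sc$dqaly[i], sg$total_qaly - nsg$total_qaly)
  }
})

test_that("a fixed seed reproduces the scatter bit for bit", {
  spec <- paper_spec()
  a <- run_psa(spec, n_draws = 25L, seed = 5L)
  b <- run_psa(spec, n_draws = 25L, seed = 5L)
  expect_identical(a, b)
  c <- run_psa(spec, n_draws = 25L, seed = 6L)
  expect_false(identical(a$dcost, c$dcost))
})

test_that("draws stay inside their supports and utilities inside the unit interval", {
  spec <- paper_spec()
  resolved <- lapply(spec$distributions, resolve_distribution)
  set.seed(8)
  for (i in 1:50) {
    s <- sample_parameters(spec, resolved)
    expect_true(all(s[grepl("^u_|^p_", names(s))] >= 0))
    expect_true(all(s[grepl("^u_|^p_", names(s))] <= 1))
    expect_true(all(s[grepl("^c_", names(s))] > 0))
  }
})

test_that("prob_cost_effective counts NMB-favorable points", {
  sc <- manual_scatter(dqaly = rep(1, 3), dcost = rep(0, 3))
  expect_identical(prob_cost_effective(sc, 0), 1)
  expect_identical(prob_cost_effective(sc, 1e6), 1)
  # hand count: 3 of 10 points satisfy 50000 * dq - dc >= 0
  sc10 <- manual_scatter(
    dqaly = c(0.10, 0.05, 0.02, 0.001, 0.001, -0.01, 0.04, 0.0, 0.0, 0.01),
    dcost = c(1000, 2000, 3000, 4000, 5000, -100, 1000, 100, 6000, 800)
  )
  expect_identical(prob_cost_effective(sc10, 50000), 0.3)
  expect_identical(prob_cost_effective(sc10, 50000) +
                     (1 - prob_cost_effective(sc10, 50000)), 1)
})

test_that("ties are awarded to the cheaper strategy", {
  tie_pos <- manual_scatter(dqaly = 1, dcost = 50000) # NMB diff exactly 0
  expect_identical(prob_cost_effective(tie_pos, 50000), 0) # dearer screening loses the tie
  tie_neg <- manual_scatter(dqaly = -1, dcost = -50000)
  expect_identical(prob_cost_effective(tie_neg, 50000), 1) # cheaper screening wins it
})

test_that("the per-point incremental NMB is linear across the grid", {
  spec <- paper_spec()
  sc <- run_psa(spec, n_draws = 10L, seed = 2L)
  w <- c(0, 5e4, 1e5, 2e5)
  for (i in seq_len(nrow(sc))) {
    nmb <- w * sc$dqaly[i] - sc$dcost[i]
    slopes <- diff(nmb) / diff(w)
    expect_equal(slopes, rep(sc$dqaly[i], 3L), tolerance = 1e-12)
  }
})

test_that("the acceptability curve respects its definitions", {
  spec <- paper_spec()
  sc <- run_psa(spec, n_draws = 100L, seed = 3L)
  cv <- ceac(sc)
  expect_identical(cv$wtp, seq(0, 200000, by = 5000))
  expect_true(all(cv$p_screening >= 0 & cv$p_screening <= 1))
  expect_equal(cv$p_screening + cv$p_nonscreening, rep(1, nrow(cv)))
  # at wtp 0, screening is acceptable exactly when it is not dearer
  expect_equal(cv$p_screening[1], mean(sc$dcost < 0 | (sc$dcost == 0)))
  expect_error(ceac(sc, wtp_grid = c(0, 0, 5)), "increasing")
  p <- plot_ceac(cv)
  expect_s3_class(p, "ggplot")
  p2 <- plot_psa_scatter(sc)
  expect_s3_class(p2, "ggplot")
})

test_that("infeasible draws are redrawn and counted", {
  spec <- generate_random_model(scenario_recipe(seed = 4))
  # force frequent row-sum violations: huge uncertainty on nodule incidence
  spec$distributions$p_health_btn_sg <- param_dist("beta", 0.5, 8, 2,
                                                   0.3, 0.95)
  spec$transitions$SG[["p_health_btn"]] <- 0.5
  spec$distributions$p_health_mtn_sg <- param_dist("beta", 0.2, 6, 14,
                                                   0.1, 0.5)
  spec$transitions$SG[["p_health_mtn"]] <- 0.2
  sc <- run_psa(spec, n_draws = 60L, seed = 10L)
  expect_gt(attr(sc, "redraws"), 0L)
  expect_identical(nrow(sc), 60L)
})
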
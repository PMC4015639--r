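# Closed-form effectiveness and cost equations.

test_that("strategy effectiveness follows the Bayes decision tree", {
  perf <- worked_example_perf()
  expect_identical(strategy1_effectiveness(0, perf), 0)
  expect_equal(strategy1_effectiveness(0.4, test_performance(sn_cmr = 1, ndx = 0)),
               0.4)

  # independent oracle: enumerate the decision-tree leaves at p = 1 —
  # diseased patients are detected via a diagnostic positive CMR or via
  # crossover after a non-diagnostic CMR
  perf1 <- worked_example_perf()
  leaves <- expand.grid(nondx = c(TRUE, FALSE), cmr_pos = c(TRUE, FALSE))
  leaves$prob <- ifelse(leaves$nondx, perf1$ndx / 2,
                        (1 - perf1$ndx) *
                          ifelse(leaves$cmr_pos, perf1$sn_cmr, 1 - perf1$sn_cmr))
  leaves$detected <- leaves$nondx | leaves$cmr_pos
  expect_equal(sum(leaves$prob[leaves$detected]), 0.886, tolerance = 1e-12)
  expect_equal(strategy1_effectiveness(1, perf1), 0.886)

  # the invasive reference detects everyone
  expect_identical(strategy2_effectiveness(0), 0)
  expect_identical(strategy2_effectiveness(1), 1)
  expect_identical(strategy2_effectiveness(0.3), 0.3)

  expect_error(strategy1_effectiveness(1.2, perf), "probabilit")
  expect_error(strategy2_effectiveness(-0.1), "probabilit")
})

test_that("effectiveness invariants hold across random parameter sets", {
  set.seed(101)
  p_grid <- seq(0, 1, by = 0.1)
  for (i in 1:25) {
    cfg <- random_config()
    e1 <- strategy1_effectiveness(p_grid, cfg$perf)
    e2 <- strategy2_effectiveness(p_grid)
    expect_true(all(e1 <= e2 + 1e-12))
    # linear in p: eff(p) = p * eff(1)
    expect_equal(e1, p_grid * strategy1_effectiveness(1, cfg$perf))
    expect_true(all(diff(e1) >= 0))
  }
  # equality iff the CMR arm cannot miss anyone
  expect_equal(strategy1_effectiveness(0.6, test_performance(sn_cmr = 1)), 0.6)
  expect_equal(strategy1_effectiveness(0.6, test_performance(ndx = 1)), 0.6)
})

test_that("false-negative complication cost is a discounted annuity", {
  perf <- worked_example_perf()
  costs <- worked_example_costs()

  # brute-force oracle: average the year-by-year discount factors
  oracle <- 10000 * 0.15 * sum((1.03)^-(1:10)) / 10
  expect_equal(discounted_fn_complication_cost(costs, perf), oracle)
  expect_equal(discounted_fn_complication_cost(costs, perf), 1279.53,
               tolerance = 0.01 / 1279.53)

  no_disc <- worked_example_costs()
  no_disc$discount_rate <- 0
  expect_equal(discounted_fn_complication_cost(no_disc, perf),
               costs$c_complication * perf$r_f)

  no_risk <- test_performance(r_f = 0)
  expect_identical(discounted_fn_complication_cost(costs, no_risk), 0)
})

test_that("invasive-strategy cost is fee + prevalence-driven FFR + risk", {
  perf <- worked_example_perf()
  costs <- worked_example_costs()
  lk <- identity_link()
  expect_equal(strategy2_expected_cost(0, perf, costs, lk), 2005)
  expect_equal(strategy2_expected_cost(0.5, perf, costs, lk), 2305)

  no_ffr <- worked_example_costs()
  no_ffr$f_ffr <- 0
  p <- seq(0, 1, by = 0.25)
  expect_true(all(strategy2_expected_cost(p, perf, no_ffr, lk) ==
                    strategy2_expected_cost(0, perf, no_ffr, lk)))

  # non-decreasing in prevalence for a non-decreasing link
  set.seed(7)
  for (i in 1:10) {
    cfg <- random_config()
    v <- strategy2_expected_cost(seq(0, 1, 0.05), cfg$perf, cfg$costs, cfg$link)
    expect_true(all(diff(v) >= -1e-9))
  }
  expect_error(strategy2_expected_cost(0.5, perf, costs, link = "no"), "link")
})

test_that("CMR-first strategy cost decomposes into the four cost components", {
  perf <- worked_example_perf()
  costs <- worked_example_costs()
  lk <- identity_link()

  comp <- strategy1_cost_components(0.5, perf, costs, lk)
  expect_equal(comp$first_line_cmr, 1000)
  expect_equal(comp$cxa_after_positive_cmr, 933.3275, tolerance = 1e-6)
  expect_equal(comp$fn_complications, 72.93323, tolerance = 1e-6)
  expect_equal(comp$crossover, 115.25)
  expect_equal(comp$total, 2121.51, tolerance = 0.01 / 2121.51)
  expect_equal(strategy1_expected_cost(0.5, perf, costs, lk), comp$total)

  # perfect test at full prevalence: CMR fee plus one angiography each
  perfect <- test_performance(sn_cmr = 1, sp_cmr = 1, ndx = 0)
  expect_equal(strategy1_expected_cost(1, perfect, costs, lk),
               costs$f_cmr + costs$f_cxa_outpatient +
                 perfect$r_cxa * costs$c_complication)

  # disease-free cohort with perfect specificity: nobody proceeds past CMR
  clean <- test_performance(sp_cmr = 1, ndx = 0)
  expect_equal(strategy1_expected_cost(0, clean, costs, lk), costs$f_cmr)
})

test_that("evaluate_strategies bundles costs, effectiveness and their ratio", {
  perf <- worked_example_perf()
  costs <- worked_example_costs()
  out <- evaluate_strategies(0.5, perf, costs, identity_link())
  expect_equal(out$ce_ratio[out$strategy == 1], 4789.0, tolerance = 0.1 / 4789)
  expect_equal(out$ce_ratio[out$strategy == 2], 4610.0)
  expect_equal(out$ce_ratio, out$expected_cost / out$effectiveness,
               tolerance = 1e-12)

  zero <- evaluate_strategies(0, perf, costs, identity_link())
  expect_equal(zero$effectiveness, c(0, 0))
  expect_false(any(zero$ce_defined))
  expect_true(all(is.na(zero$ce_ratio)))

  full <- evaluate_strategies(1, perf, costs, identity_link())
  expect_equal(full$ce_ratio[full$strategy == 2],
               costs$f_cxa_outpatient + costs$f_ffr +
                 perf$r_cxa * costs$c_complication)
})

test_that("inpatient setting switches the angiography fee in both strategies", {
  perf <- worked_example_perf()
  out_c <- worked_example_costs("outpatient")
  in_c <- worked_example_costs("inpatient")
  expect_equal(active_cxa_fee(in_c) - active_cxa_fee(out_c), 1500)
  d2 <- strategy2_expected_cost(0.5, perf, in_c, identity_link()) -
    strategy2_expected_cost(0.5, perf, out_c, identity_link())
  expect_equal(d2, 1500)
  d1 <- strategy1_expected_cost(0.5, perf, in_c, identity_link()) -
    strategy1_expected_cost(0.5, perf, out_c, identity_link())
  expect_true(d1 > 0 && d1 < 1500)  # only CXA-referred fractions pay it
})
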
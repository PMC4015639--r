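# Shared fixtures: the documented worked-example parameter set and a
# generator of random valid model configurations for property-style tests.

worked_example_perf <- function() {
  test_performance(sn_cmr = 0.88, sp_cmr = 0.90, ndx = 0.05,
                   r_cxa = 0.0005, r_f = 0.15)
}

worked_example_costs <- function(cxa_setting = "outpatient") {
  cost_schedule(f_cmr = 1000, f_cxa_outpatient = 2000,
                f_cxa_inpatient = 3500, f_ffr = 600,
                c_complication = 10000, discount_rate = 0.03,
                horizon_years = 10, currency = "XXX",
                cxa_setting = cxa_setting)
}

identity_link <- function() stenosis_link("identity")

# random but valid parameter sets; caller controls the RNG state
random_config <- function() {
  perf <- test_performance(sn_cmr = runif(1, 0.70, 0.99),
                           sp_cmr = runif(1, 0.70, 0.99),
                           ndx = runif(1, 0, 0.15),
                           r_cxa = runif(1, 0, 0.002),
                           r_f = runif(1, 0.05, 0.30))
  costs <- cost_schedule(f_cmr = runif(1, 200, 2000),
                         f_cxa_outpatient = runif(1, 500, 4000),
                         f_cxa_inpatient = runif(1, 2000, 8000),
                         f_ffr = runif(1, 100, 1500),
                         c_complication = runif(1, 5000, 30000),
                         discount_rate = runif(1, 0, 0.06),
                         horizon_years = sample(5:15, 1))
  link <- if (runif(1) < 0.5) {
    stenosis_link("identity")
  } else {
    stenosis_link("linear_clipped", c(runif(1, 0, 0.3), runif(1, 0.7, 1)))
  }
  list(perf = perf, costs = costs, link = link)
}

# dense-grid brute-force root of a difference curve; the independent check
# on the scan-and-bisect machinery
brute_force_crossing <- function(delta_fun, lo = 0.01, hi = 1, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  delta <- delta_fun(grid)
  sgn <- sign(delta)
  flips <- which(sgn[-length(sgn)] * sgn[-1L] < 0)
  zeros <- which(delta == 0)
  cand <- c(if (length(flips)) (grid[flips[1L]] + grid[flips[1L] + 1L]) / 2,
            if (length(zeros)) grid[zeros[1L]])
  if (length(cand) == 0L) return(NA_real_)
  min(cand)
}

ce_delta_fun <- function(perf, costs, link) {
  function(p) {
    strategy1_expected_cost(p, perf, costs, link) /
      strategy1_effectiveness(p, perf) -
      strategy2_expected_cost(p, perf, costs, link) / p
  }
}

cost_delta_fun <- function(perf, costs, link) {
  function(p) {
    strategy1_expected_cost(p, perf, costs, link) -
      strategy2_expected_cost(p, perf, costs, link)
  }
}
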
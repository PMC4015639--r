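#' Effectiveness of the CMR-first strategy
#'
#' The fraction of patients tested who end up correctly identified as having
#' hemodynamically significant disease with full anatomical information.
#' Under strategy 1 a diseased patient is detected either by a diagnostic,
#' positive perfusion-CMR (then referred to angiography) or by crossing over
#' to the invasive reference pathway after a non-diagnostic CMR:
#' `p_isch * (sn_cmr * (1 - ndx) + ndx)`.
#'
#' @param p_isch Pre-test likelihood(s) of significant disease.
#' @param perf A [test_performance()].
#' @return Effectiveness in `[0, 1]`, same length as `p_isch`.
#' @export
strategy1_effectiveness <- function(p_isch, perf = test_performance()) {
  assert_probabilities(p_isch, "p_isch")
  stopifnot(inherits(perf, "test_performance"))
  p_isch * (perf$sn_cmr * (1 - perf$ndx) + perf$ndx)
}

#' Effectiveness of the invasive-first strategy
#'
#' Angiography plus FFR is the reference with assumed perfect accuracy, so
#' every diseased patient is detected: effectiveness equals the pre-test
#' likelihood itself.
#'
#' @inheritParams strategy1_effectiveness
#' @return `p_isch`, unchanged.
#' @export
strategy2_effectiveness <- function(p_isch) {
  assert_probabilities(p_isch, "p_isch")
  p_isch
}

#' Present-value annuity factor for uniformly timed events
#'
#' Mean of the per-year discount factors `(1 + r)^-t` over `t = 1..horizon`.
#' With the default 3% rate and a 10-year horizon this is 0.85302.
#'
#' @param discount_rate Annual rate in `[0, 1)`.
#' @param horizon_years Integer horizon, >= 1.
#' @return A single factor in `(0, 1]`.
#' @export
annuity_factor <- function(discount_rate, horizon_years) {
  mean((1 + discount_rate)^-(seq_len(horizon_years)))
}

#' Expected discounted complication cost per false-negative patient
#'
#' A patient with undetected significant disease faces a myocardial
#' infarction with probability `r_f` over the follow-up horizon. The event
#' year is taken as uniform over years 1..horizon, and each year's cost is
#' discounted to present value, giving
#' `c_complication * r_f * annuity_factor(rate, horizon)`.
#'
#' @param costs A [cost_schedule()].
#' @param perf A [test_performance()].
#' @return Expected present-value cost per false negative.
#' @export
discounted_fn_complication_cost <- function(costs, perf) {
  stopifnot(inherits(costs, "cost_schedule"), inherits(perf, "test_performance"))
  costs$c_complication * perf$r_f *
    annuity_factor(costs$discount_rate, costs$horizon_years)
}

#' Expected per-patient cost of the invasive-first strategy
#'
#' Every patient pays the angiography fee (outpatient or inpatient per the
#' schedule); patients with a >= 50% stenosis — a fraction given by the
#' ischemia-stenosis link — additionally undergo FFR; each angiography
#' carries a procedural complication risk. There is no false-negative term
#' because the reference tests are assumed perfect.
#'
#' @inheritParams strategy1_effectiveness
#' @param costs A [cost_schedule()].
#' @param link A [stenosis_link()].
#' @return Expected cost per patient tested, same length as `p_isch`.
#' @export
strategy2_expected_cost <- function(p_isch, perf = test_performance(),
                                    costs, link = stenosis_link("identity")) {
  assert_probabilities(p_isch, "p_isch")
  stopifnot(inherits(costs, "cost_schedule"))
  if (!inherits(link, "stenosis_link")) {
    stop("'link' must be a stenosis_link object", call. = FALSE)
  }
  active_cxa_fee(costs) + apply_link(link, p_isch) * costs$f_ffr +
    perf$r_cxa * costs$c_complication
}

#' Per-patient cost components of the CMR-first strategy
#'
#' The expected cost decomposes into: the universal CMR fee; angiography
#' (fee plus procedural risk) in patients with a diagnostic positive CMR —
#' true positives and false positives alike; discounted future complication
#' costs in false negatives; and the full invasive-strategy cost for the
#' non-diagnostic fraction that crosses over. The decomposition is reported
#' so alternative cost taxonomies can be compared term by term.
#'
#' @inheritParams strategy2_expected_cost
#' @return A `data.frame` with columns `p_isch`, `first_line_cmr`,
#'   `cxa_after_positive_cmr`, `fn_complications`, `crossover`, `total`.
#' @export
strategy1_cost_components <- function(p_isch, perf = test_performance(),
                                      costs, link = stenosis_link("identity")) {
  assert_probabilities(p_isch, "p_isch")
  stopifnot(inherits(perf, "test_performance"), inherits(costs, "cost_schedule"))
  cxa_unit <- active_cxa_fee(costs) + perf$r_cxa * costs$c_complication
  p_pos_diag <- (1 - perf$ndx) *
    (perf$sn_cmr * p_isch + (1 - perf$sp_cmr) * (1 - p_isch))
  p_fn <- (1 - perf$ndx) * (1 - perf$sn_cmr) * p_isch
  comp <- data.frame(
    p_isch = p_isch,
    first_line_cmr = rep_len(costs$f_cmr, length(p_isch)),
    cxa_after_positive_cmr = p_pos_diag * cxa_unit,
    fn_complications = p_fn * discounted_fn_complication_cost(costs, perf),
    crossover = perf$ndx * strategy2_expected_cost(p_isch, perf, costs, link))
  comp$total <- comp$first_line_cmr + comp$cxa_after_positive_cmr +
    comp$fn_complications + comp$crossover
  comp
}

#' Expected per-patient cost of the CMR-first strategy
#'
#' Sum of the components in [strategy1_cost_components()].
#'
#' @inheritParams strategy2_expected_cost
#' @return Expected cost per patient tested, same length as `p_isch`.
#' @export
strategy1_expected_cost <- function(p_isch, perf = test_performance(),
                                    costs, link = stenosis_link("identity")) {
  strategy1_cost_components(p_isch, perf, costs, link)$total
}

#' Evaluate both strategies at one pre-test likelihood
#'
#' Computes effectiveness, expected per-patient cost, and the
#' cost-effectiveness ratio (cost per patient correctly diagnosed) for both
#' strategies. At `p_isch = 0` effectiveness is zero and the ratio is
#' undefined (`NA` with `ce_defined = FALSE`), not an error.
#'
#' @inheritParams strategy2_expected_cost
#' @return A `data.frame` of class `strategy_outcomes` with one row per
#'   strategy and columns `strategy`, `effectiveness`, `expected_cost`,
#'   `ce_ratio`, `ce_defined`.
#' @examples
#' costs <- cost_schedule(f_cmr = 1000, f_cxa_outpatient = 2000,
#'                        f_ffr = 600, c_complication = 10000)
#' evaluate_strategies(0.5, test_performance(), costs)
#' @export
evaluate_strategies <- function(p_isch, perf = test_performance(),
                                costs, link = stenosis_link("identity")) {
  assert_probability(p_isch, "p_isch")
  eff <- c(strategy1_effectiveness(p_isch, perf),
           strategy2_effectiveness(p_isch))
  cost <- c(strategy1_expected_cost(p_isch, perf, costs, link),
            strategy2_expected_cost(p_isch, perf, costs, link))
  defined <- eff > 0
  ratio <- ifelse(defined, cost / eff, NA_real_)
  structure(data.frame(strategy = c(1L, 2L), effectiveness = eff,
                       expected_cost = cost, ce_ratio = ratio,
                       ce_defined = defined),
            class = c("strategy_outcomes", "data.frame"))
}
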
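#' Simulate a patient cohort through one diagnostic strategy
#'
#' Patient-level Monte Carlo counterpart of the closed-form model, used as
#' an independent stochastic check: its expectations equal the analytic
#' effectiveness and cost by construction, so large-cohort estimates must
#' agree with them to within Monte Carlo error.
#'
#' Sampling rules: true ischemia is Bernoulli at the pre-test likelihood;
#' stenosis is certain in ischemic patients and sampled in the rest so that
#' the marginal stenosis rate equals the link output; CMR is non-diagnostic
#' with probability `ndx` independent of disease, otherwise positive with
#' probability `sn_cmr` in diseased and `1 - sp_cmr` in disease-free
#' patients; every angiography carries a `r_cxa` complication risk; a false
#' negative suffers a complication with probability `r_f`, its year uniform
#' over 1..horizon and its cost discounted to present value. Non-diagnostic
#' patients cross over to the invasive pathway with perfect accuracy.
#'
#' @param p_isch Pre-test likelihood of significant disease.
#' @param n Number of simulated patients.
#' @inheritParams strategy2_expected_cost
#' @param strategy `1` (CMR first) or `2` (angiography + FFR).
#' @param seed Integer seed; required, so runs are reproducible.
#' @return A list with `patients` (one row per patient: truth, test results,
#'   complications, accrued cost, classification) and `estimate` (a
#'   `simulation_estimate` with means, standard errors, `n`, `seed`).
#' @examples
#' costs <- cost_schedule(f_cmr = 1000, f_cxa_outpatient = 2000,
#'                        f_ffr = 600, c_complication = 10000)
#' sim <- simulate_cohort(0.5, n = 1000, costs = costs, strategy = 1, seed = 7)
#' sim$estimate
#' @export
simulate_cohort <- function(p_isch, n, perf = test_performance(), costs,
                            link = stenosis_link("identity"),
                            strategy = 1L, seed) {
  assert_probability(p_isch, "p_isch")
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer", call. = FALSE)
  strategy <- as.integer(strategy)
  if (!strategy %in% c(1L, 2L)) stop("'strategy' must be 1 or 2", call. = FALSE)
  stopifnot(inherits(perf, "test_performance"), inherits(costs, "cost_schedule"))

  p_sten <- apply_link(link, p_isch)
  if (p_sten < p_isch - 1e-12) {
    stop("apply_link(p_isch) < p_isch: ischemia must imply stenosis",
         call. = FALSE)
  }

  set.seed(seed)
  ischemic <- stats::runif(n) < p_isch
  # conditional stenosis rate in non-ischemic patients so the marginal
  # stenosis frequency is p_sten
  p_sten_given_healthy <- if (p_isch < 1) (p_sten - p_isch) / (1 - p_isch) else 0
  stenosed <- ischemic | (stats::runif(n) < p_sten_given_healthy)

  cxa_fee <- active_cxa_fee(costs)
  horizon <- costs$horizon_years

  cmr_result <- rep("not_done", n)
  cxa_done <- logical(n)
  ffr_done <- logical(n)
  proc_comp <- logical(n)
  fn_comp <- logical(n)
  fn_year <- rep(NA_integer_, n)
  cost <- numeric(n)
  class_ <- character(n)

  # invasive reference pathway: CXA in all, FFR in stenosed; perfect accuracy
  run_invasive <- function(idx) {
    cxa_done[idx] <<- TRUE
    ffr_done[idx] <<- stenosed[idx]
    comp <- stats::runif(length(idx)) < perf$r_cxa
    proc_comp[idx] <<- comp
    cost[idx] <<- cost[idx] + cxa_fee + ffr_done[idx] * costs$f_ffr +
      comp * costs$c_complication
  }

  if (strategy == 2L) {
    run_invasive(seq_len(n))
    class_ <- ifelse(ischemic, "TP", "TN")
  } else {
    cost[] <- costs$f_cmr
    u <- stats::runif(n)
    nondx <- u < perf$ndx
    p_pos <- ifelse(ischemic, perf$sn_cmr, 1 - perf$sp_cmr)
    positive <- !nondx & (stats::runif(n) < p_pos)
    cmr_result <- ifelse(nondx, "nondiagnostic",
                         ifelse(positive, "positive", "negative"))
    if (any(nondx)) run_invasive(which(nondx))
    pos_idx <- which(positive)
    if (length(pos_idx)) {
      cxa_done[pos_idx] <- TRUE
      comp <- stats::runif(length(pos_idx)) < perf$r_cxa
      proc_comp[pos_idx] <- comp
      cost[pos_idx] <- cost[pos_idx] + cxa_fee + comp * costs$c_complication
    }
    fn_idx <- which(!nondx & !positive & ischemic)
    if (length(fn_idx)) {
      ev <- stats::runif(length(fn_idx)) < perf$r_f
      fn_comp[fn_idx] <- ev
      yrs <- sample.int(horizon, length(fn_idx), replace = TRUE)
      fn_year[fn_idx[ev]] <- yrs[ev]
      cost[fn_idx] <- cost[fn_idx] +
        ev * costs$c_complication * (1 + costs$discount_rate)^-yrs
    }
    class_ <- ifelse(nondx, ifelse(ischemic, "crossover_TP", "crossover_TN"),
                     ifelse(positive, ifelse(ischemic, "TP", "FP"),
                            ifelse(ischemic, "FN", "TN")))
  }

  patients <- data.frame(id = seq_len(n), ischemic = ischemic,
                         stenosed = stenosed, cmr_result = cmr_result,
                         cxa_done = cxa_done, ffr_done = ffr_done,
                         procedure_complication = proc_comp,
                         fn_complication = fn_comp, fn_event_year = fn_year,
                         cost_accrued = cost, classification = class_,
                         stringsAsFactors = FALSE)
  estimate <- cohort_estimate(patients, seed = seed)
  list(patients = patients, estimate = estimate)
}

cohort_estimate <- function(patients, seed = NA_integer_) {
  n <- nrow(patients)
  eff_hat <- mean(patients$classification %in% c("TP", "crossover_TP"))
  cost_hat <- mean(patients$cost_accrued)
  structure(list(effectiveness_hat = eff_hat,
                 cost_hat = cost_hat,
                 se_effectiveness = sqrt(eff_hat * (1 - eff_hat) / n),
                 se_cost = stats::sd(patients$cost_accrued) / sqrt(n),
                 n = n, seed = seed),
            class = "simulation_estimate")
}

#' Aggregate a simulated patient table into a strategy outcome
#'
#' Effectiveness is the fraction of patients classified `TP` or
#' `crossover_TP`; expected cost is the mean accrued cost; the CE ratio is
#' their quotient, flagged undefined when no true positives exist.
#'
#' @param patients Patient table from [simulate_cohort()].
#' @return A one-row `data.frame` with `effectiveness`, `expected_cost`,
#'   `ce_ratio`, `ce_defined`.
#' @export
estimate_ce <- function(patients) {
  if (!is.data.frame(patients) || nrow(patients) == 0L) {
    stop("'patients' must be a non-empty patient table", call. = FALSE)
  }
  eff <- mean(patients$classification %in% c("TP", "crossover_TP"))
  cost <- mean(patients$cost_accrued)
  data.frame(effectiveness = eff, expected_cost = cost,
             ce_ratio = if (eff > 0) cost / eff else NA_real_,
             ce_defined = eff > 0)
}

#' @export
print.simulation_estimate <- function(x, ...) {
  cat(sprintf("Microsimulation estimate (n = %d, seed = %s)\n", x$n, x$seed))
  cat(sprintf("  effectiveness %.4f (se %.2g) | cost %.2f (se %.2g)\n",
              x$effectiveness_hat, x$se_effectiveness, x$cost_hat, x$se_cost))
  invisible(x)
}
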
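#' Test-performance parameters for the two diagnostic strategies
#'
#' Bundles the per-patient diagnostic accuracy of perfusion-CMR against the
#' FFR reference, the non-diagnostic CMR rate, the reference-test accuracies
#' (assumed perfect by default), and the two complication rates that drive
#' subsequent costs.
#'
#' @param sn_cmr Sensitivity of perfusion-CMR for ischemia (vs FFR <= 0.75).
#' @param sp_cmr Specificity of perfusion-CMR.
#' @param ndx Non-diagnostic CMR rate; these patients cross over to the
#'   invasive strategy.
#' @param sn_cxa,sp_cxa,sn_ffr,sp_ffr Reference-test accuracies; default 1.
#' @param r_cxa Major complication rate per invasive angiography procedure.
#' @param r_f Complication rate per 10-year follow-up in false-negative
#'   patients with untreated significant disease.
#'
#' @return An object of class `test_performance`.
#' @examples
#' perf <- test_performance()           # literature defaults
#' perf$sn_cmr
#' @export
test_performance <- function(sn_cmr = 0.88, sp_cmr = 0.90, ndx = 0.05,
                             sn_cxa = 1, sp_cxa = 1, sn_ffr = 1, sp_ffr = 1,
                             r_cxa = 0.0005, r_f = 0.15) {
  perf <- list(sn_cmr = sn_cmr, sp_cmr = sp_cmr, ndx = ndx,
               sn_cxa = sn_cxa, sp_cxa = sp_cxa,
               sn_ffr = sn_ffr, sp_ffr = sp_ffr,
               r_cxa = r_cxa, r_f = r_f)
  for (nm in names(perf)) {
    assert_probability(perf[[nm]], nm)
  }
  structure(perf, class = "test_performance")
}

#' Country cost schedule
#'
#' Fees and cost parameters from a third-party-payer perspective: the
#' first-line test fees, the incremental FFR fee on top of angiography, the
#' cost of a myocardial infarction (PCI, one week in hospital, four weeks of
#' rehabilitation), and the discounting rule applied to future
#' false-negative complication costs.
#'
#' @param f_cmr CMR examination fee.
#' @param f_cxa_outpatient,f_cxa_inpatient Angiography fee in the two
#'   settings; the active fee is selected by `cxa_setting`.
#' @param f_ffr Incremental fee of an FFR measurement during angiography.
#' @param c_complication Cost of one myocardial infarction.
#' @param discount_rate Annual discount rate applied to future complication
#'   costs (default 0.03).
#' @param horizon_years Follow-up horizon over which false-negative
#'   complications may occur (default 10).
#' @param currency Currency label; never converted.
#' @param cxa_setting `"outpatient"` (default) or `"inpatient"`.
#'
#' @return An object of class `cost_schedule`.
#' @examples
#' costs <- cost_schedule(f_cmr = 1000, f_cxa_outpatient = 2000,
#'                        f_ffr = 600, c_complication = 10000)
#' active_cxa_fee(costs)
#' @export
cost_schedule <- function(f_cmr, f_cxa_outpatient, f_cxa_inpatient = f_cxa_outpatient,
                          f_ffr, c_complication,
                          discount_rate = 0.03, horizon_years = 10L,
                          currency = "XXX",
                          cxa_setting = c("outpatient", "inpatient")) {
  cxa_setting <- match.arg(cxa_setting)
  money <- c(f_cmr = f_cmr, f_cxa_outpatient = f_cxa_outpatient,
             f_cxa_inpatient = f_cxa_inpatient, f_ffr = f_ffr,
             c_complication = c_complication)
  for (nm in names(money)) {
    if (!is.numeric(money[[nm]]) || length(money[[nm]]) != 1L ||
        is.na(money[[nm]]) || money[[nm]] < 0) {
      stop(sprintf("'%s' must be a single non-negative number", nm), call. = FALSE)
    }
  }
  if (!is.numeric(discount_rate) || length(discount_rate) != 1L ||
      is.na(discount_rate) || discount_rate < 0 || discount_rate >= 1) {
    stop("'discount_rate' must be in [0, 1)", call. = FALSE)
  }
  horizon_years <- as.integer(horizon_years)
  if (is.na(horizon_years) || horizon_years < 1L) {
    stop("'horizon_years' must be an integer >= 1", call. = FALSE)
  }
  structure(list(f_cmr = f_cmr,
                 f_cxa_outpatient = f_cxa_outpatient,
                 f_cxa_inpatient = f_cxa_inpatient,
                 f_ffr = f_ffr,
                 c_complication = c_complication,
                 discount_rate = discount_rate,
                 horizon_years = horizon_years,
                 currency = as.character(currency),
                 cxa_setting = cxa_setting),
            class = "cost_schedule")
}

#' Angiography fee active under the schedule's setting
#'
#' @param costs A [cost_schedule()].
#' @return The outpatient or inpatient angiography fee.
#' @export
active_cxa_fee <- function(costs) {
  stopifnot(inherits(costs, "cost_schedule"))
  if (costs$cxa_setting == "inpatient") costs$f_cxa_inpatient else costs$f_cxa_outpatient
}

# single-probability check shared by constructors and model functions
assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

# vectorised variant used on prevalence grids
assert_probabilities <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be probabilities in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.test_performance <- function(x, ...) {
  cat("Test performance parameters\n")
  cat(sprintf("  CMR: Sn = %.3f, Sp = %.3f, non-diagnostic rate = %.3f\n",
              x$sn_cmr, x$sp_cmr, x$ndx))
  cat(sprintf("  Reference: Sn/Sp CXA = %.2f/%.2f, Sn/Sp FFR = %.2f/%.2f\n",
              x$sn_cxa, x$sp_cxa, x$sn_ffr, x$sp_ffr))
  cat(sprintf("  Complications: per CXA = %.4f, per 10-y FN follow-up = %.3f\n",
              x$r_cxa, x$r_f))
  invisible(x)
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat(sprintf("Cost schedule (%s, %s CXA)\n", x$currency, x$cxa_setting))
  cat(sprintf("  CMR %.2f | CXA out %.2f / in %.2f | FFR +%.2f | MI %.2f\n",
              x$f_cmr, x$f_cxa_outpatient, x$f_cxa_inpatient, x$f_ffr,
              x$c_complication))
  cat(sprintf("  discount %.1f%%/y over %d years\n",
              100 * x$discount_rate, x$horizon_years))
  invisible(x)
}
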
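#' Cost-effectiveness curves over a prevalence grid
#'
#' Evaluates effectiveness, expected per-patient cost, and the
#' cost-effectiveness ratio of both strategies at each pre-test likelihood
#' on the grid. The default grid spans 10% to 100% in 1% steps. Rows where
#' effectiveness is zero carry `NA` ratios.
#'
#' @inheritParams strategy2_expected_cost
#' @param grid Prevalence grid, all values in `(0, 1]` (0 is allowed but
#'   yields undefined ratios).
#' @return A `data.frame` with columns `p_isch`, `eff1`, `eff2`, `cost1`,
#'   `cost2`, `cer1`, `cer2`.
#' @export
ce_curve <- function(perf = test_performance(), costs,
                     link = stenosis_link("identity"),
                     grid = seq(0.10, 1.00, by = 0.01)) {
  if (length(grid) == 0L) stop("'grid' must be non-empty", call. = FALSE)
  assert_probabilities(grid, "grid")
  eff1 <- strategy1_effectiveness(grid, perf)
  eff2 <- strategy2_effectiveness(grid)
  cost1 <- strategy1_expected_cost(grid, perf, costs, link)
  cost2 <- strategy2_expected_cost(grid, perf, costs, link)
  data.frame(p_isch = grid, eff1 = eff1, eff2 = eff2,
             cost1 = cost1, cost2 = cost2,
             cer1 = ifelse(eff1 > 0, cost1 / eff1, NA_real_),
             cer2 = ifelse(eff2 > 0, cost2 / eff2, NA_real_))
}

# Scan-then-bisect root finder for a difference curve delta(p) on [lo, hi].
# Returns the smallest root; warns when the scan shows several sign changes.
find_crossing_generic <- function(delta_fun, domain, scan_step = 1e-3,
                                  rel_tol = 1e-6, scale_fun = NULL,
                                  bisect_tol = 1e-6) {
  lo <- domain[1L]; hi <- domain[2L]
  if (!(lo > 0 && hi <= 1 && lo < hi)) {
    stop("'domain' must be an interval within (0, 1]", call. = FALSE)
  }
  grid <- unique(c(seq(lo, hi, by = scan_step), hi))
  delta <- delta_fun(grid)
  scale <- if (is.null(scale_fun)) pmax(abs(delta), 1) else pmax(abs(scale_fun(grid)), 1)
  if (all(abs(delta) <= rel_tol * scale)) {
    return(list(p_star = NA_real_, bracket = c(lo, hi),
                status = "degenerate_equal"))
  }
  sgn <- sign(delta)
  # treat exact zeros as roots directly
  zero_idx <- which(abs(delta) <= rel_tol * scale)
  flips <- which(sgn[-length(sgn)] * sgn[-1L] < 0)
  if (length(zero_idx) == 0L && length(flips) == 0L) {
    return(list(p_star = NA_real_, bracket = c(lo, hi),
                status = "none_in_domain"))
  }
  n_roots <- length(flips) + as.integer(length(zero_idx) > 0L)
  if (length(flips) > 1L) {
    warning("multiple sign changes detected; reporting the smallest root",
            call. = FALSE)
  }
  if (length(zero_idx) > 0L &&
      (length(flips) == 0L || grid[zero_idx[1L]] < grid[flips[1L]])) {
    p0 <- grid[zero_idx[1L]]
    return(list(p_star = p0, bracket = c(p0, p0), status = "found"))
  }
  a <- grid[flips[1L]]; b <- grid[flips[1L] + 1L]
  fa <- delta_fun(a)
  while (b - a > bisect_tol) {
    m <- (a + b) / 2
    fm <- delta_fun(m)
    if (fm == 0) { a <- m; b <- m; break }
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
  }
  list(p_star = (a + b) / 2, bracket = c(a, b), status = "found")
}

#' Locate the cost-effectiveness crossing point between strategies
#'
#' Finds the pre-test likelihood at which the two strategies' cost per
#' correctly diagnosed patient are equal, by scanning
#' `CER1(p) - CER2(p)` on a fine grid (step `1e-3`) and bisecting any sign
#' change down to a bracket of `1e-6`. Absence of a crossing in the domain
#' is reported as a status, not an error.
#'
#' @inheritParams strategy2_expected_cost
#' @param domain Search interval, a length-2 vector within `(0, 1]`.
#' @return A list of class `crossing_result` with `p_star`,
#'   `ce_at_crossing` (the shared CE ratio when found), `bracket`, `status`
#'   (`"found"`, `"none_in_domain"`, or `"degenerate_equal"`).
#' @export
find_ce_crossing <- function(perf = test_performance(), costs,
                             link = stenosis_link("identity"),
                             domain = c(0.01, 1)) {
  delta <- function(p) {
    strategy1_expected_cost(p, perf, costs, link) / strategy1_effectiveness(p, perf) -
      strategy2_expected_cost(p, perf, costs, link) / strategy2_effectiveness(p)
  }
  cer2 <- function(p) strategy2_expected_cost(p, perf, costs, link) / p
  res <- find_crossing_generic(delta, domain, scale_fun = cer2)
  res$ce_at_crossing <- if (res$status == "found") cer2(res$p_star) else NA_real_
  structure(res[c("p_star", "ce_at_crossing", "bracket", "status")],
            class = "crossing_result")
}

#' Locate the per-patient cost crossing point between strategies
#'
#' Same scan-and-bisect machinery as [find_ce_crossing()], applied to the
#' difference of expected per-patient costs rather than CE ratios.
#'
#' @inheritParams find_ce_crossing
#' @return A `crossing_result` list; `cost_at_crossing` holds the shared
#'   per-patient cost when found.
#' @export
find_cost_crossing <- function(perf = test_performance(), costs,
                               link = stenosis_link("identity"),
                               domain = c(0.01, 1)) {
  delta <- function(p) {
    strategy1_expected_cost(p, perf, costs, link) -
      strategy2_expected_cost(p, perf, costs, link)
  }
  cost2 <- function(p) strategy2_expected_cost(p, perf, costs, link)
  res <- find_crossing_generic(delta, domain, scale_fun = cost2)
  res$cost_at_crossing <- if (res$status == "found") cost2(res$p_star) else NA_real_
  structure(res[c("p_star", "cost_at_crossing", "bracket", "status")],
            class = "crossing_result")
}

#' @export
print.crossing_result <- function(x, ...) {
  if (x$status == "found") {
    at <- if (!is.null(x$ce_at_crossing)) x$ce_at_crossing else x$cost_at_crossing
    cat(sprintf("Crossing at p_isch = %.6f (value %.2f)\n", x$p_star, at))
  } else {
    cat(sprintf("No crossing: %s\n", x$status))
  }
  invisible(x)
}

#' Define a one-way sensitivity scenario
#'
#' One scenario perturbs exactly one model input: scaling or setting a
#' single performance or cost parameter, swapping the ischemia-stenosis
#' link (e.g. to an FFR-0.80 calibration), or swapping the angiography
#' setting between outpatient and inpatient.
#'
#' @param label Human-readable scenario name.
#' @param perturbation One of `"relative_scale"`, `"absolute_set"`,
#'   `"swap_link"`, `"swap_setting"`.
#' @param parameter Field of [test_performance()] or [cost_schedule()] to
#'   perturb (for the first two kinds).
#' @param magnitude Scale factor or absolute value (for the first two kinds).
#' @param value Replacement [stenosis_link()] for `"swap_link"`, or setting
#'   string for `"swap_setting"` (defaults to flipping the current one).
#' @return A list of class `sensitivity_scenario`.
#' @export
sensitivity_scenario <- function(label,
                                 perturbation = c("relative_scale", "absolute_set",
                                                  "swap_link", "swap_setting"),
                                 parameter = NULL, magnitude = NA_real_,
                                 value = NULL) {
  perturbation <- match.arg(perturbation)
  if (perturbation %in% c("relative_scale", "absolute_set")) {
    if (is.null(parameter)) stop("'parameter' is required", call. = FALSE)
    if (is.na(magnitude)) stop("'magnitude' is required", call. = FALSE)
  }
  if (perturbation == "swap_link" && !inherits(value, "stenosis_link")) {
    stop("'value' must be a stenosis_link for swap_link", call. = FALSE)
  }
  structure(list(label = label, perturbation = perturbation,
                 parameter = parameter, magnitude = magnitude, value = value),
            class = "sensitivity_scenario")
}

# probability-valued fields that must be clipped (with a warning) if a
# relative scaling pushes them outside [0, 1]
.prob_fields <- c("sn_cmr", "sp_cmr", "ndx", "sn_cxa", "sp_cxa",
                  "sn_ffr", "sp_ffr", "r_cxa", "r_f")

# Apply one scenario; returns perturbed (perf, costs, link) or valid = FALSE.
apply_scenario <- function(scenario, perf, costs, link) {
  out <- list(perf = perf, costs = costs, link = link, valid = TRUE)
  sc <- scenario
  if (sc$perturbation == "swap_link") {
    out$link <- sc$value
    return(out)
  }
  if (sc$perturbation == "swap_setting") {
    new_setting <- if (!is.null(sc$value)) sc$value else
      if (costs$cxa_setting == "outpatient") "inpatient" else "outpatient"
    out$costs$cxa_setting <- new_setting
    return(out)
  }
  target <- if (sc$parameter %in% names(perf)) "perf"
            else if (sc$parameter %in% names(costs)) "costs"
            else return(modifyList(out, list(valid = FALSE)))
  obj <- out[[target]]
  new_val <- if (sc$perturbation == "relative_scale") {
    obj[[sc$parameter]] * sc$magnitude
  } else sc$magnitude
  if (sc$parameter %in% .prob_fields && (new_val < 0 || new_val > 1)) {
    warning(sprintf("scenario '%s': '%s' clipped to [0, 1]",
                    sc$label, sc$parameter), call. = FALSE)
    new_val <- min(max(new_val, 0), 1)
  }
  if (target == "costs" && sc$parameter != "cxa_setting" && new_val < 0) {
    return(modifyList(out, list(valid = FALSE)))
  }
  obj[[sc$parameter]] <- new_val
  out[[target]] <- obj
  out
}

#' One-way sensitivity analysis on the crossing point
#'
#' Perturbs one parameter at a time and reports how far the
#' cost-effectiveness (or per-patient cost) crossing point moves, in
#' percentage points of pre-test likelihood. Each perturbed crossing is
#' recomputed from scratch; scenarios are independent and order does not
#' matter. A perturbation that leaves the valid range marks the scenario
#' `invalid` and the run continues.
#'
#' @inheritParams find_ce_crossing
#' @param scenarios A list of [sensitivity_scenario()] objects.
#' @param type Which crossing to track: `"ce"` (default) or `"cost"`.
#' @return A `data.frame` with columns `label`, `p_star_base`,
#'   `p_star_perturbed`, `shift_percentage_points`, `status`.
#' @export
one_way_sensitivity <- function(perf = test_performance(), costs,
                                link = stenosis_link("identity"),
                                scenarios, type = c("ce", "cost"),
                                domain = c(0.01, 1)) {
  type <- match.arg(type)
  finder <- if (type == "ce") find_ce_crossing else find_cost_crossing
  if (length(scenarios) == 0L) {
    return(data.frame(label = character(), p_star_base = numeric(),
                      p_star_perturbed = numeric(),
                      shift_percentage_points = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  base <- finder(perf, costs, link, domain)
  rows <- lapply(scenarios, function(sc) {
    pert <- apply_scenario(sc, perf, costs, link)
    if (!pert$valid) {
      return(data.frame(label = sc$label, p_star_base = base$p_star,
                        p_star_perturbed = NA_real_,
                        shift_percentage_points = NA_real_,
                        status = "invalid", stringsAsFactors = FALSE))
    }
    res <- finder(pert$perf, pert$costs, pert$link, domain)
    shift <- if (base$status == "found" && res$status == "found") {
      100 * (res$p_star - base$p_star)
    } else NA_real_
    data.frame(label = sc$label, p_star_base = base$p_star,
               p_star_perturbed = res$p_star,
               shift_percentage_points = shift,
               status = res$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
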
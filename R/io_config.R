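#' Load a country configuration file
#'
#' Reads a YAML configuration describing one health-care system: a country
#' label, a mandatory provenance note (so synthetic example fees are never
#' mistaken for a payer's published schedule), the cost schedule, optional
#' test-performance overrides (literature defaults fill any omitted field),
#' and an optional calibration-points table for the ischemia-stenosis link.
#'
#' @param path Path to a YAML file.
#' @return A list of class `country_config` with elements `country_label`,
#'   `provenance_note`, `costs` ([cost_schedule()]), `performance`
#'   ([test_performance()]), `link` ([stenosis_link()]).
#' @examples
#' cfg <- load_config(system.file("extdata", "synthetic_country.yaml",
#'                                package = "cadcea"))
#' cfg$costs
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$provenance_note) || !nzchar(trimws(raw$provenance_note))) {
    stop("validation error: 'provenance_note' is mandatory and non-empty",
         call. = FALSE)
  }
  required_costs <- c("f_cmr", "f_cxa_outpatient", "f_ffr", "c_complication")
  missing_fields <- setdiff(required_costs, names(raw$costs))
  if (length(missing_fields)) {
    stop(sprintf("validation error: missing mandatory cost field(s): %s",
                 paste(missing_fields, collapse = ", ")), call. = FALSE)
  }
  cost_args <- raw$costs
  cost_args$currency <- raw$currency %||% "XXX"
  costs <- tryCatch(do.call(cost_schedule, cost_args),
                    error = function(e) stop(sprintf("validation error: %s",
                                                     conditionMessage(e)),
                                             call. = FALSE))
  perf <- tryCatch(do.call(test_performance, raw$performance %||% list()),
                   error = function(e) stop(sprintf("validation error: %s",
                                                    conditionMessage(e)),
                                            call. = FALSE))
  link <- if (!is.null(raw$link_points_path)) {
    pts_path <- raw$link_points_path
    if (!file.exists(pts_path)) {
      pts_path <- file.path(dirname(path), raw$link_points_path)
    }
    pts <- read_link_points(pts_path)
    fit_link(pts, raw$link_form %||% "linear_clipped")
  } else {
    stenosis_link(raw$link_form %||% "identity",
                  parameters = unlist(raw$link_parameters %||% list()))
  }
  structure(list(country_label = raw$country_label %||% "unnamed",
                 provenance_note = raw$provenance_note,
                 costs = costs, performance = perf, link = link),
            class = "country_config")
}

#' Write a country configuration file
#'
#' Inverse of [load_config()]: serialises a `country_config` to YAML so
#' that loading it back yields an identical configuration.
#'
#' @param config A `country_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "country_config"))
  costs <- unclass(config$costs)
  currency <- costs$currency
  costs$currency <- NULL
  out <- list(country_label = config$country_label,
              provenance_note = config$provenance_note,
              currency = currency,
              costs = costs,
              performance = unclass(config$performance),
              link_form = config$link$form)
  if (length(config$link$parameters)) {
    out$link_parameters <- as.list(config$link$parameters)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read link calibration points from a delimited table
#'
#' Expects tab- or comma-separated columns `p_isch`, `p_sten`, and
#' optionally `weight` and `threshold_label`.
#'
#' @param path Path to the table.
#' @return A [link_points()] table.
#' @export
read_link_points <- function(path) {
  if (!file.exists(path)) stop(sprintf("link points file not found: %s", path),
                               call. = FALSE)
  tab <- utils::read.delim(path, sep = "", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("p_isch", "p_sten") %in% names(tab))) {
    stop("link points table needs columns 'p_isch' and 'p_sten'",
         call. = FALSE)
  }
  link_points(tab$p_isch, tab$p_sten,
              weight = tab$weight %||% 1,
              threshold_label = as.character(tab$threshold_label[1L] %||% "0.75"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.country_config <- function(x, ...) {
  cat(sprintf("Country config: %s [%s]\n", x$country_label, x$provenance_note))
  print(x$costs)
  print(x$performance)
  print(x$link)
  invisible(x)
}
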
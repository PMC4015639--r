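#' Construct a link between ischemia prevalence and stenosis prevalence
#'
#' To cost the invasive strategy, the fraction of patients with a >= 50%
#' diameter stenosis on angiography (who then undergo FFR) must be known at
#' each pre-test likelihood of hemodynamically significant disease. That
#' relationship is represented as a monotone map `p_isch -> p_sten`, clipped
#' to `[0, 1]`. Three functional forms are supported:
#' `identity` (every stenosis is flow-limiting), `linear_clipped`
#' (`a + b * p`, clipped), and `logit_linear` (linear on the logit-logit
#' scale).
#'
#' @param form One of `"identity"`, `"linear_clipped"`, `"logit_linear"`.
#' @param parameters Numeric parameters: none for `identity`, `c(intercept,
#'   slope)` for the other two forms (logit-scale for `logit_linear`).
#' @param ffr_threshold_label Which FFR positivity threshold the calibration
#'   encodes, `"0.75"` (default) or `"0.80"`; a label only.
#'
#' @return An object of class `stenosis_link`.
#' @examples
#' lk <- stenosis_link("linear_clipped", c(0.2, 1))
#' apply_link(lk, 0.5)   # 0.7
#' apply_link(lk, 0.95)  # clipped to 1
#' @export
stenosis_link <- function(form = c("identity", "linear_clipped", "logit_linear"),
                          parameters = numeric(),
                          ffr_threshold_label = c("0.75", "0.80")) {
  form <- match.arg(form)
  ffr_threshold_label <- match.arg(ffr_threshold_label)
  if (form == "identity") {
    parameters <- numeric()
  } else {
    if (length(parameters) != 2L || anyNA(parameters)) {
      stop(sprintf("form '%s' requires parameters c(intercept, slope)", form),
           call. = FALSE)
    }
    if (parameters[2L] < 0) {
      stop("fitted/declared slope is negative: link must be non-decreasing",
           call. = FALSE)
    }
  }
  structure(list(form = form, parameters = unname(parameters),
                 ffr_threshold_label = ffr_threshold_label),
            class = "stenosis_link")
}

#' Calibration points for the ischemia-stenosis link
#'
#' One row per source study: the fraction FFR-positive (`p_isch`), the
#' fraction with >= 50% stenosis (`p_sten`), and a weight (study size).
#'
#' @param p_isch,p_sten Probabilities; `p_sten >= p_isch` is expected since
#'   every flow-limiting lesion is an anatomic stenosis.
#' @param weight Positive weights, recycled if scalar.
#' @param threshold_label FFR threshold the points encode.
#' @return A `data.frame` of class `link_points`.
#' @export
link_points <- function(p_isch, p_sten, weight = 1,
                        threshold_label = c("0.75", "0.80")) {
  threshold_label <- match.arg(threshold_label)
  assert_probabilities(p_isch, "p_isch")
  assert_probabilities(p_sten, "p_sten")
  if (length(p_sten) != length(p_isch)) {
    stop("'p_isch' and 'p_sten' must have equal length", call. = FALSE)
  }
  weight <- rep_len(weight, length(p_isch))
  if (any(weight <= 0) || anyNA(weight)) {
    stop("'weight' must be positive", call. = FALSE)
  }
  if (any(p_sten < p_isch)) {
    warning("some calibration points have p_sten < p_isch; ",
            "ischemia should imply stenosis", call. = FALSE)
  }
  structure(data.frame(p_isch = p_isch, p_sten = p_sten, weight = weight,
                       threshold_label = threshold_label,
                       stringsAsFactors = FALSE),
            class = c("link_points", "data.frame"))
}

#' Fit the ischemia-stenosis link to study-level calibration points
#'
#' Weighted least squares of the chosen functional form. `logit_linear` fits
#' on the logit-logit scale and drops boundary points (0 or 1) where the
#' logit is undefined. A fit with negative slope violates the monotonicity
#' requirement and is an error.
#'
#' @param points A [link_points()] table (or data.frame with columns
#'   `p_isch`, `p_sten`, and optionally `weight`).
#' @param form Functional form; see [stenosis_link()].
#' @return A calibrated [stenosis_link()].
#' @examples
#' pts <- link_points(c(0.2, 0.6), c(0.4, 0.8))
#' fit_link(pts, "linear_clipped")   # slope 1, intercept 0.2
#' @export
fit_link <- function(points, form = c("linear_clipped", "logit_linear", "identity")) {
  form <- match.arg(form)
  threshold <- if (!is.null(points$threshold_label)) {
    as.character(points$threshold_label[1L])
  } else "0.75"
  if (form == "identity") {
    return(stenosis_link("identity", ffr_threshold_label = threshold))
  }
  if (is.null(points$weight)) points$weight <- 1
  pts <- points
  if (form == "logit_linear") {
    keep <- pts$p_isch > 0 & pts$p_isch < 1 & pts$p_sten > 0 & pts$p_sten < 1
    pts <- pts[keep, , drop = FALSE]
  }
  if (length(unique(pts$p_isch)) < 2L) {
    stop("calibration requires >= 2 points with distinct p_isch", call. = FALSE)
  }
  if (form == "linear_clipped") {
    fit <- stats::lm(p_sten ~ p_isch, data = pts, weights = pts$weight)
  } else {
    lpts <- data.frame(x = stats::qlogis(pts$p_isch),
                       y = stats::qlogis(pts$p_sten))
    fit <- stats::lm(y ~ x, data = lpts, weights = pts$weight)
  }
  coefs <- unname(stats::coef(fit))
  if (coefs[2L] < 0) {
    stop("fitted slope is negative: monotone calibration failed", call. = FALSE)
  }
  stenosis_link(form, coefs, ffr_threshold_label = threshold)
}

#' Evaluate the ischemia-stenosis link
#'
#' @param link A calibrated [stenosis_link()].
#' @param p_isch Pre-test likelihood(s) of significant disease, in `[0, 1]`.
#' @return Stenosis prevalence(s), non-decreasing in `p_isch` and clipped to
#'   `[0, 1]`.
#' @export
apply_link <- function(link, p_isch) {
  stopifnot(inherits(link, "stenosis_link"))
  assert_probabilities(p_isch, "p_isch")
  out <- switch(link$form,
    identity = p_isch,
    linear_clipped = link$parameters[1L] + link$parameters[2L] * p_isch,
    logit_linear = {
      # boundary inputs map to themselves (logit undefined there)
      res <- p_isch
      inner <- p_isch > 0 & p_isch < 1
      res[inner] <- stats::plogis(link$parameters[1L] +
                                    link$parameters[2L] * stats::qlogis(p_isch[inner]))
      res
    })
  pmin(pmax(out, 0), 1)
}

#' @export
print.stenosis_link <- function(x, ...) {
  cat(sprintf("Stenosis link: %s (FFR threshold %s)\n",
              x$form, x$ffr_threshold_label))
  if (length(x$parameters)) {
    cat(sprintf("  intercept = %.6g, slope = %.6g\n",
                x$parameters[1L], x$parameters[2L]))
  }
  invisible(x)
}
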
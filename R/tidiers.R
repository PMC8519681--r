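#' Broom-style tidiers for fitted primary-tail models
#'
#' `tidy()` returns one row per model parameter, `glance()` a one-row
#' model summary, and `augment()` the fitted points with modelled dose
#' and per-point percent deviation. `tidy()` also works on bare
#' [primary_tail_params()] and [energy_regressions()] objects.
#'
#' @param x A `pdd_fit` object (or `primary_tail_params` /
#'   `energy_regressions` for `tidy()`).
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name tidy.pdd_fit
NULL

#' @rdname tidy.pdd_fit
#' @export
tidy.pdd_fit <- function(x, ...) {
  p <- x$params
  terms <- c("N", "n", "mu", "t")
  est <- c(p$N, p$n, p$mu, p$t)
  if (p$tail_form == "sigmoid") {
    terms <- c(terms, "p")
    est <- c(est, p$p)
  }
  tibble::tibble(term = terms, estimate = est)
}

#' @rdname tidy.pdd_fit
#' @export
glance.pdd_fit <- function(x, ...) {
  tibble::tibble(
    rms_deviation = x$rms_deviation,
    sse = x$sse,
    converged = x$converged,
    n_points = x$n_points,
    tail_form = x$params$tail_form,
    weighting = x$weighting
  )
}

#' @rdname tidy.pdd_fit
#' @export
augment.pdd_fit <- function(x, ...) {
  tibble::tibble(
    depth_mm = x$data$depth_mm,
    dose_percent = x$data$dose_percent,
    .fitted = x$fitted,
    .deviation_pct = x$deviation_pct
  )
}

#' Predict modelled dose at new depths
#'
#' @param object A `pdd_fit` object.
#' @param depths Depths in mm (defaults to the fitted depths).
#' @param ... Unused.
#' @return A [depth_dose_curve()] tibble of the normalized model.
#' @export
predict.pdd_fit <- function(object, depths = NULL, ...) {
  depths <- depths %||% object$data$depth_mm
  pdd_model(depths, object$params, normalize = TRUE)
}
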
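#' Depth-dose curves
#'
#' A depth-dose curve is a tibble with columns `depth_mm` (strictly
#' increasing, >= 0) and `dose_percent` (finite, >= 0), one row per
#' sampled depth along the beam central axis. All package functions
#' accept any data frame with those two columns; `depth_dose_curve()`
#' validates and adds the `"pdd_curve"` class used by [autoplot()].
#'
#' @param depth_mm Depths in mm, strictly increasing, all >= 0.
#' @param dose_percent Relative dose in percent of the maximum, same
#'   length as `depth_mm`, finite and >= 0.
#' @param label Optional free-text identifier (energy/cone), stored as
#'   an attribute.
#' @return A tibble of class `"pdd_curve"`.
#' @examples
#' depth_dose_curve(c(0, 10, 20), c(100, 50, 0))
#' @export
depth_dose_curve <- function(depth_mm, dose_percent, label = NULL) {
  curve <- tibble::tibble(depth_mm = as.numeric(depth_mm),
                          dose_percent = as.numeric(dose_percent))
  validate_curve(curve)
  class(curve) <- c("pdd_curve", class(curve))
  attr(curve, "label") <- label
  curve
}

#' Coerce a data frame to a depth-dose curve
#'
#' @param x A data frame with columns `depth_mm` and `dose_percent`.
#' @inheritParams depth_dose_curve
#' @return A validated `"pdd_curve"` tibble.
#' @export
as_pdd_curve <- function(x, label = NULL) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.", class = "epdd_input_error")
  missing_cols <- setdiff(c("depth_mm", "dose_percent"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", "), "."),
          class = "epdd_input_error")
  }
  depth_dose_curve(x$depth_mm, x$dose_percent,
                   label = label %||% attr(x, "label"))
}

# Shared validity rules for every curve-consuming operation.
validate_curve <- function(curve, min_points = 1L, call_name = NULL) {
  what <- if (is.null(call_name)) "curve" else sprintf("curve passed to %s()", call_name)
  if (!is.data.frame(curve) ||
      !all(c("depth_mm", "dose_percent") %in% names(curve))) {
    abort(sprintf("The %s must have columns `depth_mm` and `dose_percent`.", what),
          class = "epdd_input_error")
  }
  d <- curve$depth_mm
  v <- curve$dose_percent
  if (nrow(curve) < min_points) {
    abort(sprintf("The %s needs at least %d points (has %d).",
                  what, min_points, nrow(curve)),
          class = "epdd_input_error")
  }
  if (!is.numeric(d) || !is.numeric(v) || anyNA(d) || anyNA(v) ||
      any(!is.finite(d)) || any(!is.finite(v))) {
    abort(sprintf("The %s must be numeric and finite.", what),
          class = "epdd_input_error")
  }
  if (any(d < 0)) {
    abort("Depths must be >= 0 mm.", class = "epdd_input_error")
  }
  if (nrow(curve) > 1 && any(diff(d) <= 0)) {
    abort("Depths must be strictly increasing (no duplicates).",
          class = "epdd_input_error")
  }
  if (any(v < 0)) {
    abort("Dose values must be >= 0 %.", class = "epdd_input_error")
  }
  invisible(curve)
}

#' Rescale a curve so its maximum is 100
#'
#' @param curve A depth-dose curve (data frame with `depth_mm`,
#'   `dose_percent`).
#' @return The curve with `dose_percent` rescaled to peak at exactly 100.
#' @export
normalize_pdd <- function(curve) {
  validate_curve(curve, call_name = "normalize_pdd")
  m <- max(curve$dose_percent)
  if (m <= 0) {
    abort("Cannot normalize: curve maximum is not positive.",
          class = "epdd_normalization_error")
  }
  curve$dose_percent <- 100 * curve$dose_percent / m
  curve
}

#' @export
print.pdd_curve <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("<pdd_curve> %d points, %g-%g mm%s\n", nrow(x),
              min(x$depth_mm), max(x$depth_mm),
              if (is.null(lbl)) "" else paste0(", ", lbl)))
  NextMethod()
}
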
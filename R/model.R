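#' Primary component of the depth-dose model
#'
#' Evaluates `primary(x) = (x^0.1 / (N + x^0.2)) * exp(-mu * x)`, the
#' build-up/attenuation part of the primary-tail percent depth dose
#' model. The numerator vanishes at the surface, so `primary(0) = 0`;
#' the hardening factor `N` controls how quickly the curve grows with
#' depth and `mu` (mm^-1) is a slow exponential attenuation.
#'
#' @param x Depth in water, mm, `>= 0`. Vectorized.
#' @param N Hardening factor, `> 0`.
#' @param mu Linear attenuation factor, mm^-1, `>= 0`.
#' @return Dimensionless primary values, same length as `x`.
#' @examples
#' pdd_primary(25, N = 8.9, mu = 5e-4)
#' @export
pdd_primary <- function(x, N, mu) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0) {
    abort("`N` must be a single number > 0.", class = "epdd_domain_error")
  }
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0) {
    abort("`mu` must be a single number >= 0.", class = "epdd_domain_error")
  }
  if (any(x < 0)) abort("Depths must be >= 0 mm.", class = "epdd_domain_error")
  # x^0.1 -> 0 as x -> 0+, so the surface value is exactly 0
  ifelse(x == 0, 0, x^0.1 / (N + x^0.2) * exp(-mu * x))
}

#' Tail component of the depth-dose model
#'
#' The tail multiplies the primary component and carries the distal
#' behaviour plus the bremsstrahlung offset `t`. Two shapes are
#' available:
#'
#' * `"printed"`: `1 - x / (sqrt(n) + x^2) + t`. Equals `1 + t` at the
#'   surface and tends back to `1 + t` at depth, with a shallow minimum
#'   at `x = n^0.25`.
#' * `"sigmoid"`: `1 - x^p / (n^p + x^p) + t`, a logistic-like falloff
#'   dropping from `1 + t` towards `t` with half-value depth `n` (mm)
#'   and sharpness `p`. This is the shape used when fitting measured
#'   scans, whose distal limb the printed form cannot descend.
#'
#' @param x Depth in water, mm, `>= 0`. Vectorized.
#' @param n Spreading factor, `> 0` (half-value depth in mm for the
#'   sigmoid form).
#' @param t Tail-height offset.
#' @param tail_form `"printed"` or `"sigmoid"`.
#' @param p Sharpness exponent for the sigmoid form.
#' @return Dimensionless tail values, same length as `x`.
#' @examples
#' pdd_tail(25, n = 290)
#' pdd_tail(25, n = 48, tail_form = "sigmoid", p = 9)
#' @export
pdd_tail <- function(x, n, t = 0, tail_form = c("printed", "sigmoid"), p = 9) {
  tail_form <- match.arg(tail_form)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    abort("`n` must be a single number > 0.", class = "epdd_domain_error")
  }
  if (any(x < 0)) abort("Depths must be >= 0 mm.", class = "epdd_domain_error")
  if (tail_form == "printed") {
    1 - x / (sqrt(n) + x^2) + t
  } else {
    # written as 1/(1 + (x/n)^p) to avoid overflow of n^p for large p
    ifelse(x == 0, 1 + t, 1 - 1 / (1 + (n / x)^p) + t)
  }
}

#' Evaluate the primary-tail depth-dose model on a grid
#'
#' Pointwise product of [pdd_primary()] and [pdd_tail()] over a depth
#' grid, optionally rescaled so the grid maximum equals exactly 100
#' (the convention of modelled PDD tables). The normalization reference
#' is the grid maximum, not an analytic maximum.
#'
#' @param depths Depth grid in mm, non-empty, strictly increasing, all
#'   `>= 0`.
#' @param params A [primary_tail_params()] object (or anything
#'   [as_primary_tail_params()] accepts).
#' @param normalize If `TRUE` (default), rescale so `max == 100`.
#' @return A [depth_dose_curve()] tibble.
#' @examples
#' pdd_model(seq(0, 80, 5), primary_tail_params(8.9, 290, 5e-4))
#' @export
pdd_model <- function(depths, params, normalize = TRUE) {
  params <- as_primary_tail_params(params)
  if (length(depths) == 0) {
    abort("`depths` must be non-empty.", class = "epdd_input_error")
  }
  if (anyNA(depths) || any(!is.finite(depths)) || any(depths < 0)) {
    abort("`depths` must be finite and >= 0 mm.", class = "epdd_input_error")
  }
  if (length(depths) > 1 && any(diff(depths) <= 0)) {
    abort("`depths` must be strictly increasing.", class = "epdd_input_error")
  }
  raw <- pdd_primary(depths, params$N, params$mu) *
    pdd_tail(depths, params$n, params$t, params$tail_form, params$p)
  if (normalize) {
    if (max(raw) <= 0) {
      abort("Degenerate parameters: raw model is not positive anywhere on the grid.",
            class = "epdd_normalization_error")
    }
    raw <- 100 * raw / max(raw)
  }
  # raw can dip below zero only through a negative tail offset; clamp is
  # deliberate so model output is always a valid dose curve
  raw <- pmax(raw, 0)
  depth_dose_curve(depths, raw)
}
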
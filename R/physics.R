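#' Energy regressions linking model parameters to mean energy
#'
#' Linear relations between the mean surface energy `E0` (MeV) and the
#' primary-tail parameters, used to seed fits and to predict parameters
#' at unmeasured energies:
#' `n = 31.667 E0 - 88`, `N = 0.9975 E0 - 2.8535`,
#' `ln(mu) = -0.1355 E0 - 6.0986` (mu stored positive, mm^-1).
#' Defaults are the published coefficients; [refit_energy_regressions()]
#' re-estimates them from a per-energy parameter table.
#'
#' @param n_slope,n_intercept Coefficients of `n ~ E0`.
#' @param N_slope,N_intercept Coefficients of `N ~ E0`.
#' @param lnmu_slope,lnmu_intercept Coefficients of `ln(mu) ~ E0`.
#' @return An object of class `"energy_regressions"`.
#' @examples
#' energy_regressions()
#' @export
energy_regressions <- function(n_slope = 31.667, n_intercept = -88,
                               N_slope = 0.9975, N_intercept = -2.8535,
                               lnmu_slope = -0.1355, lnmu_intercept = -6.0986) {
  vals <- c(n_slope = n_slope, n_intercept = n_intercept,
            N_slope = N_slope, N_intercept = N_intercept,
            lnmu_slope = lnmu_slope, lnmu_intercept = lnmu_intercept)
  if (any(!is.finite(vals))) {
    abort("All regression coefficients must be finite.",
          class = "epdd_domain_error")
  }
  structure(as.list(vals), class = "energy_regressions")
}

#' @export
print.energy_regressions <- function(x, ...) {
  cat("<energy_regressions>\n")
  cat(sprintf("  n      = %g * E0 + %g\n", x$n_slope, x$n_intercept))
  cat(sprintf("  N      = %g * E0 + %g\n", x$N_slope, x$N_intercept))
  cat(sprintf("  ln(mu) = %g * E0 + %g\n", x$lnmu_slope, x$lnmu_intercept))
  invisible(x)
}

#' @rdname tidy.pdd_fit
#' @export
tidy.energy_regressions <- function(x, ...) {
  tibble::tibble(
    response = c("n", "N", "ln_mu"),
    slope = c(x$n_slope, x$N_slope, x$lnmu_slope),
    intercept = c(x$n_intercept, x$N_intercept, x$lnmu_intercept)
  )
}

#' Predict primary-tail parameters from beam energy
#'
#' Applies the energy regressions to obtain `n`, `N` and
#' `mu = exp(lnmu_slope * E + lnmu_intercept)` at a given mean energy;
#' the tail offset `t` starts at 0. Energies outside the measured
#' 6-18 MeV span trigger a warning; energies at which the regressions
#' give non-positive `n` or `N` are a domain error.
#'
#' @param energy_mev Mean beam energy in MeV.
#' @param reg An [energy_regressions()] object.
#' @param warn Warn when extrapolating outside 6-18 MeV (default TRUE).
#' @return A [primary_tail_params()] object with `t = 0`.
#' @examples
#' params_from_energy(12)
#' @export
params_from_energy <- function(energy_mev, reg = energy_regressions(),
                               warn = TRUE) {
  if (!is.numeric(energy_mev) || length(energy_mev) != 1L ||
      !is.finite(energy_mev)) {
    abort("`energy_mev` must be a single finite number.",
          class = "epdd_domain_error")
  }
  if (warn && (energy_mev < 6 || energy_mev > 18)) {
    rlang::warn(sprintf(
      "Energy %g MeV is outside the 6-18 MeV span of the fitted regressions; extrapolating.",
      energy_mev))
  }
  n <- reg$n_slope * energy_mev + reg$n_intercept
  N <- reg$N_slope * energy_mev + reg$N_intercept
  if (n <= 0 || N <= 0) {
    abort(sprintf("Regressions give non-positive parameters at %g MeV (n = %g, N = %g).",
                  energy_mev, n, N),
          class = "epdd_domain_error")
  }
  mu <- exp(reg$lnmu_slope * energy_mev + reg$lnmu_intercept)
  primary_tail_params(N = N, n = n, mu = mu, t = 0)
}

#' Refit the energy regressions from a per-energy parameter table
#'
#' Ordinary least squares of `n`, `N` and `ln(mu)` against energy.
#'
#' @param param_table Data frame with columns `energy_mev`, `n`, `N`,
#'   `mu` (one row per beam energy, at least 3 rows, `mu > 0`).
#' @return An [energy_regressions()] object.
#' @examples
#' refit_energy_regressions(pdd_reference("table2"))
#' @export
refit_energy_regressions <- function(param_table) {
  req <- c("energy_mev", "n", "N", "mu")
  if (!is.data.frame(param_table) || !all(req %in% names(param_table))) {
    abort("`param_table` needs columns energy_mev, n, N, mu.",
          class = "epdd_input_error")
  }
  if (nrow(param_table) < 3) {
    abort("Need at least 3 energies to refit the regressions.",
          class = "epdd_input_error")
  }
  e <- param_table$energy_mev
  if (length(unique(e)) < 2) {
    abort("Energies are collinear (all identical); singular fit.",
          class = "epdd_singular_error")
  }
  if (any(param_table$mu <= 0)) {
    abort("`mu` must be > 0 to regress ln(mu).", class = "epdd_domain_error")
  }
  cn <- coef(lm(param_table$n ~ e))
  cN <- coef(lm(param_table$N ~ e))
  cm <- coef(lm(log(param_table$mu) ~ e))
  energy_regressions(
    n_slope = unname(cn[2]), n_intercept = unname(cn[1]),
    N_slope = unname(cN[2]), N_intercept = unname(cN[1]),
    lnmu_slope = unname(cm[2]), lnmu_intercept = unname(cm[1])
  )
}

#' Empirical stopping-power depth correction
#'
#' Water-to-air stopping-power ratio modelled from the primary-tail
#' parameters: `(-0.042 ln N + 1.072) * exp((-n * 5e-5 + 0.0381) * x)`.
#' The depth `x` enters the exponent in cm by default: with mm the
#' ratio would reach physically impossible values (~3.2 at 50 mm for a
#' 12 MeV beam) whereas with cm it stays in the plausible ~0.98-1.10
#' band; `depth_unit = "mm"` forces the literal mm reading.
#'
#' @param N Hardening factor, `> 0`.
#' @param n Spreading factor, `> 0`.
#' @param depth Depth in water, `>= 0`, in the unit given. Vectorized.
#' @param depth_unit `"cm"` (default) or `"mm"`.
#' @return Dimensionless stopping-power ratio.
#' @examples
#' stopping_power(8.9, 290, 0)   # 0.9802
#' stopping_power(8.9, 290, 5)   # ~1.103 at 5 cm
#' @export
stopping_power <- function(N, n, depth, depth_unit = c("cm", "mm")) {
  depth_unit <- match.arg(depth_unit)
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0) {
    abort("`N` must be a single number > 0.", class = "epdd_domain_error")
  }
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    abort("`n` must be a single number > 0.", class = "epdd_domain_error")
  }
  if (any(!is.finite(depth)) || any(depth < 0)) {
    abort("`depth` must be finite and >= 0.", class = "epdd_domain_error")
  }
  (-0.042 * log(N) + 1.072) * exp((-n * 5e-5 + 0.0381) * depth)
}

#' Convert between ionization-reading and dose curves
#'
#' Pointwise multiplies (`"reading_to_dose"`) or divides
#' (`"dose_to_reading"`) a curve by the empirical [stopping_power()]
#' at each depth, then renormalizes to max 100. The direction must be
#' chosen explicitly; there is no default.
#'
#' @param curve A depth-dose (or percent-reading) curve.
#' @param direction `"reading_to_dose"` or `"dose_to_reading"`.
#' @param N,n Primary-tail parameters of the beam, or supply `params`.
#' @param params Optional [primary_tail_params()] supplying `N` and `n`.
#' @param depth_unit Unit in which depth enters the stopping-power
#'   exponent; `"cm"` (default) or `"mm"`. Curve depths are always mm.
#' @return The converted, renormalized curve.
#' @examples
#' scan <- pdd_model(seq(1, 80, 1), primary_tail_params(8.9, 290, 5e-4))
#' convert_reading_dose(scan, "reading_to_dose", N = 8.9, n = 290)
#' @export
convert_reading_dose <- function(curve, direction, N = NULL, n = NULL,
                                 params = NULL,
                                 depth_unit = c("cm", "mm")) {
  if (missing(direction)) {
    abort("`direction` is required: \"reading_to_dose\" or \"dose_to_reading\".",
          class = "epdd_input_error")
  }
  direction <- match.arg(direction, c("reading_to_dose", "dose_to_reading"))
  depth_unit <- match.arg(depth_unit)
  validate_curve(curve, call_name = "convert_reading_dose")
  if (!is.null(params)) {
    params <- as_primary_tail_params(params)
    N <- params$N
    n <- params$n
  }
  if (is.null(N) || is.null(n)) {
    abort("Supply `N` and `n` (or `params`).", class = "epdd_input_error")
  }
  depth <- if (depth_unit == "cm") curve$depth_mm / 10 else curve$depth_mm
  sp <- stopping_power(N, n, depth, depth_unit = depth_unit)
  if (any(sp <= 0)) {
    abort("Stopping power is non-positive at some depth.",
          class = "epdd_domain_error")
  }
  v <- if (direction == "reading_to_dose") curve$dose_percent * sp
       else curve$dose_percent / sp
  out <- curve
  out$dose_percent <- v
  normalize_pdd(out)
}

#' Printed relation between attenuation factor and falloff slope
#'
#' Evaluates `atan(slope) = -6.6729 * ln(mu) - 16.623` as printed.
#' This relation is inconsistent with the tabulated falloff data it
#' claims to describe (at `mu = 0.0005` it returns 34.10 while the
#' directly measured `atan(slope)` is -1.35473 rad), so every call
#' emits a warning; the function is provided for completeness and for
#' documenting the inconsistency. Re-estimate the relation from data
#' with [refit_slope_mu()].
#'
#' @param mu Linear attenuation factor, mm^-1, `> 0`. Vectorized.
#' @return The printed right-hand side (nominally radians).
#' @export
slope_mu_relation <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    abort("`mu` must be > 0.", class = "epdd_domain_error")
  }
  rlang::warn(
    paste("The printed atan(slope) ~ ln(mu) relation does not reproduce",
          "measured atan(slope) values (e.g. 34.10 vs -1.35473 at mu = 5e-4);",
          "its constants appear misprinted. Interpret with caution."),
    class = "epdd_inconsistent_formula")
  -6.6729 * log(mu) - 16.623
}

#' Refit the atan(slope) ~ ln(mu) relation from data
#'
#' Ordinary least squares of `atan(slope)` against `ln(mu)` over a
#' per-energy table, as a usable replacement for the misprinted
#' published constants.
#'
#' @param slope_table Data frame with columns `mu` (> 0) and
#'   `slope_80_20` (%/mm), at least 3 rows.
#' @return One-row tibble with `slope` and `intercept` of
#'   `atan(slope_80_20) ~ ln(mu)`.
#' @examples
#' refit_slope_mu(pdd_reference("table4"))
#' @export
refit_slope_mu <- function(slope_table) {
  if (!is.data.frame(slope_table) ||
      !all(c("mu", "slope_80_20") %in% names(slope_table))) {
    abort("`slope_table` needs columns mu and slope_80_20.",
          class = "epdd_input_error")
  }
  if (nrow(slope_table) < 3) {
    abort("Need at least 3 rows.", class = "epdd_input_error")
  }
  if (any(slope_table$mu <= 0)) {
    abort("`mu` must be > 0.", class = "epdd_domain_error")
  }
  fit <- lm(atan(slope_table$slope_80_20) ~ log(slope_table$mu))
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]))
}
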
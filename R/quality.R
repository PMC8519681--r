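#' Depth at a given percent-of-maximum dose on the distal limb
#'
#' Linear interpolation between the bracketing samples on the
#' descending (distal) side of the curve maximum. `level = 90` gives
#' R90, `level = 50` gives R50.
#'
#' @param curve A depth-dose curve.
#' @param level Dose level as percent of the curve maximum, in (0, 100).
#' @return Depth in mm.
#' @examples
#' tri <- depth_dose_curve(c(0, 10, 20), c(100, 50, 0))
#' depth_at_dose_level(tri, 50) # 10
#' @export
depth_at_dose_level <- function(curve, level) {
  validate_curve(curve, call_name = "depth_at_dose_level")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 100) {
    abort("`level` must be a single percent in (0, 100).",
          class = "epdd_domain_error")
  }
  d <- curve$depth_mm
  v <- curve$dose_percent
  im <- which.max(v)
  target <- level / 100 * v[im]
  if (im == nrow(curve)) {
    abort(sprintf("The %g%% level is never crossed distally.", level),
          class = "epdd_not_found_error")
  }
  for (i in im:(nrow(curve) - 1L)) {
    if (v[i] >= target && v[i + 1L] < target) {
      return(d[i] + (v[i] - target) / (v[i] - v[i + 1L]) * (d[i + 1L] - d[i]))
    }
  }
  abort(sprintf("The %g%% level is never crossed distally.", level),
        class = "epdd_not_found_error")
}

#' Least-squares line through the 80-20% distal falloff
#'
#' Fits an ordinary least-squares line through every sample whose dose
#' lies within \[20%, 80%\] of the maximum on the distal limb, with the
#' 80% and 20% endpoints included by linear interpolation. This line is
#' the operational "tangent at the inflection" used to define the
#' practical range.
#'
#' @param curve A depth-dose curve whose distal limb crosses both 80%
#'   and 20% of the maximum.
#' @return One-row tibble with `slope` (%/mm, negative), `intercept`
#'   (%), `d80_mm`, `d20_mm`.
#' @export
falloff_line <- function(curve) {
  validate_curve(curve, call_name = "falloff_line")
  d80 <- depth_at_dose_level(curve, 80)
  d20 <- depth_at_dose_level(curve, 20)
  vmax <- max(curve$dose_percent)
  inside <- curve$depth_mm > d80 & curve$depth_mm < d20
  xs <- c(d80, curve$depth_mm[inside], d20)
  ys <- c(0.8 * vmax, curve$dose_percent[inside], 0.2 * vmax)
  if (length(xs) < 2) {
    abort("Fewer than 2 points in the 80-20% window.",
          class = "epdd_not_found_error")
  }
  fit <- lm(ys ~ xs)
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 d80_mm = d80, d20_mm = d20)
}

#' Slope of the 80-20% distal falloff
#'
#' @inheritParams falloff_line
#' @return Slope in %/mm (negative on any physical electron PDD).
#' @examples
#' slope_80_20(depth_dose_curve(c(0, 10, 20), c(100, 50, 0))) # -5
#' @export
slope_80_20 <- function(curve) {
  falloff_line(curve)$slope
}

#' Bremsstrahlung (X-ray) contamination level
#'
#' Estimates the flat photon-background plateau beyond the electron
#' range. Candidate samples are those beyond the distal 10%-of-maximum
#' crossing; the plateau is the longest terminal run of candidates over
#' which consecutive slopes stay within `slope_tol` %/mm in magnitude
#' (i.e. the tail has actually flattened), and the estimate is the
#' median dose over that run. This keeps samples still on the falloff
#' out of the estimate and is robust to the non-monotone noise of real
#' tails.
#'
#' @param curve A depth-dose curve extending beyond its distal 10%
#'   crossing.
#' @param slope_tol Flatness threshold in %/mm (default 0.1).
#' @return Plateau dose in percent of maximum.
#' @export
xray_contamination <- function(curve, slope_tol = 0.1) {
  validate_curve(curve, call_name = "xray_contamination")
  d10 <- depth_at_dose_level(curve, 10)
  beyond <- which(curve$depth_mm > d10)
  if (length(beyond) == 0) {
    abort("No samples beyond the distal 10% crossing.",
          class = "epdd_not_found_error")
  }
  d <- curve$depth_mm[beyond]
  v <- curve$dose_percent[beyond]
  k <- length(v)
  start <- k
  if (k > 1) {
    for (i in (k - 1L):1L) {
      sl <- (v[i + 1L] - v[i]) / (d[i + 1L] - d[i])
      if (abs(sl) <= slope_tol) start <- i else break
    }
  }
  median(v[start:k])
}

#' Practical range Rp
#'
#' Depth at which the 80-20% falloff line (the operational inflection
#' tangent, see [falloff_line()]) meets the horizontal bremsstrahlung
#' background estimated by [xray_contamination()].
#'
#' @inheritParams falloff_line
#' @return Practical range in mm.
#' @export
practical_range <- function(curve) {
  line <- falloff_line(curve)
  if (line$slope >= 0) {
    abort("Distal falloff slope is not negative; Rp undefined.",
          class = "epdd_not_found_error")
  }
  bg <- xray_contamination(curve)
  (bg - line$intercept) / line$slope
}

#' Mean energy at the surface from R50
#'
#' `E0 = 2.33 MeV/cm * R50`, the standard beam-quality conversion for
#' clinical electron beams.
#'
#' @param r50_cm Half-value depth R50 in cm, `> 0`. Vectorized.
#' @return Mean surface energy in MeV.
#' @examples
#' mean_energy_from_r50(7.31) # 17.03
#' @export
mean_energy_from_r50 <- function(r50_cm) {
  if (any(!is.finite(r50_cm)) || any(r50_cm <= 0)) {
    abort("`r50_cm` must be > 0.", class = "epdd_domain_error")
  }
  2.33 * r50_cm
}

#' Most probable surface energy from the practical range
#'
#' NACP quadratic in the practical range:
#' `(E_p)0 = C1 + C2 * Rp + C3 * Rp^2` with `C1 = 0.22` MeV,
#' `C2 = 1.98` MeV/cm, `C3 = 0.0025` MeV/cm^2 for water.
#'
#' @param rp_cm Practical range in cm, `>= 0`. Vectorized.
#' @return Most probable energy at the surface, MeV.
#' @examples
#' most_probable_energy(3.02)
#' @export
most_probable_energy <- function(rp_cm) {
  if (any(!is.finite(rp_cm)) || any(rp_cm < 0)) {
    abort("`rp_cm` must be >= 0.", class = "epdd_domain_error")
  }
  0.22 + 1.98 * rp_cm + 0.0025 * rp_cm^2
}

#' Full beam-quality report for a depth-dose curve
#'
#' Assembles every clinical beam-quality metric the package extracts:
#' depth of maximum, R90, R50, practical range, 80-20% falloff slope,
#' bremsstrahlung contamination, and the mean energy `2.33 * R50`.
#' Metrics whose extraction fails on the given curve are reported as
#' `NA`, never silently zero. `r_max_mm` and `d_max_mm` both report the
#' argmax depth of the supplied curve; distinguishing the ionization
#' maximum from the dose maximum requires both the reading and the
#' converted curve (see [convert_reading_dose()]).
#'
#' @param curve A depth-dose curve with at least 4 points.
#' @return One-row tibble with columns `r_max_mm`, `d_max_mm`,
#'   `r90_mm`, `r50_mm`, `rp_mm`, `slope_80_20`, `xray_pct`, `e0_mev`.
#' @examples
#' scan <- pdd_model(seq(1, 100, 0.5),
#'   primary_tail_params(8.9, 48, 5e-4, 0.02, tail_form = "sigmoid"))
#' beam_quality(scan)
#' @export
beam_quality <- function(curve) {
  validate_curve(curve, min_points = 4L, call_name = "beam_quality")
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  dmax <- curve$depth_mm[which.max(curve$dose_percent)]
  r50 <- try_na(depth_at_dose_level(curve, 50))
  tibble::tibble(
    r_max_mm = dmax,
    d_max_mm = dmax,
    r90_mm = try_na(depth_at_dose_level(curve, 90)),
    r50_mm = r50,
    rp_mm = try_na(practical_range(curve)),
    slope_80_20 = try_na(slope_80_20(curve)),
    xray_pct = try_na(xray_contamination(curve)),
    e0_mev = if (is.na(r50)) NA_real_ else mean_energy_from_r50(r50 / 10)
  )
}
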
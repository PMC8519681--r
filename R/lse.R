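#' Minimal square-field side for lateral scatter equilibrium
#'
#' Empirical minimal side length of a square electron field below
#' which the central-axis PDD starts to depend on field size:
#' `S_eq = (n - N)^0.288 / (E0 / n)^0.0195`, returned in cm (the
#' expression is dimensionless as printed; the cm reading is the only
#' one consistent with the tabulated mm values, which are 10x the
#' formula's result).
#'
#' @param n Spreading factor of the beam, `> N`.
#' @param N Hardening factor, `> 0`.
#' @param e0_mev Mean surface energy in MeV, `> 0`.
#' @return Minimal equilibrium side length in cm. Vectorized over
#'   equal-length inputs.
#' @examples
#' lse_min_side(400, 12.3, 14.04) # ~5.94 cm
#' @export
lse_min_side <- function(n, N, e0_mev) {
  if (any(!is.finite(n)) || any(!is.finite(N)) || any(!is.finite(e0_mev))) {
    abort("Inputs must be finite.", class = "epdd_domain_error")
  }
  if (any(N <= 0)) abort("`N` must be > 0.", class = "epdd_domain_error")
  if (any(n <= N)) abort("`n` must exceed `N`.", class = "epdd_domain_error")
  if (any(e0_mev <= 0)) abort("`e0_mev` must be > 0.", class = "epdd_domain_error")
  (n - N)^0.288 / (e0_mev / n)^0.0195
}

#' Literature square-root rule for the equilibrium side
#'
#' The classical energy-based rule `S_eq = 1.58 * sqrt(E0)` in cm.
#' (Sometimes typeset without the root; the square-root form is the one
#' that matches the tabulated values.)
#'
#' @param e0_mev Mean surface energy in MeV, `> 0`. Vectorized.
#' @return Equilibrium side length in cm.
#' @examples
#' lse_sqrt_rule(14.04) # 5.920 cm
#' @export
lse_sqrt_rule <- function(e0_mev) {
  if (any(!is.finite(e0_mev)) || any(e0_mev <= 0)) {
    abort("`e0_mev` must be > 0.", class = "epdd_domain_error")
  }
  1.58 * sqrt(e0_mev)
}

#' Judge a clinical cutout against the equilibrium side length
#'
#' Compares a square-field side against [lse_min_side()] (and the
#' [lse_sqrt_rule()] comparator). A field side equal to the minimal
#' side counts as adequate: equilibrium is reached at that size.
#'
#' @param field_side_mm Field side length to judge, mm, `> 0`.
#' @param n,N,e0_mev Beam parameters as in [lse_min_side()].
#' @return One-row tibble with `field_side_mm`, `s_eq_mm`,
#'   `s_eq_sqrt_mm`, `adequate`, `margin_mm`, and `note` (a warning
#'   string when the field is below the equilibrium side, else `NA`).
#' @examples
#' check_lse(60, n = 210, N = 6.2, e0_mev = 8.66)
#' @export
check_lse <- function(field_side_mm, n, N, e0_mev) {
  if (!is.numeric(field_side_mm) || length(field_side_mm) != 1L ||
      !is.finite(field_side_mm) || field_side_mm <= 0) {
    abort("`field_side_mm` must be a single number > 0.",
          class = "epdd_domain_error")
  }
  s_eq_mm <- 10 * lse_min_side(n, N, e0_mev)
  s_eq_sqrt_mm <- 10 * lse_sqrt_rule(e0_mev)
  adequate <- field_side_mm >= s_eq_mm
  tibble::tibble(
    field_side_mm = field_side_mm,
    s_eq_mm = s_eq_mm,
    s_eq_sqrt_mm = s_eq_sqrt_mm,
    adequate = adequate,
    margin_mm = field_side_mm - s_eq_mm,
    note = if (adequate) NA_character_ else
      sprintf(paste("Field side %.1f mm is below the %.1f mm lateral scatter",
                    "equilibrium side: PDD and output become field-size",
                    "dependent; monitor units may need correction."),
              field_side_mm, s_eq_mm)
  )
}
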
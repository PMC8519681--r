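#' Primary-tail model parameters
#'
#' Container for the four scalars of the empirical primary-tail percent
#' depth dose model: the hardening factor `N`, the spreading factor `n`,
#' the linear attenuation factor `mu` (mm^-1, stored positive and applied
#' as `exp(-mu * x)`), and the tail-height offset `t` that raises the
#' bremsstrahlung plateau.
#'
#' Two tail shapes are supported (see [pdd_tail()]):
#' * `"printed"` — `1 - x / (sqrt(n) + x^2) + t`, the package default;
#' * `"sigmoid"` — `1 - x^p / (k + x^p) + t`, a logistic-like distal
#'   falloff. For this form the stored spreading parameter `n` is the
#'   half-value depth `x0 = k^(1/p)` in mm (so `k = n^p` internally),
#'   which is numerically stable and directly interpretable as the depth
#'   where the tail has dropped half-way.
#'
#' @param N Hardening factor, dimensionless, `> 0`.
#' @param n Spreading factor, `> 0`. Dimensionless for the printed tail;
#'   half-value depth in mm for the sigmoid tail.
#' @param mu Linear attenuation factor in mm^-1, `>= 0`.
#' @param t Tail-height offset, dimensionless, `abs(t) < 1`.
#' @param tail_form `"printed"` or `"sigmoid"`.
#' @param p Sharpness exponent of the sigmoid tail (ignored for the
#'   printed form).
#'
#' @return An object of class `"primary_tail_params"`.
#' @examples
#' primary_tail_params(N = 8.9, n = 290, mu = 5e-4)
#' @export
primary_tail_params <- function(N, n, mu, t = 0,
                                tail_form = c("printed", "sigmoid"),
                                p = 9) {
  tail_form <- match.arg(tail_form)
  for (nm in c("N", "n", "mu", "t", "p")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "epdd_domain_error")
    }
  }
  if (N <= 0) abort("`N` must be > 0.", class = "epdd_domain_error")
  if (n <= 0) abort("`n` must be > 0.", class = "epdd_domain_error")
  if (mu < 0) {
    abort("`mu` must be >= 0 (stored positive, applied as exp(-mu*x)).",
          class = "epdd_domain_error")
  }
  if (abs(t) >= 1) abort("`t` must satisfy abs(t) < 1.", class = "epdd_domain_error")
  if (tail_form == "sigmoid" && p <= 0) {
    abort("`p` must be > 0 for the sigmoid tail.", class = "epdd_domain_error")
  }
  structure(
    list(N = N, n = n, mu = mu, t = t, tail_form = tail_form, p = p),
    class = "primary_tail_params"
  )
}

#' Coerce to primary-tail parameters
#'
#' @param x A `primary_tail_params` object, or a named list / numeric
#'   vector with elements `N`, `n`, `mu` and optionally `t`, `tail_form`, `p`.
#' @return A `primary_tail_params` object.
#' @export
as_primary_tail_params <- function(x) {
  if (inherits(x, "primary_tail_params")) return(x)
  x <- as.list(x)
  if (!all(c("N", "n", "mu") %in% names(x))) {
    abort("Need named elements `N`, `n`, `mu`.", class = "epdd_input_error")
  }
  primary_tail_params(
    N = as.numeric(x$N), n = as.numeric(x$n), mu = as.numeric(x$mu),
    t = if (is.null(x$t)) 0 else as.numeric(x$t),
    tail_form = if (is.null(x$tail_form)) "printed" else x$tail_form,
    p = if (is.null(x$p)) 9 else as.numeric(x$p)
  )
}

#' @export
print.primary_tail_params <- function(x, ...) {
  cat("<primary_tail_params>\n")
  cat(sprintf("  N  = %g (hardening)\n", x$N))
  if (x$tail_form == "printed") {
    cat(sprintf("  n  = %g (spreading)\n", x$n))
  } else {
    cat(sprintf("  n  = %g mm (sigmoid half-value depth)\n", x$n))
  }
  cat(sprintf("  mu = %g mm^-1 (attenuation)\n", x$mu))
  cat(sprintf("  t  = %g (tail offset)\n", x$t))
  cat(sprintf("  tail: %s", x$tail_form))
  if (x$tail_form == "sigmoid") cat(sprintf(" (p = %g)", x$p))
  cat("\n")
  invisible(x)
}

#' @export
as.list.primary_tail_params <- function(x, ...) unclass(x)

#' @rdname tidy.pdd_fit
#' @export
tidy.primary_tail_params <- function(x, ...) {
  tibble::tibble(
    term = c("N", "n", "mu", "t"),
    estimate = c(x$N, x$n, x$mu, x$t)
  )
}
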
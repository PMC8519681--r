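#' Signed percent deviation between modelled and measured dose
#'
#' `(model - measured) / measured * 100`, the per-depth comparison
#' metric used throughout modelled-vs-measured PDD tables.
#'
#' @param model_dose Modelled dose, percent. Vectorized.
#' @param measured_dose Measured dose, percent, `> 0`. Vectorized.
#' @return Signed deviation in percent (unrounded).
#' @examples
#' pdd_deviation(79.93, 83.34) # -4.09 after 2-decimal rounding
#' @export
pdd_deviation <- function(model_dose, measured_dose) {
  if (any(!is.finite(measured_dose)) || any(measured_dose <= 0)) {
    abort("`measured_dose` must be finite and > 0.", class = "epdd_domain_error")
  }
  (model_dose - measured_dose) / measured_dose * 100
}

#' Per-depth deviation table for a parameter set
#'
#' Evaluates the normalized primary-tail model at every depth of a
#' measured curve and tabulates the signed percent deviation, mirroring
#' the layout of modelled-vs-measured comparison tables.
#'
#' @param curve Measured depth-dose curve (data frame with `depth_mm`,
#'   `dose_percent`, all doses `> 0`).
#' @param params A [primary_tail_params()] object.
#' @return A tibble with columns `depth_mm`, `measured`, `modeled`,
#'   `deviation_pct`.
#' @export
deviation_table <- function(curve, params) {
  validate_curve(curve, call_name = "deviation_table")
  params <- as_primary_tail_params(params)
  modeled <- pdd_model(curve$depth_mm, params, normalize = TRUE)$dose_percent
  tibble::tibble(
    depth_mm = curve$depth_mm,
    measured = curve$dose_percent,
    modeled = modeled,
    deviation_pct = pdd_deviation(modeled, curve$dose_percent)
  )
}

# Bounded parameter space for the optimizer, on the natural scale.
fit_bounds <- function(tail_form) {
  if (tail_form == "printed") {
    list(lower = c(N = 1e-3, n = 1e-2, mu = 0, t = -0.999),
         upper = c(N = 100, n = 5000, mu = 1, t = 0.999))
  } else {
    list(lower = c(N = 1e-3, n = 1, mu = 0, t = -0.999, p = 0.5),
         upper = c(N = 100, n = 500, mu = 1, t = 0.999, p = 40))
  }
}

# Normalized model values on a depth vector, from an unnamed parameter
# vector in fit order.
fit_model_values <- function(par, depths, tail_form) {
  raw <- pdd_primary(depths, par[[1]], par[[3]]) *
    pdd_tail(depths, par[[2]], par[[4]], tail_form,
             p = if (tail_form == "sigmoid") par[[5]] else 9)
  if (max(raw) <= 0) return(rep(NA_real_, length(depths)))
  pmax(100 * raw / max(raw), 0)
}

# Data-driven starting point when neither params nor energy is given:
# R50 of the scan -> mean energy -> published regressions.
heuristic_init <- function(curve, tail_form, p) {
  r50 <- tryCatch(depth_at_dose_level(curve, 50), error = function(e) NULL)
  base <- if (!is.null(r50)) {
    e0 <- mean_energy_from_r50(r50 / 10)
    tryCatch(params_from_energy(e0, warn = FALSE),
             error = function(e) primary_tail_params(8.9, 290, 5e-4))
  } else {
    primary_tail_params(8.9, 290, 5e-4)
  }
  if (tail_form == "sigmoid") {
    # half-value depth of the tail sits near the measured R50
    primary_tail_params(base$N, n = if (!is.null(r50)) r50 else 50,
                        mu = base$mu, t = 0.02,
                        tail_form = "sigmoid", p = p)
  } else {
    base
  }
}

#' Fit the primary-tail model to a measured depth-dose curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the normalized primary-tail model against a
#' measured scan. The loss is the sum of squared residuals between the
#' normalized model and the normalized measurement (both peak at 100);
#' with `weighting = "relative"` each residual is divided by the
#' measured dose, so the optimizer minimizes the per-point percent
#' deviations directly. Surface (depth 0) samples are excluded by
#' default because the model is identically 0 there.
#'
#' A deterministic multi-start is used: the initialization itself, then
#' doubling/halving perturbations of `N` and `n`; the best objective
#' wins, and the returned parameters never score worse than the
#' initialization.
#'
#' @param curve Measured depth-dose curve with at least 4 usable points.
#' @param init Optional starting [primary_tail_params()]. If `NULL` and
#'   `energy` is given, the energy regressions supply the start; if both
#'   are `NULL`, a data-driven start is derived from the scan's R50.
#' @param energy Optional nominal/mean beam energy in MeV used to seed
#'   the start via [params_from_energy()].
#' @param include_surface Keep depth-0 samples in the fit (default
#'   `FALSE`).
#' @param weighting `"none"` (unweighted residuals, default) or
#'   `"relative"` (residuals divided by measured dose).
#' @param tail_form Tail shape to fit: `"printed"` (default) or
#'   `"sigmoid"`. The sigmoid additionally fits the sharpness `p`.
#' @param max_iter Iteration cap for the optimizer (values above the
#'   \pkg{minpack.lm} hard cap of 1024 are truncated); the objective
#'   tolerance is `1e-10`.
#' @return An object of class `"pdd_fit"`: a list with `params`
#'   (fitted [primary_tail_params()]), `data` (points used), `fitted`
#'   (modelled dose at those points), `deviation_pct` (per point),
#'   `rms_deviation`, `sse`, `converged`, `n_points`, `init`.
#' @examples
#' truth <- primary_tail_params(8.9, 290, 5e-4, t = 0.02)
#' scan <- pdd_model(1:80, truth)
#' fit <- fit_pdd(scan, init = primary_tail_params(5, 150, 1e-3))
#' glance(fit)
#' @export
fit_pdd <- function(curve, init = NULL, energy = NULL,
                    include_surface = FALSE,
                    weighting = c("none", "relative"),
                    tail_form = c("printed", "sigmoid"),
                    max_iter = 2000) {
  weighting <- match.arg(weighting)
  tail_form <- match.arg(tail_form)
  validate_curve(curve, call_name = "fit_pdd")

  keep <- if (include_surface) rep(TRUE, nrow(curve)) else curve$depth_mm > 0
  keep <- keep & curve$dose_percent > 0
  data <- curve[keep, c("depth_mm", "dose_percent")]
  if (nrow(data) < 4) {
    abort(sprintf("Need at least 4 usable points to fit (have %d).", nrow(data)),
          class = "epdd_input_error")
  }
  # both sides of the loss live on the max = 100 scale
  y <- 100 * data$dose_percent / max(data$dose_percent)
  x <- data$depth_mm

  if (is.null(init)) {
    init <- if (!is.null(energy)) {
      base <- params_from_energy(energy)
      if (tail_form == "sigmoid") {
        primary_tail_params(base$N, n = min(max(6 * energy, 10), 450),
                            mu = base$mu, t = 0.02, tail_form = "sigmoid", p = 9)
      } else {
        base
      }
    } else {
      heuristic_init(data, tail_form, p = 9)
    }
  } else {
    init <- as_primary_tail_params(init)
    if (init$tail_form != tail_form) {
      init <- primary_tail_params(init$N, init$n, init$mu, init$t,
                                  tail_form = tail_form, p = init$p)
    }
  }

  bounds <- fit_bounds(tail_form)
  par0 <- c(N = init$N, n = init$n, mu = init$mu, t = init$t)
  if (tail_form == "sigmoid") par0 <- c(par0, p = init$p)
  par0 <- pmin(pmax(par0, bounds$lower), bounds$upper)

  residual_fn <- function(par) {
    m <- fit_model_values(par, x, tail_form)
    if (anyNA(m)) return(rep(1e6, length(y)))
    r <- m - y
    if (weighting == "relative") r <- r / y
    r
  }
  objective <- function(par) sum(residual_fn(par)^2)

  # deterministic multi-start: init, then x2 / /2 perturbations of N and n
  starts <- list(par0)
  for (fac in c(2, 0.5)) {
    s <- par0; s[["N"]] <- par0[["N"]] * fac
    starts <- c(starts, list(s))
    s <- par0; s[["n"]] <- par0[["n"]] * fac
    starts <- c(starts, list(s))
  }
  starts <- lapply(starts, function(s) pmin(pmax(s, bounds$lower), bounds$upper))

  best <- NULL
  best_obj <- Inf
  converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = s, lower = bounds$lower, upper = bounds$upper,
        fn = residual_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = min(max_iter, 1024), ftol = 1e-10, ptol = 1e-10))),
      error = function(e) NULL)
    if (is.null(res)) next
    obj <- sum(res$fvec^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- res
      converged <- res$info %in% 1:3
    }
  }

  # the returned parameters must never score worse than the initialization
  init_obj <- objective(par0)
  if (is.null(best) || best_obj > init_obj) {
    final_par <- par0
    converged <- FALSE
  } else {
    final_par <- unlist(best$par)
  }

  params <- primary_tail_params(
    N = final_par[["N"]], n = final_par[["n"]], mu = final_par[["mu"]],
    t = final_par[["t"]], tail_form = tail_form,
    p = if (tail_form == "sigmoid") final_par[["p"]] else 9)

  fitted <- fit_model_values(final_par, x, tail_form)
  deviation_pct <- pdd_deviation(fitted, data$dose_percent)
  structure(
    list(params = params,
         data = data,
         fitted = fitted,
         deviation_pct = deviation_pct,
         rms_deviation = sqrt(mean(deviation_pct^2)),
         sse = objective(final_par),
         converged = converged,
         n_points = nrow(data),
         weighting = weighting,
         init = init),
    class = "pdd_fit")
}

#' @export
print.pdd_fit <- function(x, ...) {
  cat(sprintf("<pdd_fit> %s tail, %d points, rms deviation %.2f%%%s\n",
              x$params$tail_form, x$n_points, x$rms_deviation,
              if (x$converged) "" else " (NOT converged)"))
  print(x$params)
  invisible(x)
}
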
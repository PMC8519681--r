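test_that("energy regressions predict parameters with the printed coefficients", {
  p12 <- params_from_energy(12)
  expect_equal(p12$n, 31.667 * 12 - 88, tolerance = 1e-12)  # 292.004
  expect_equal(p12$N, 0.9975 * 12 - 2.8535, tolerance = 1e-12)
  expect_equal(p12$mu, exp(-0.1355 * 12 - 6.0986), tolerance = 1e-12)
  expect_equal(p12$mu, 4.41e-4, tolerance = 1e-2)
  expect_identical(p12$t, 0)
  expect_error(suppressWarnings(params_from_energy(0)),
               class = "epdd_domain_error")
  expect_warning(params_from_energy(20), "outside")
  expect_no_warning(params_from_energy(20, warn = FALSE))
})

test_that("predicted n and N grow with energy while mu shrinks", {
  energies <- seq(6, 18, 3)
  pars <- lapply(energies, params_from_energy)
  expect_true(all(diff(vapply(pars, `[[`, 1, "n")) > 0))
  expect_true(all(diff(vapply(pars, `[[`, 1, "N")) > 0))
  expect_true(all(diff(vapply(pars, `[[`, 1, "mu")) < 0))
})

test_that("regression refit equals the closed-form OLS oracle", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(3:7, 1)
    tbl <- tibble::tibble(
      energy_mev = sort(runif(k, 4, 25)),
      n = runif(k, 50, 600),
      N = runif(k, 1, 20),
      mu = runif(k, 1e-4, 2e-3))
    reg <- refit_energy_regressions(tbl)
    on <- oracle_ols(tbl$energy_mev, tbl$n)
    oN <- oracle_ols(tbl$energy_mev, tbl$N)
    om <- oracle_ols(tbl$energy_mev, log(tbl$mu))
    expect_equal(reg$n_slope, unname(on["slope"]), tolerance = 1e-9)
    expect_equal(reg$n_intercept, unname(on["intercept"]), tolerance = 1e-9)
    expect_equal(reg$N_slope, unname(oN["slope"]), tolerance = 1e-9)
    expect_equal(reg$lnmu_slope, unname(om["slope"]), tolerance = 1e-9)
    expect_equal(reg$lnmu_intercept, unname(om["intercept"]), tolerance = 1e-9)
  }
})

test_that("refit rejects short and collinear tables", {
  tbl2 <- tibble::tibble(energy_mev = c(9, 9), n = c(210, 211),
                         N = c(6.2, 6.3), mu = c(7e-4, 7e-4))
  expect_error(refit_energy_regressions(tbl2), class = "epdd_input_error")
  tbl_flat <- tibble::tibble(energy_mev = rep(12, 3), n = c(1, 2, 3),
                             N = c(1, 2, 3), mu = rep(5e-4, 3))
  expect_error(refit_energy_regressions(tbl_flat),
               class = "epdd_singular_error")
})

test_that("stopping power matches hand arithmetic and its depth monotonicity flips at n = 762", {
  expect_equal(stopping_power(8.9, 290, 0), 1.072 - 0.042 * log(8.9),
               tolerance = 1e-12)
  expect_equal(stopping_power(8.9, 290, 0), 0.9802, tolerance = 1e-4)
  expect_equal(stopping_power(1, 762, 0), 1.072)
  expect_equal(stopping_power(8.9, 290, 5),
               (1.072 - 0.042 * log(8.9)) * exp((0.0381 - 290 * 5e-5) * 5),
               tolerance = 1e-12)
  expect_equal(stopping_power(8.9, 290, 5), 1.103, tolerance = 1e-3)
  depths <- seq(0, 10, 0.5)
  expect_true(all(diff(stopping_power(8.9, 761, depths)) > 0))
  expect_true(all(diff(stopping_power(8.9, 763, depths)) < 0))
  expect_error(stopping_power(0, 290, 1), class = "epdd_domain_error")
})

test_that("mm depth unit plugs millimetres straight into the exponent", {
  expect_equal(stopping_power(8.9, 290, 50, depth_unit = "mm"),
               (1.072 - 0.042 * log(8.9)) * exp((0.0381 - 290 * 5e-5) * 50),
               tolerance = 1e-12)
})

test_that("reading-dose conversion is a renormalized pointwise scaling with exact round trip", {
  # N = exp(0.072/0.042), n = 762 makes the stopping power identically 1
  p_unit <- list(N = exp(0.072 / 0.042), n = 762)
  scan <- pdd_model(1:60, primary_tail_params(8.9, 290, 5e-4, 0.01))
  out <- convert_reading_dose(scan, "reading_to_dose",
                              N = p_unit$N, n = p_unit$n)
  expect_equal(out$dose_percent, normalize_pdd(scan)$dose_percent,
               tolerance = 1e-9)

  # constant reading with exponential stopping power: max at deepest point
  const <- depth_dose_curve(seq(10, 60, 10), rep(100, 6))
  conv <- convert_reading_dose(const, "reading_to_dose", N = 8.9, n = 290)
  expect_equal(which.max(conv$dose_percent), 6L)
  sp <- stopping_power(8.9, 290, const$depth_mm / 10)
  expect_equal(conv$dose_percent, 100 * sp / max(sp), tolerance = 1e-12)

  set.seed(31)
  rand <- depth_dose_curve(sort(sample(1:100, 20)), runif(20, 1, 100))
  round_trip <- convert_reading_dose(
    convert_reading_dose(rand, "reading_to_dose", N = 6.2, n = 210),
    "dose_to_reading", N = 6.2, n = 210)
  expect_equal(round_trip$dose_percent, normalize_pdd(rand)$dose_percent,
               tolerance = 1e-9)
  expect_error(convert_reading_dose(rand, N = 6.2, n = 210),
               class = "epdd_input_error")
})

test_that("printed slope-attenuation relation evaluates but warns of its inconsistency", {
  expect_warning(v <- slope_mu_relation(5e-4),
                 class = "epdd_inconsistent_formula")
  expect_equal(v, -6.6729 * log(5e-4) - 16.623, tolerance = 1e-12)
  expect_equal(round(v, 2), 34.10)
  expect_warning(v2 <- slope_mu_relation(1e-3),
                 class = "epdd_inconsistent_formula")
  expect_equal(round(v2, 2), 29.47)
  expect_error(slope_mu_relation(0), class = "epdd_domain_error")
  refit <- refit_slope_mu(pdd_reference("table4"))
  expect_true(is.finite(refit$slope) && is.finite(refit$intercept))
})
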
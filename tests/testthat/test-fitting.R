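test_that("percent deviation reproduces printed comparison cells", {
  expect_equal(round(pdd_deviation(79.93, 83.34), 2), -4.09)
  expect_equal(round(pdd_deviation(40.86, 46.10), 2), -11.37)
  expect_equal(round(pdd_deviation(88.49, 88.27), 2), 0.25)
  for (v in c(0.3, 7, 99.56)) expect_equal(pdd_deviation(v, v), 0)
  expect_error(pdd_deviation(50, 0), class = "epdd_domain_error")
  expect_error(pdd_deviation(50, -3), class = "epdd_domain_error")
})

test_that("deviation satisfies the swap identity dev(a,b) = -dev(b,a) * a/b", {
  set.seed(77)
  a <- runif(25, 1, 120)
  b <- runif(25, 1, 120)
  expect_equal(pdd_deviation(a, b), -pdd_deviation(b, a) * (a / b),
               tolerance = 1e-12)
})

test_that("deviation table is zero when model equals measurement", {
  p <- primary_tail_params(8.9, 290, 5e-4, 0.02)
  grid <- seq(5, 70, 5)
  exact <- pdd_model(grid, p)
  tab <- deviation_table(exact, p)
  expect_equal(tab$deviation_pct, rep(0, length(grid)), tolerance = 1e-10)
  expect_named(tab, c("depth_mm", "measured", "modeled", "deviation_pct"))
  zero_curve <- tibble::tibble(depth_mm = grid,
                               dose_percent = c(0, exact$dose_percent[-1]))
  expect_error(deviation_table(zero_curve, p), class = "epdd_domain_error")
})

test_that("noiseless parameter recovery is exact to well under 1%", {
  truth <- primary_tail_params(8.9, 290, 5e-4, t = 0.02)
  scan <- pdd_model(1:80, truth)
  fit <- fit_pdd(scan, init = primary_tail_params(5, 150, 1e-3, 0))
  expect_true(fit$converged)
  got <- unlist(fit$params[c("N", "n", "mu", "t")])
  want <- unlist(truth[c("N", "n", "mu", "t")])
  expect_true(all(abs(got - want) / abs(want) < 0.01))
})

test_that("fits refuse curves with fewer than 4 usable points", {
  tiny <- depth_dose_curve(c(5, 10, 15), c(80, 95, 100))
  expect_error(fit_pdd(tiny), class = "epdd_input_error")
  # 4 points but one at the surface, excluded by default
  four <- depth_dose_curve(c(0, 5, 10, 15), c(80, 90, 95, 100))
  expect_error(fit_pdd(four), class = "epdd_input_error")
  expect_no_error(fit_pdd(four, include_surface = TRUE, max_iter = 50))
})

test_that("returned parameters never score worse than the initialization", {
  set.seed(88)
  for (i in 1:5) {
    truth <- primary_tail_params(runif(1, 3, 15), runif(1, 100, 450),
                                 runif(1, 2e-4, 1.5e-3), runif(1, 0, 0.04))
    scan <- synth_scan(truth, stop = 80, step = 1, noise_sd = 0.5,
                       seed = 500 + i)
    init <- primary_tail_params(5, 150, 1e-3, 0)
    fit <- fit_pdd(scan, init = init)
    data <- scan[scan$depth_mm > 0 & scan$dose_percent > 0, ]
    y <- 100 * data$dose_percent / max(data$dose_percent)
    sse_of <- function(p) {
      m <- pdd_model(data$depth_mm, p)$dose_percent
      sum((m - y)^2)
    }
    expect_lte(fit$sse, sse_of(init) + 1e-8)
    expect_equal(fit$sse, sse_of(fit$params), tolerance = 1e-8)
  }
})

test_that("generate-fit chain reproduces the underlying curve within noise", {
  truth <- primary_tail_params(8.9, 290, 5e-4, 0.02)
  scan <- synth_scan(truth, stop = 80, step = 1, noise_sd = 0.5, seed = 42)
  fit <- fit_pdd(scan, init = primary_tail_params(5, 150, 1e-3, 0))
  expect_true(fit$converged)
  expect_lt(fit$rms_deviation, 1.5)
  inner <- scan$depth_mm[scan$depth_mm > 0]
  expect_lt(max(abs(predict(fit, inner)$dose_percent -
                    pdd_model(inner, truth)$dose_percent)), 2)
})

test_that("sigmoid-tail fits track a measured-style falloff", {
  truth <- primary_tail_params(8.9, 48, 5e-4, 0.02, tail_form = "sigmoid",
                               p = 9)
  scan <- sigmoid_scan_12mev(step = 1, stop = 100, noise_sd = 0.5, seed = 9)
  fit <- fit_pdd(scan, weighting = "relative", tail_form = "sigmoid")
  expect_true(fit$converged)
  # relative deviations in the ~2%-dose tail are noise-dominated, so fit
  # quality is judged on the >= 10% portion and at curve level
  hi <- scan$dose_percent >= 10
  expect_lt(sqrt(mean(fit$deviation_pct[hi]^2)), 3)
  expect_lt(max(abs(predict(fit, scan$depth_mm)$dose_percent -
                    pdd_model(scan$depth_mm, truth)$dose_percent)), 3)
  # the falloff position is sharply identified
  expect_lt(abs(fit$params$n - truth$n) / truth$n, 0.05)
  expect_setequal(tidy(fit)$term, c("N", "n", "mu", "t", "p"))
})

test_that("tidiers expose parameters, summary and per-point table", {
  scan <- pdd_model(1:60, primary_tail_params(6.2, 210, 7e-4))
  fit <- fit_pdd(scan, energy = 9)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  gl <- glance(fit)
  expect_true(all(c("rms_deviation", "sse", "converged", "n_points") %in%
                    names(gl)))
  expect_identical(gl$n_points, nrow(augment(fit)))
  expect_named(augment(fit),
               c("depth_mm", "dose_percent", ".fitted", ".deviation_pct"))
})
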
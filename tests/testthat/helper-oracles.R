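# Independent oracles kept deliberately separate from the package
# implementation: plain arithmetic assembled term by term.

oracle_primary <- function(x, N, mu) {
  if (x == 0) return(0)
  num <- x^0.1
  den <- N + x^0.2
  att <- exp(-mu * x)
  (num / den) * att
}

oracle_tail_printed <- function(x, n, t) {
  1 - x / (n^0.5 + x^2) + t
}

oracle_model_printed <- function(x, N, n, mu, t) {
  oracle_primary(x, N, mu) * oracle_tail_printed(x, n, t)
}

# Closed-form distal crossing for a piecewise-linear curve: walk the
# segments after the maximum and solve the line equation directly.
oracle_pl_crossing <- function(depths, values, level_pct) {
  target <- level_pct / 100 * max(values)
  im <- which.max(values)
  for (i in seq(im, length(depths) - 1)) {
    y1 <- values[i]; y2 <- values[i + 1]
    if (y1 >= target && y2 < target) {
      x1 <- depths[i]; x2 <- depths[i + 1]
      return(x1 + (target - y1) * (x2 - x1) / (y2 - y1))
    }
  }
  NA_real_
}

# Two-parameter OLS in closed form.
oracle_ols <- function(x, y) {
  sx <- mean(x); sy <- mean(y)
  b <- sum((x - sx) * (y - sy)) / sum((x - sx)^2)
  c(intercept = sy - b * sx, slope = b)
}

# A strictly unimodal synthetic scan with a realistic distal falloff
# (sigmoid tail), used wherever a test needs a full-featured curve.
sigmoid_scan_12mev <- function(step = 0.5, stop = 120, noise_sd = 0,
                               seed = NULL) {
  synth_scan(
    primary_tail_params(8.9, 48, 5e-4, 0.02, tail_form = "sigmoid", p = 9),
    start = step, stop = stop, step = step,
    noise_sd = noise_sd, xray_floor = 0, seed = seed)
}
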
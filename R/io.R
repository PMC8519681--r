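#' Read a depth-dose curve from CSV
#'
#' Expects a header `depth_mm,dose_percent`; the delimiter (comma or
#' tab) is auto-detected and lines starting with `#` are skipped.
#' Depths are sorted ascending; duplicate depths, missing columns and
#' non-numeric cells are parse errors naming the offending row.
#'
#' @param path Path to a CSV/TSV file.
#' @param label Optional label; defaults to the file name.
#' @return A [depth_dose_curve()] tibble.
#' @export
read_curve <- function(path, label = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "epdd_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  rows <- which(keep)  # original line numbers, for diagnostics
  if (length(lines) < 2) {
    abort(sprintf("%s: need a header line and at least one data row.", path),
          class = "epdd_parse_error")
  }
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- tryCatch(
    read.csv(text = paste(lines, collapse = "\n"), sep = sep,
             colClasses = "character", check.names = FALSE,
             strip.white = TRUE),
    error = function(e) abort(sprintf("%s: %s", path, conditionMessage(e)),
                              class = "epdd_parse_error"))
  missing_cols <- setdiff(c("depth_mm", "dose_percent"), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(missing_cols, collapse = ", ")),
          class = "epdd_parse_error")
  }
  d <- suppressWarnings(as.numeric(df$depth_mm))
  v <- suppressWarnings(as.numeric(df$dose_percent))
  bad <- which(is.na(d) | is.na(v))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric cell in data row %d (file line %d).",
                  path, bad[1], rows[bad[1] + 1L]),
          class = "epdd_parse_error")
  }
  dup <- which(duplicated(d))
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate depth %g mm (data row %d).",
                  path, d[dup[1]], dup[1]),
          class = "epdd_parse_error")
  }
  o <- order(d)
  depth_dose_curve(d[o], v[o], label = label %||% basename(path))
}

# Decimal-true round-half-even at 2 decimals: ties in the *decimal*
# representation (e.g. 83.335) go to the even cent even when the binary
# double sits fractionally below the half.
round2_half_even <- function(x) {
  z <- round(x, 8) * 100
  f <- z - floor(z)
  tie <- abs(f - 0.5) < 1e-6
  r <- ifelse(tie,
              floor(z) + floor(z) %% 2,  # up to even when floor is odd
              round(z))
  r / 100
}

format_dose <- function(x) sprintf("%.2f", round2_half_even(x))

#' Write a depth-dose curve to CSV
#'
#' Writes `depth_mm,dose_percent` with doses formatted to 2 decimals
#' (decimal round-half-even). `read_curve(write_curve(c))` is the
#' identity for curves whose doses carry at most 2 decimals.
#'
#' @param curve A depth-dose curve.
#' @param path Output path.
#' @param comments Optional character vector written as leading
#'   `# `-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, comments = NULL) {
  validate_curve(curve, call_name = "write_curve")
  if (nrow(curve) == 0) {
    abort("Refusing to write an empty curve.", class = "epdd_input_error")
  }
  lines <- c(
    if (length(comments) > 0) paste0("# ", comments),
    "depth_mm,dose_percent",
    paste(format(curve$depth_mm, trim = TRUE, digits = 15),
          format_dose(curve$dose_percent), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic water-phantom scan
#'
#' Emulates a measured PDD scan: the normalized primary-tail model on
#' a regular depth grid, floored at a flat bremsstrahlung level beyond
#' the depth where the model first drops below it, with additive
#' Gaussian noise. Deterministic for a fixed seed. Defaults mirror
#' routine water-phantom practice: a 1 mm grid to 80 mm and 0.5%
#' scanning noise.
#'
#' @param params A [primary_tail_params()] object.
#' @param start,stop,step Depth grid in mm (`step > 0`).
#' @param noise_sd Gaussian noise standard deviation in percent dose
#'   (`>= 0`).
#' @param xray_floor Flat bremsstrahlung plateau level in percent
#'   (0 disables flooring).
#' @param seed Optional integer seed; recorded as the `"seed"`
#'   attribute and in the CSV header comment when written by the CLI.
#' @return A [depth_dose_curve()] tibble (values clamped at 0).
#' @examples
#' synth_scan(primary_tail_params(8.9, 48, 5e-4, 0.02, tail_form = "sigmoid"),
#'            stop = 100, noise_sd = 0.5, xray_floor = 2, seed = 42)
#' @export
synth_scan <- function(params, start = 0, stop = 80, step = 1,
                       noise_sd = 0.5, xray_floor = 0, seed = NULL) {
  params <- as_primary_tail_params(params)
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    abort("`step` must be > 0.", class = "epdd_input_error")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "epdd_input_error")
  if (stop <= start) {
    abort("Degenerate grid: `stop` must exceed `start`.",
          class = "epdd_input_error")
  }
  grid <- seq(start, stop, by = step)
  if (length(grid) < 2) {
    abort("Degenerate grid: fewer than 2 points.", class = "epdd_input_error")
  }
  curve <- pdd_model(grid, params, normalize = TRUE)
  v <- curve$dose_percent
  if (xray_floor > 0) {
    im <- which.max(v)
    below <- which(seq_along(v) > im & v < xray_floor)
    if (length(below) > 0) v[min(below):length(v)] <- xray_floor
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      rnorm(length(v), 0, noise_sd)
    } else {
      withr::with_seed(as.integer(seed), rnorm(length(v), 0, noise_sd))
    }
    v <- v + noise
  }
  out <- depth_dose_curve(grid, pmax(v, 0),
                          label = sprintf("synthetic (%s tail)", params$tail_form))
  attr(out, "seed") <- seed
  out
}
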
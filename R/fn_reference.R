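# Calibration of the flicker-noise reference entropy curve Sbar_fn(alpha):
# the permutation entropy of flicker noise as a function of its spectral
# exponent, against which every analyzed series is compared.

#' Calibrate the flicker-noise reference entropy curve
#'
#' For each alpha on the grid, generates `realizations` seeded flicker series
#' of `series_length` samples and records the mean and standard deviation of
#' their normalized permutation entropy.  The curve peaks at alpha = 0
#' (white noise, Sbar = 1) and decreases as |alpha| grows.
#'
#' Normalized PE carries a finite-size bias (with `w` windows at most
#' `log(w)/log(D!)` is reachable), so the curve must be calibrated at a
#' length comparable to the series it will be compared against; this is why
#' `series_length` is a first-class parameter rather than a constant.
#'
#' @param alpha_min,alpha_max grid ends, within \[-1, 3\] (the regime the
#'   regressor is trained on).
#' @param step grid spacing (<= 0.1).
#' @param realizations flicker realizations per grid point (>= 20).
#' @param series_length samples per realization.
#' @param seed master seed.
#' @param D,lag ordinal configuration.
#' @return An `fn_curve`: list with `alpha_grid`, `sbar_mean`, `sbar_sd`,
#'   `realizations`, `series_length`, `D`, `lag`.
#' @export
calibrate_fn_curve <- function(alpha_min = -1, alpha_max = 3, step = 0.05,
                               realizations = 100L, series_length = 2^17,
                               seed = 1L, D = 6L, lag = 1L) {
  if (alpha_min < -1 || alpha_max > 3 || alpha_min >= alpha_max)
    stop("the curve is calibrated on [-1, 3] only; got [",
         alpha_min, ", ", alpha_max, "]")
  if (step > 0.1) stop("grid step must be <= 0.1")
  realizations <- check_count(realizations, "realizations", min = 20L)
  series_length <- check_count(series_length, "series_length", min = 8L)
  grid <- seq(alpha_min, alpha_max, by = step)
  seeds <- child_seeds(seed, length(grid))
  sbar_mean <- sbar_sd <- numeric(length(grid))
  for (i in seq_along(grid)) {
    rs <- child_seeds(seeds[[i]], realizations)
    s <- vapply(rs, function(si)
      normalized_pe(generate_flicker(grid[i], series_length, seed = si),
                    D = D, lag = lag), 0)
    sbar_mean[i] <- mean(s)
    sbar_sd[i] <- sd(s)
  }
  structure(list(alpha_grid = grid, sbar_mean = sbar_mean, sbar_sd = sbar_sd,
                 realizations = realizations, series_length = series_length,
                 D = D, lag = lag, seed = seed),
            class = "fn_curve")
}

#' @export
print.fn_curve <- function(x, ...) {
  cat(sprintf(
    "<fn_curve> alpha in [%g, %g], %d points, %d x %d samples per point\n",
    min(x$alpha_grid), max(x$alpha_grid), length(x$alpha_grid),
    x$realizations, x$series_length))
  cat(sprintf("  Sbar_fn: %.4f at alpha=%g .. peak %.4f .. %.4f at alpha=%g\n",
              x$sbar_mean[1], x$alpha_grid[1], max(x$sbar_mean),
              x$sbar_mean[length(x$sbar_mean)],
              x$alpha_grid[length(x$alpha_grid)]))
  invisible(x)
}

#' Reference entropy at an estimated exponent
#'
#' Linear interpolation of the calibrated curve at `alpha_e`; exact at grid
#' points.  Values outside the calibrated range are clamped to the grid ends
#' (the regressor is only trusted on its training range).
#'
#' @param curve an `fn_curve`.
#' @param alpha_e estimated exponent (vectorized).
#' @return `Sbar_fn(alpha_e)`.
#' @export
lookup_sbar <- function(curve, alpha_e) {
  stopifnot(inherits(curve, "fn_curve"))
  if (length(curve$alpha_grid) == 0L) stop("empty reference curve")
  a <- pmin(pmax(alpha_e, min(curve$alpha_grid)), max(curve$alpha_grid))
  approx(curve$alpha_grid, curve$sbar_mean, xout = a)$y
}

#' Write a calibration curve as CSV (plus a JSON settings sidecar)
#'
#' Columns `alpha`, `sbar_mean`, `sbar_sd`; calibration settings go into
#' '#'-prefixed header lines and, when `sidecar = TRUE`, a `<path>.json`
#' sidecar.
#'
#' @param curve an `fn_curve`.
#' @param path output CSV path.
#' @param sidecar also write `<path>.json` with the settings.
#' @return `path`, invisibly.
#' @export
write_fn_curve <- function(curve, path, sidecar = FALSE) {
  stopifnot(inherits(curve, "fn_curve"))
  meta <- sprintf(
    "# chaostoch fn_curve v1: realizations=%d series_length=%d D=%d lag=%d seed=%s",
    curve$realizations, curve$series_length, curve$D, curve$lag,
    format(curve$seed))
  con <- file(path, "w")
  writeLines(meta, con)
  writeLines("alpha,sbar_mean,sbar_sd", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", curve$alpha_grid, curve$sbar_mean,
                     curve$sbar_sd), con)
  close(con)
  if (sidecar)
    writeLines(jsonlite::toJSON(
      curve[c("realizations", "series_length", "D", "lag", "seed")],
      auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' Read a curve written by [write_fn_curve()]
#'
#' @param path CSV path.
#' @return An `fn_curve`.
#' @export
read_fn_curve <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# chaostoch fn_curve", header))
    stop("not a chaostoch fn_curve file: ", path)
  kv <- regmatches(header, gregexpr("[a-z_]+=[-0-9.e]+", header))[[1]]
  meta <- as.list(as.numeric(sub("^[a-z_]+=", "", kv)))
  names(meta) <- sub("=.*$", "", kv)
  df <- read.table(path, sep = ",", header = TRUE, comment.char = "#")
  structure(list(alpha_grid = df$alpha, sbar_mean = df$sbar_mean,
                 sbar_sd = df$sbar_sd,
                 realizations = as.integer(meta$realizations),
                 series_length = as.integer(meta$series_length),
                 D = as.integer(meta$D), lag = as.integer(meta$lag),
                 seed = meta$seed),
            class = "fn_curve")
}
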
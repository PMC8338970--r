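#' Simulated time-series container
#'
#' Generators in this package return a `chs_series`: the sample values plus
#' the provenance needed to regenerate the series exactly (generator id,
#' parameter record, seed).  Most analysis functions accept either a
#' `chs_series` or a bare numeric vector.
#'
#' @param values numeric vector of samples (length >= 2, all finite).
#' @param generator character id of the generating process.
#' @param params named list of generator parameters.
#' @param seed the seed used, or `NULL`.
#' @return An object of class `chs_series` with fields `values`, `n`, `meta`.
#' @export
new_series <- function(values, generator = "user", params = list(),
                       seed = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a time series needs at least 2 samples")
  if (!all(is.finite(values))) stop("all series values must be finite")
  structure(
    list(values = values, n = length(values),
         meta = list(generator = generator, params = params, seed = seed)),
    class = "chs_series")
}

#' Extract the sample values of a series
#'
#' @param x a `chs_series` or numeric vector.
#' @return Numeric vector of samples.
#' @export
series_values <- function(x) {
  if (inherits(x, "chs_series")) return(x$values)
  if (is.numeric(x)) return(as.numeric(x))
  stop("`x` must be a chs_series or a numeric vector")
}

#' @export
as.double.chs_series <- function(x, ...) x$values

#' @export
length.chs_series <- function(x) x$n

#' @export
print.chs_series <- function(x, ...) {
  p <- x$meta$params
  ptxt <- if (length(p))
    paste(names(p), vapply(p, format, ""), sep = "=", collapse = ", ")
  else ""
  cat(sprintf("<chs_series> %s(%s)  n = %d  seed = %s\n",
              x$meta$generator, ptxt, x$n,
              if (is.null(x$meta$seed)) "none" else format(x$meta$seed)))
  cat("  head:", paste(signif(head(x$values, 5), 5), collapse = " "), "...\n")
  invisible(x)
}

#' Read a single-column series from a plain-text file
#'
#' One ASCII decimal per line, no header; the format written by
#' [write_series()] and by the `simulate` CLI subcommand.
#'
#' @param path file path.
#' @return A `chs_series` with generator id `"file"`.
#' @export
read_series <- function(path) {
  v <- scan(path, what = double(), quiet = TRUE, comment.char = "#")
  new_series(v, generator = "file", params = list(path = path))
}

#' Write a series as single-column plain text
#'
#' @param x series or numeric vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  v <- series_values(x)
  writeLines(sprintf("%.17g", v), path)
  invisible(path)
}
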
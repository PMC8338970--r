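# Bandt-Pompe ordinal-pattern encoding and permutation entropy: the feature
# extractor feeding both the alpha regressor and the Omega statistic.

#' Ordinal rank-string of a window
#'
#' Each value of the window is replaced by its relative amplitude, ordered
#' from 0 to D-1: `c(0, 5, 10, 13)` becomes `"0123"` and `c(0, 13, 5, 10)`
#' becomes `"0312"`.  Ties are broken by temporal order (the earlier sample
#' ranks lower).
#'
#' @param window numeric vector of D finite values (2 <= D <= 8).
#' @return Character rank-string of length D.
#' @export
ordinal_pattern <- function(window) {
  D <- length(window)
  if (D < 2L || D > 8L) stop("window length must be in [2, 8]")
  if (!all(is.finite(window))) stop("all window values must be finite")
  ranks <- rank(window, ties.method = "first") - 1L
  paste(ranks, collapse = "")
}

#' Encode a window as a pattern index
#'
#' Returns the lexicographic rank (Lehmer code) of the window's rank-string
#' among all D! permutations, an integer in `[0, D!)`.  This fixed indexing
#' is the feature-position contract shared by training and inference: the
#' all-ascending window maps to 0 and the all-descending window to D!-1.
#'
#' @inheritParams ordinal_pattern
#' @return Integer pattern index in `[0, factorial(D))`.
#' @export
encode_pattern <- function(window) {
  D <- length(window)
  if (D < 2L || D > 8L) stop("window length must be in [2, 8]")
  ordinal_codes_cpp(as.numeric(window), D, 1L)[1]
}

#' Ordinal-pattern probability distribution of a series
#'
#' Counts every overlapping window of D samples spaced `lag` apart (window
#' step 1, so D-1 values overlap between consecutive windows) and normalizes
#' by the window count `n - (D-1)*lag`.
#'
#' @param x series or numeric vector with at least `(D-1)*lag + 1` samples.
#' @param D pattern length (default 6, giving D! = 720 probabilities).
#' @param lag spacing between the D samples of a window (default 1).
#' @return An `ordinal_distribution`: list with `probs` (length D!),
#'   `counts`, `n_windows`, `D`, `lag`.
#' @export
pattern_distribution <- function(x, D = 6L, lag = 1L) {
  v <- series_values(x)
  D <- check_count(D, "D", min = 2L)
  if (D > 8L) stop("D must be in [2, 8]")
  lag <- check_count(lag, "lag", min = 1L)
  codes <- ordinal_codes_cpp(v, D, lag)
  counts <- tabulate(codes + 1L, nbins = factorial(D))
  structure(
    list(probs = counts / length(codes), counts = counts,
         n_windows = length(codes), D = D, lag = lag),
    class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf(
    "<ordinal_distribution> D = %d, lag = %d, %d windows, %d/%d patterns seen\n",
    x$D, x$lag, x$n_windows, sum(x$counts > 0L), length(x$probs)))
  invisible(x)
}

as_distribution <- function(x, D, lag) {
  if (inherits(x, "ordinal_distribution")) x
  else pattern_distribution(x, D = D, lag = lag)
}

#' Permutation entropy (nats)
#'
#' Shannon entropy `S = -sum_i P(i) log P(i)` of the ordinal-pattern
#' probabilities, with `0 * log 0 = 0`.  S ranges from 0 (a single pattern)
#' to `log(D!)` (all patterns equally likely).
#'
#' @param x an `ordinal_distribution`, or a series from which one is built.
#' @inheritParams pattern_distribution
#' @return Entropy in nats.
#' @export
permutation_entropy <- function(x, D = 6L, lag = 1L) {
  d <- as_distribution(x, D, lag)
  p <- d$probs[d$probs > 0]
  -sum(p * log(p))
}

#' Normalized permutation entropy
#'
#' `Sbar = S / log(D!)`, in \[0, 1\]: 1 for white noise (uniform pattern
#' distribution), 0 for a fully predictable ordering.
#'
#' @inheritParams permutation_entropy
#' @return Normalized entropy in \[0, 1\].
#' @export
normalized_pe <- function(x, D = 6L, lag = 1L) {
  d <- as_distribution(x, D, lag)
  permutation_entropy(d) / log(factorial(d$D))
}

#' Write an ordinal distribution as CSV
#'
#' Two columns, `pattern_index` (0-based) and `probability`.
#'
#' @param d an `ordinal_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(d, path) {
  stopifnot(inherits(d, "ordinal_distribution"))
  df <- data.frame(pattern_index = seq_along(d$probs) - 1L,
                   probability = d$probs)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
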
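# Naive ordinal oracle, independent of the package's optimized counter:
# argsort each window, read off the rank-string, and look it up in an
# explicitly enumerated lexicographic permutation table.

lex_perms <- function(D) {
  if (D == 1L) return(matrix(0L, 1L, 1L))
  sub <- lex_perms(D - 1L)
  do.call(rbind, lapply(0:(D - 1L), function(first) {
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    cbind(first, rest, deparse.level = 0)
  }))
}

oracle_code <- function(window) {
  D <- length(window)
  ranks <- integer(D)
  ranks[order(window)] <- 0:(D - 1L)      # stable sort: earlier ranks lower
  keys <- apply(lex_perms(D), 1L, paste, collapse = ",")
  match(paste(ranks, collapse = ","), keys) - 1L
}

oracle_codes <- function(v, D, lag = 1L) {
  keys <- apply(lex_perms(D), 1L, paste, collapse = ",")
  m <- length(v) - (D - 1L) * lag
  vapply(seq_len(m), function(t) {
    w <- v[t + (0:(D - 1L)) * lag]
    ranks <- integer(D)
    ranks[order(w)] <- 0:(D - 1L)
    match(paste(ranks, collapse = ","), keys) - 1L
  }, 0L)
}

oracle_probs <- function(v, D, lag = 1L) {
  codes <- oracle_codes(v, D, lag)
  tabulate(codes + 1L, nbins = factorial(D)) / length(codes)
}
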
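# Ordinal encoding and permutation entropy: worked examples, the naive
# argsort oracle, and the invariances the symbolic method guarantees.

test_that("windows encode to the documented rank-strings and indices", {
  expect_identical(ordinal_pattern(c(0, 5, 10, 13)), "0123")
  expect_identical(ordinal_pattern(c(0, 13, 5, 10)), "0312")
  expect_identical(encode_pattern(c(0, 5, 10, 13)), 0L)
  expect_identical(encode_pattern(c(0, 13, 5, 10)),
                   oracle_code(c(0, 13, 5, 10)))
  # any strictly decreasing window is the last pattern lexicographically
  for (D in 3:6)
    expect_identical(encode_pattern(seq(D, 1)), as.integer(factorial(D)) - 1L)
  expect_error(encode_pattern(c(1, NA, 2)), "finite")
})

test_that("ties rank the earlier sample lower", {
  expect_identical(ordinal_pattern(c(2, 2, 1)), "120")
  expect_identical(encode_pattern(c(2, 2, 1)), oracle_code(c(2, 2, 1)))
  expect_identical(encode_pattern(c(1, 1, 1, 1)), oracle_code(rep(1, 4)))
})

test_that("optimized encoder agrees with the argsort oracle everywhere", {
  set.seed(42)
  for (case in seq_len(1000)) {
    D <- sample(3:6, 1)
    n <- sample(20:60, 1)
    v <- switch(sample(3, 1),
                rnorm(n),
                sample(5, n, replace = TRUE),   # heavy ties
                cumsum(rnorm(n)))
    codes <- chaostoch:::ordinal_codes_cpp(v, D, 1L)
    expect_identical(codes, oracle_codes(v, D))
  }
})

test_that("pattern distributions count every overlapping window", {
  # monotone series concentrates all mass on one pattern
  d <- pattern_distribution(1:50, D = 4)
  expect_identical(sum(d$probs > 0), 1L)
  expect_equal(d$probs[1], 1)
  expect_identical(d$n_windows, 47L)
  # worked small example against the oracle
  x <- c(4, 7, 9, 10, 6, 11, 3)
  d <- pattern_distribution(x, D = 3)
  expect_identical(d$n_windows, 5L)
  expect_equal(d$probs, oracle_probs(x, 3))
  # D = 6 gives the 720-dimensional feature vector
  d6 <- pattern_distribution(rnorm(5000), D = 6)
  expect_length(d6$probs, 720L)
  expect_equal(sum(d6$probs), 1, tolerance = 1e-12)
  expect_identical(sum(d6$counts), d6$n_windows)
  expect_error(pattern_distribution(1:5, D = 6), "at least")
})

test_that("permutation entropy spans [0, log D!] with the right extremes", {
  d <- pattern_distribution(1:100, D = 5)
  expect_equal(permutation_entropy(d), 0)
  expect_equal(normalized_pe(d), 0)
  # uniform distribution attains the maximum
  u <- structure(list(probs = rep(1 / 720, 720), counts = rep(1L, 720),
                      n_windows = 720L, D = 6L, lag = 1L),
                 class = "ordinal_distribution")
  expect_equal(permutation_entropy(u), log(720))
  expect_equal(normalized_pe(u), 1)
  # two equiprobable patterns give ln 2
  b <- structure(list(probs = c(0.5, 0.5, 0, 0, 0, 0),
                      counts = c(5L, 5L, 0L, 0L, 0L, 0L),
                      n_windows = 10L, D = 3L, lag = 1L),
                 class = "ordinal_distribution")
  expect_equal(permutation_entropy(b), log(2))
  # long white noise saturates the normalized entropy
  expect_gte(normalized_pe(generate_iid("gaussian", 2^18, seed = 1)), 0.999)
})

test_that("the distribution is invariant under strictly increasing maps", {
  set.seed(7)
  v <- rnorm(400)
  base <- pattern_distribution(v, D = 5)$probs
  expect_identical(pattern_distribution(exp(v), D = 5)$probs, base)
  expect_identical(pattern_distribution(v^3, D = 5)$probs, base)
  expect_identical(pattern_distribution(2.5 * v + 10, D = 5)$probs, base)
})

test_that("lagged windows shorten the window count accordingly", {
  v <- rnorm(100)
  d <- pattern_distribution(v, D = 4, lag = 3)
  expect_identical(d$n_windows, 100L - 9L)
  expect_equal(d$probs, oracle_probs(v, 4, lag = 3))
})

test_that("distributions serialize to the two-column CSV contract", {
  d <- pattern_distribution(rnorm(50), D = 3)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_distribution(d, f)
  back <- read.csv(f)
  expect_identical(names(back), c("pattern_index", "probability"))
  expect_equal(back$probability, d$probs)
})
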
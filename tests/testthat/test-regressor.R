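# Corpus construction, the feed-forward regressor, Eq.-5 error accounting
# and lossless serialization.  Heavier end-to-end accuracy checks live in
# test-acceptance.R; units here use tiny corpora.

tiny_cfg <- function(series_length = 2^12, ...) {
  training_config(n_series = 40L, series_length = series_length,
                  epochs = 15L, seed = 33L, ...)
}

# A regressor with hand-set weights (constant predictor), bypassing training.
constant_model <- function(value, n_in = 720L, h = 64L) {
  structure(list(W1 = matrix(0, n_in, h), b1 = numeric(h),
                 W2 = matrix(0, h, 1L), b2 = value, feature_scale = 1,
                 D = 6L, lag = 1L, alpha_range = c(-1, 3),
                 n_params = n_in * h + h + h + 1L),
            class = "fn_regressor")
}

test_that("corpus rows are probability vectors, labeled and reproducible", {
  cfg <- tiny_cfg()
  c1 <- suppressWarnings(build_corpus(cfg))
  expect_identical(dim(c1$features), c(40L, 720L))
  expect_equal(rowSums(c1$features), rep(1, 40), tolerance = 1e-12)
  expect_true(all(c1$alphas >= -1 & c1$alphas <= 3))
  c2 <- suppressWarnings(build_corpus(cfg))
  expect_identical(c1$features, c2$features)
  expect_identical(c1$alphas, c2$alphas)
  expect_warning(build_corpus(tiny_cfg(series_length = 2^10)), "noisy")
})

test_that("white-noise features concentrate near the uniform distribution", {
  # binomial concentration: each of the 720 pattern probabilities of a long
  # white-noise series stays within a few standard errors of 1/720
  p <- pattern_distribution(generate_flicker(0, 2^16, seed = 9))$probs
  expect_lt(max(p), 2 / 720)
})

test_that("the reference architecture has exactly 46209 parameters", {
  cfg <- tiny_cfg()
  model <- suppressWarnings(train_regressor(build_corpus(cfg), cfg))
  expect_identical(n_params(model), 46209L)
  expect_identical(dim(model$W1), c(720L, 64L))
  expect_identical(as.integer(prod(dim(model$W1))) + length(model$b1),
                   46144L)
  expect_identical(as.integer(prod(dim(model$W2))) + length(model$b2), 65L)
})

test_that("training is seeded and aborts cleanly on divergence", {
  cfg <- tiny_cfg()
  corpus <- suppressWarnings(build_corpus(cfg))
  m1 <- train_regressor(corpus, cfg)
  m2 <- train_regressor(corpus, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_gte(m1$eval$mae, 0)
  expect_error(
    train_regressor(corpus, tiny_cfg(learning_rate = 1e160)),
    "non-finite")
})

test_that("evaluate_mae implements the mean absolute error exactly", {
  # predictions equal to labels give zero error
  feats <- matrix(1 / 720, 4, 720)
  mid <- constant_model(1)
  expect_equal(evaluate_mae(mid, feats, rep(1, 4))$mae, 0)
  # constant predictor at the midpoint of [-1,3] vs uniform labels -> 1
  set.seed(1)
  labs <- runif(20000, -1, 3)
  r <- evaluate_mae(mid, matrix(1 / 720, length(labs), 720), labs)
  expect_equal(r$mae, 1, tolerance = 0.02)
  expect_identical(r$n_eval, length(labs))
  expect_true(all(diff(r$per_alpha_error$alpha_bin) > 0))
})

test_that("prediction validates feature length and accepts all input forms", {
  m <- constant_model(0.5)
  x <- generate_flicker(0, 4096, seed = 2)
  d <- pattern_distribution(x)
  expect_equal(predict_alpha(m, x), 0.5)
  expect_equal(predict_alpha(m, d), 0.5)
  expect_equal(predict_alpha(m, d$probs), 0.5)
  expect_error(predict_alpha(m, pattern_distribution(x$values, D = 4)),
               "feature length")
})

test_that("save/load reproduces predictions bit-identically", {
  cfg <- tiny_cfg()
  model <- suppressWarnings(train_regressor(build_corpus(cfg), cfg))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  save_regressor(model, f)
  back <- load_regressor(f)
  expect_identical(back$W1, model$W1)
  expect_identical(back$W2, model$W2)
  probe <- pattern_distribution(generate_flicker(1.7, 4096, seed = 4))
  expect_identical(predict_alpha(back, probe), predict_alpha(model, probe))
  junk <- tempfile(fileext = ".json")
  on.exit(unlink(junk), add = TRUE)
  writeLines('{"format": "something-else"}', junk)
  expect_error(load_regressor(junk), "not a chaostoch regressor")
})
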
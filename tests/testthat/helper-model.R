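# Shared desk-scale model and reference curves, trained/calibrated once per
# test run (a few minutes) and reused by every downstream test.

the <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(the$model)) {
    cfg <- training_config(n_series = 2000L, series_length = 2^16,
                           seed = 101L)
    the$model <- train_regressor(build_corpus(cfg), cfg)
  }
  the$model
}

# Length-matched reference curves, cached per series length.
test_curve <- function(series_length = 2^16, realizations = 20L,
                       step = 0.05) {
  key <- paste0("curve_", series_length)
  if (is.null(the[[key]]))
    the[[key]] <- calibrate_fn_curve(step = step,
                                     realizations = realizations,
                                     series_length = series_length,
                                     seed = 202L)
  the[[key]]
}

# Ensemble mean alpha_e / Omega for one benchmark system.
ensemble_stats <- function(system, replicates, n, model, curve, seed) {
  alpha <- omega <- numeric(replicates)
  for (i in seq_len(replicates)) {
    r <- suppressWarnings(analyze_series(
      generate_system(system, n, seed + i), model, curve))
    alpha[i] <- r$alpha_e
    omega[i] <- r$omega
  }
  list(alpha = mean(alpha), omega = mean(omega))
}
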
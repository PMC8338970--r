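# Scripted, seeded reproductions of the synthetic validation experiments
# (system table, noise-contamination sweep, summed-map sweep, length
# robustness, MAE-vs-length) plus the deterministic fixture generator used by
# the regression tests.

stochastic_systems <- c("flicker0", "fbm05", "fgn05", "cauchy", "uniform")
chaotic_systems <- c("betax", "lorenz", "logistic", "schuster", "skewtent")

#' Generate one realization of a named benchmark system
#'
#' Dispatcher over the ten benchmark systems: `flicker0` (flicker noise,
#' alpha = 0), `fbm05` / `fgn05` (H = 0.5), `cauchy`, `uniform`, and the
#' chaotic `betax`, `logistic`, `schuster`, `skewtent`, `lorenz` (successive
#' x maxima).  Map and flow parameters are the benchmark defaults of
#' [iterate_map()] and [lorenz_maxima()].
#'
#' @param system system id (see above).
#' @param n series length (number of maxima for `lorenz`).
#' @param seed integer seed.
#' @return A [new_series()] object.
#' @export
generate_system <- function(system, n, seed = NULL) {
  switch(system,
    flicker0 = generate_flicker(0, n, seed),
    fbm05 = generate_fractional("fbm", 0.5, n, seed),
    fgn05 = generate_fractional("fgn", 0.5, n, seed),
    cauchy = generate_iid("cauchy", n, seed),
    uniform = generate_iid("uniform", n, seed),
    betax = ,
    logistic = ,
    schuster = ,
    skewtent = iterate_map(system, n, seed),
    lorenz = lorenz_maxima(n, seed),
    stop("unknown system: ", system))
}

experiment_header <- function(id, model, curve, settings) {
  c(sprintf("# chaostoch experiment: %s", id),
    sprintf("# settings: %s",
            paste(names(settings), vapply(settings, format, ""),
                  sep = "=", collapse = " ")),
    sprintf("# model: hash=%s heldout_mae=%s",
            if (is.null(model$config_hash)) "none" else model$config_hash,
            format(model$eval$mae)),
    sprintf("# curve: points=%d realizations=%d series_length=%d seed=%s",
            length(curve$alpha_grid), curve$realizations,
            curve$series_length, format(curve$seed)))
}

write_experiment_csv <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(unname(df), sep = ",")), con)
  close(con)
  invisible(path)
}

analyze_ensemble <- function(system, replicates, n, model, curve, seed) {
  seeds <- child_seeds(seed, replicates)
  alpha <- omega <- numeric(replicates)
  for (i in seq_len(replicates)) {
    res <- suppressWarnings(
      analyze_series(generate_system(system, n, seeds[[i]]), model, curve))
    alpha[i] <- res$alpha_e
    omega[i] <- res$omega
  }
  list(alpha = alpha, omega = omega)
}

#' Benchmark table: mean and sd of alpha_e and Omega per system
#'
#' Reproduces the ten-system summary (five stochastic, five chaotic) at a
#' configurable ensemble scale.  The reference study used 1000 replicates of
#' 2^20 samples; the desk-scale defaults (100 x 2^17, 20 x 2^15 maxima for
#' the Lorenz flow) give ensemble means well inside the quoted tolerances.
#'
#' @param model an `fn_regressor`.
#' @param curve an `fn_curve` calibrated at (roughly) `series_length`.
#' @param replicates ensemble size per system.
#' @param series_length samples per replicate.
#' @param lorenz_replicates,lorenz_n ensemble size and maxima count for the
#'   Lorenz system (its integration cost per sample is much higher).
#' @param include_schuster include the Schuster map row (its published
#'   parameterization is ambiguous between z = 0.5 and z = 1.5; the row uses
#'   the package default z = 1.5).
#' @param seed master seed.
#' @param out optional CSV output path ('#'-prefixed metadata header).
#' @return Data frame: system, kind, alpha_mean, alpha_sd, omega_mean,
#'   omega_sd, replicates, n.
#' @export
run_table1 <- function(model, curve, replicates = 100L,
                       series_length = 2^17, lorenz_replicates = 20L,
                       lorenz_n = 2^15, include_schuster = TRUE, seed = 1L,
                       out = NULL) {
  replicates <- check_count(replicates, "replicates", 1L)
  if (replicates == 1L)
    warning("replicates = 1: standard deviations are reported as 0")
  systems <- c(stochastic_systems,
               if (include_schuster) chaotic_systems
               else setdiff(chaotic_systems, "schuster"))
  seeds <- child_seeds(seed, length(systems))
  rows <- vector("list", length(systems))
  for (i in seq_along(systems)) {
    sys <- systems[i]
    reps <- if (sys == "lorenz") lorenz_replicates else replicates
    len <- if (sys == "lorenz") lorenz_n else series_length
    ens <- analyze_ensemble(sys, reps, len, model, curve, seeds[[i]])
    sd0 <- function(v) if (length(v) > 1L) sd(v) else 0
    rows[[i]] <- data.frame(
      system = sys,
      kind = if (sys %in% stochastic_systems) "stochastic" else "chaotic",
      alpha_mean = mean(ens$alpha), alpha_sd = sd0(ens$alpha),
      omega_mean = mean(ens$omega), omega_sd = sd0(ens$omega),
      replicates = reps, n = len)
  }
  df <- do.call(rbind, rows)
  if (!is.null(out))
    write_experiment_csv(df, out, experiment_header(
      "table1", model, curve,
      list(replicates = replicates, series_length = series_length,
           seed = seed)))
  df
}

#' Noise-contamination sweep: Omega vs eta
#'
#' Mixes a chaotic signal with uniform white noise,
#' `Z = (1-eta) X + eta Y` (both standardized), and tracks the median and
#' IQR of Omega across the eta grid, together with a shuffled-surrogate
#' control (same marginals, temporal order destroyed) which stays near 0
#' throughout.
#'
#' @param model,curve trained regressor and matching reference curve.
#' @param system chaotic system id providing `X`.
#' @param etas noise-fraction grid in \[0, 1\].
#' @param replicates ensemble size per grid point.
#' @param series_length samples per replicate.
#' @param seed master seed.
#' @param out optional CSV output path.
#' @return Data frame: eta, omega_median, omega_q25, omega_q75,
#'   omega_shuffled_median.
#' @export
run_eta_sweep <- function(model, curve, system = "logistic",
                          etas = seq(0, 1, by = 0.1), replicates = 50L,
                          series_length = 2^14, seed = 1L, out = NULL) {
  stopifnot(system %in% chaotic_systems)
  seeds <- child_seeds(seed, length(etas))
  rows <- vector("list", length(etas))
  for (j in seq_along(etas)) {
    rs <- child_seeds(seeds[[j]], 3L * replicates)
    om <- om_sh <- numeric(replicates)
    for (i in seq_len(replicates)) {
      x <- generate_system(system, series_length, rs[[3L * i - 2L]])
      y <- generate_iid("uniform", series_length, rs[[3L * i - 1L]])
      z <- mix_signals(x, y, etas[j])
      om[i] <- suppressWarnings(analyze_series(z, model, curve))$omega
      om_sh[i] <- suppressWarnings(analyze_series(
        shuffle_series(z, rs[[3L * i]]), model, curve))$omega
    }
    rows[[j]] <- data.frame(
      eta = etas[j], omega_median = median(om),
      omega_q25 = quantile(om, 0.25), omega_q75 = quantile(om, 0.75),
      omega_shuffled_median = median(om_sh))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(out))
    write_experiment_csv(df, out, experiment_header(
      "eta_sweep", model, curve,
      list(system = system, replicates = replicates,
           series_length = series_length, seed = seed)))
  df
}

#' Summed-map sweep: Omega vs the number of aggregated chaotic signals
#'
#' @param model,curve trained regressor and matching reference curve.
#' @param system chaotic map id.
#' @param ms grid of aggregation counts m.
#' @param replicates ensemble size per grid point.
#' @param series_length samples per replicate.
#' @param seed master seed.
#' @param out optional CSV output path.
#' @return Data frame: m, omega_median, omega_q25, omega_q75.
#' @export
run_m_sweep <- function(model, curve, system = "logistic",
                        ms = c(1L, 2L, 5L, 10L, 50L), replicates = 50L,
                        series_length = 2^14, seed = 1L, out = NULL) {
  stopifnot(system %in% setdiff(chaotic_systems, "lorenz"))
  seeds <- child_seeds(seed, length(ms))
  rows <- vector("list", length(ms))
  for (j in seq_along(ms)) {
    rs <- child_seeds(seeds[[j]], replicates)
    om <- vapply(rs, function(si) {
      z <- sum_of_maps(system, ms[j], series_length, seed = si)
      suppressWarnings(analyze_series(z, model, curve))$omega
    }, 0)
    rows[[j]] <- data.frame(m = ms[j], omega_median = median(om),
                            omega_q25 = quantile(om, 0.25),
                            omega_q75 = quantile(om, 0.75))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(out))
    write_experiment_csv(df, out, experiment_header(
      "m_sweep", model, curve,
      list(system = system, replicates = replicates,
           series_length = series_length, seed = seed)))
  df
}

#' Length-robustness sweep: Omega vs series length N
#'
#' For each length a reference curve is recalibrated at that length (the
#' normalized PE of finite series is length-biased, so a fixed-length curve
#' would misclassify short stochastic series), then every benchmark system
#' is analyzed at that length.
#'
#' @param model an `fn_regressor`.
#' @param lengths grid of series lengths.
#' @param replicates ensemble size per (system, length).
#' @param curve_realizations flicker realizations per curve grid point.
#' @param curve_step curve grid spacing.
#' @param systems system ids to include.
#' @param seed master seed.
#' @param out optional CSV output path.
#' @return Data frame: system, kind, n, omega_mean, omega_sd.
#' @export
run_length_sweep <- function(model,
                             lengths = c(64L, 128L, 256L, 512L, 1024L),
                             replicates = 100L, curve_realizations = 50L,
                             curve_step = 0.1,
                             systems = c(stochastic_systems,
                                         setdiff(chaotic_systems,
                                                 "schuster")),
                             seed = 1L, out = NULL) {
  seeds <- child_seeds(seed, length(lengths))
  rows <- list()
  last_curve <- NULL
  for (j in seq_along(lengths)) {
    n <- lengths[j]
    curve <- calibrate_fn_curve(step = curve_step,
                                realizations = curve_realizations,
                                series_length = n, seed = seeds[[j]],
                                D = model$D, lag = model$lag)
    last_curve <- curve
    sys_seeds <- child_seeds(seeds[[j]] + 1, length(systems))
    for (i in seq_along(systems)) {
      ens <- analyze_ensemble(systems[i], replicates, n, model, curve,
                              sys_seeds[[i]])
      rows[[length(rows) + 1L]] <- data.frame(
        system = systems[i],
        kind = if (systems[i] %in% stochastic_systems) "stochastic"
               else "chaotic",
        n = n, omega_mean = mean(ens$omega), omega_sd = sd(ens$omega))
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(out))
    write_experiment_csv(df, out, experiment_header(
      "length_sweep", model, last_curve,
      list(replicates = replicates, seed = seed)))
  df
}

#' Regressor error versus series length and exponent
#'
#' Mean absolute error of alpha_e over an (alpha, N) grid of freshly
#' generated flicker noise: the error shrinks as N grows and is largest at
#' the strongly non-stationary high-alpha end.
#'
#' @param model an `fn_regressor`.
#' @param lengths series-length grid.
#' @param alphas exponent grid.
#' @param L realizations per grid cell.
#' @param seed master seed.
#' @param out optional CSV output path.
#' @return Data frame: alpha, n, mae.
#' @export
run_mae_sweep <- function(model, lengths = 2^c(8L, 10L, 12L, 14L),
                          alphas = seq(-1, 3, by = 0.5), L = 50L,
                          seed = 1L, out = NULL) {
  seeds <- child_seeds(seed, length(lengths) * length(alphas))
  rows <- list()
  k <- 0L
  for (n in lengths) for (a in alphas) {
    k <- k + 1L
    rs <- child_seeds(seeds[[k]], L)
    err <- vapply(rs, function(si) {
      x <- generate_flicker(a, n, seed = si)
      abs(predict_alpha(model, x) - a)
    }, 0)
    rows[[k]] <- data.frame(alpha = a, n = n, mae = mean(err))
  }
  df <- do.call(rbind, rows)
  if (!is.null(out)) {
    hdr <- c("# chaostoch experiment: mae_sweep",
             sprintf("# settings: L=%d seed=%s model=%s", L, format(seed),
                     model$config_hash))
    write_experiment_csv(df, out, hdr)
  }
  df
}

# ---- fixtures ------------------------------------------------------------

# Lexicographic table of all permutations of 0:(D-1), one per row.
perm_table <- function(D) {
  if (D == 1L) return(matrix(0L, 1L, 1L))
  sub <- perm_table(D - 1L)
  out <- matrix(0L, factorial(D), D)
  r <- 0L
  for (first in 0:(D - 1L)) {
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    idx <- r + seq_len(nrow(sub))
    out[idx, 1L] <- first
    out[idx, -1L] <- rest
    r <- r + nrow(sub)
  }
  out
}

# Naive per-window oracle: rank each window with an explicit argsort and look
# the rank-string up in the lexicographic permutation table.  Deliberately
# independent of the optimized Lehmer-code counter.
naive_pattern_probs <- function(v, D, lag = 1L) {
  tbl <- perm_table(D)
  keys <- apply(tbl, 1L, paste, collapse = "")
  m <- length(v) - (D - 1L) * lag
  counts <- integer(factorial(D))
  for (t in seq_len(m)) {
    w <- v[t + (0:(D - 1L)) * lag]
    ranks <- integer(D)
    ranks[order(w)] <- 0:(D - 1L)   # stable: earlier sample ranks lower
    i <- match(paste(ranks, collapse = ""), keys)
    counts[i] <- counts[i] + 1L
  }
  counts / m
}

#' Write deterministic regression-test fixtures
#'
#' One series per benchmark system (single-column text) plus its expected
#' ordinal-pattern distribution computed by the naive argsort oracle
#' (CSV `pattern_index,probability`).  Regeneration with the same seed is
#' bit-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param n samples per fixture series.
#' @param D,lag ordinal configuration for the expected distributions.
#' @return Invisibly, the vector of files written.
#' @export
make_fixtures <- function(dir, seed = 1L, n = 4096L, D = 4L, lag = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  systems <- c(stochastic_systems, chaotic_systems)
  seeds <- child_seeds(seed, length(systems))
  files <- character(0)
  for (i in seq_along(systems)) {
    x <- generate_system(systems[i], n, seeds[[i]])
    f1 <- file.path(dir, paste0(systems[i], ".txt"))
    write_series(x, f1)
    probs <- naive_pattern_probs(x$values, D, lag)
    f2 <- file.path(dir, paste0(systems[i], "_dist_D", D, ".csv"))
    df <- data.frame(pattern_index = seq_along(probs) - 1L,
                     probability = sprintf("%.17g", probs))
    write_experiment_csv(df, f2,
                         sprintf("# chaostoch fixture: %s D=%d lag=%d seed=%s n=%d",
                                 systems[i], D, lag, format(seeds[[i]]), n))
    files <- c(files, f1, f2)
  }
  invisible(files)
}
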
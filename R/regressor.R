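# Flicker-noise training corpus and the 720 -> 64(relu) -> 1 feed-forward
# regressor for the temporal-correlation exponent alpha, trained with Adam on
# a mean-square-error loss.  The network is small enough that plain
# vectorized matrix algebra trains it in a couple of minutes on one core.

#' Training configuration for the alpha regressor
#'
#' The reference study trains on 50,000 flicker series of 2^20 samples with
#' alpha uniform on \[-1, 3\] and a 40,000/10,000 split; the desk-scale
#' defaults here (5,000 series of 2^16 samples) train in minutes and reach a
#' held-out mean absolute error of a few hundredths.
#'
#' @param n_series number of flicker series in the corpus.
#' @param series_length samples per series.
#' @param alpha_range closed interval for the uniform alpha labels, within
#'   \[-1, 3\].
#' @param train_fraction fraction of the corpus used for training, the rest
#'   is the held-out test split.
#' @param epochs maximum optimization epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param patience early-stopping patience (epochs without held-out MAE
#'   improvement); `Inf` disables early stopping.
#' @param hidden hidden-layer width (64 in the reference architecture).
#' @param D,lag ordinal configuration for the features (D = 6 gives the 720
#'   input probabilities).
#' @param seed master seed for labels, noise, split, initialization and
#'   minibatch shuffling.
#' @return A `training_config` list.
#' @export
training_config <- function(n_series = 5000L, series_length = 2^16,
                            alpha_range = c(-1, 3), train_fraction = 0.8,
                            epochs = 200L, batch_size = 32L,
                            learning_rate = 1e-3, patience = 30L,
                            hidden = 64L, D = 6L, lag = 1L, seed = 1L) {
  stopifnot(length(alpha_range) == 2L, alpha_range[1] < alpha_range[2])
  if (alpha_range[1] < -1 || alpha_range[2] > 3)
    stop("`alpha_range` must lie within [-1, 3] (the calibrated regime)")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  cfg <- list(n_series = check_count(n_series, "n_series", 2L),
              series_length = check_count(series_length, "series_length", 8L),
              alpha_range = as.numeric(alpha_range),
              train_fraction = train_fraction,
              epochs = check_count(epochs, "epochs", 1L),
              batch_size = check_count(batch_size, "batch_size", 1L),
              learning_rate = learning_rate,
              patience = if (is.finite(patience))
                check_count(patience, "patience", 1L) else Inf,
              hidden = check_count(hidden, "hidden", 1L),
              D = check_count(D, "D", 2L), lag = check_count(lag, "lag", 1L),
              seed = seed)
  class(cfg) <- "training_config"
  cfg
}

#' Build the labeled flicker-noise feature corpus
#'
#' Draws `n_series` exponents uniformly from `alpha_range`, generates one
#' flicker series per exponent, and stores its D! ordinal probabilities as
#' the feature row.  A warning is raised when `series_length` is not large
#' compared to D!, since the probabilities are then poorly estimated.
#'
#' @param cfg a [training_config()].
#' @param progress print a progress line every 1000 series.
#' @return List with `features` (n_series x D! matrix), `alphas`, `cfg`.
#' @export
build_corpus <- function(cfg = training_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "training_config"))
  nf <- factorial(cfg$D)
  if (cfg$series_length < 10 * nf)
    warning("series_length (", cfg$series_length,
            ") is not large compared to D! = ", nf,
            "; ordinal probabilities will be noisy")
  alphas <- with_seed(cfg$seed,
                      runif(cfg$n_series, cfg$alpha_range[1],
                            cfg$alpha_range[2]))
  seeds <- child_seeds(cfg$seed + 1, cfg$n_series)
  feats <- matrix(0, cfg$n_series, nf)
  for (i in seq_len(cfg$n_series)) {
    x <- generate_flicker(alphas[i], cfg$series_length, seed = seeds[[i]])
    feats[i, ] <- pattern_distribution(x, D = cfg$D, lag = cfg$lag)$probs
    if (progress && i %% 1000L == 0L)
      message("  corpus: ", i, "/", cfg$n_series)
  }
  list(features = feats, alphas = alphas, cfg = cfg)
}

glorot_init <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -limit, limit), n_in, n_out)
}

mlp_forward <- function(model, X) {
  H <- X %*% model$W1
  H <- sweep(H, 2L, model$b1, "+")
  H[H < 0] <- 0
  drop(H %*% model$W2) + model$b2
}

#' Train the alpha regressor
#'
#' Fits the feed-forward network D! -> hidden (relu) -> 1 (linear) by Adam
#' on the mean-square error, with early stopping on the held-out mean
#' absolute error (`mean(|alpha_e - alpha|)`); the weights of the best
#' held-out epoch are kept.  The inputs are the raw ordinal probabilities
#' (no standardization or rescaling): with O(1/D!) features every relu unit
#' starts near its switching point, which keeps training in a smooth,
#' nearly-lazy regime whose extrapolation to feature vectors far from the
#' flicker manifold (chaotic signals, very short series) is stable across
#' training runs.
#'
#' @param corpus output of [build_corpus()].
#' @param cfg a [training_config()]; defaults to the corpus' own.
#' @param verbose print the held-out MAE every 10 epochs.
#' @return An `fn_regressor` with weights, `n_params`, feature scale, the
#'   held-out [evaluate_mae()] report and the training configuration.
#' @export
train_regressor <- function(corpus, cfg = corpus$cfg, verbose = FALSE) {
  X <- corpus$features
  y <- corpus$alphas
  L <- nrow(X)
  n_in <- ncol(X)
  h <- cfg$hidden
  with_seed(cfg$seed + 2, {
    idx <- sample.int(L)
    n_train <- max(1L, floor(cfg$train_fraction * L))
    tr <- idx[seq_len(n_train)]
    te <- idx[-seq_len(n_train)]
    if (length(te) == 0L) stop("empty test split; reduce train_fraction")
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[te, , drop = FALSE]; yte <- y[te]

    model <- list(W1 = glorot_init(n_in, h), b1 = numeric(h),
                  W2 = glorot_init(h, 1L), b2 = 0,
                  feature_scale = 1, D = cfg$D, lag = cfg$lag,
                  alpha_range = cfg$alpha_range)
    m <- lapply(model[1:4], function(w) w * 0)  # Adam first moments
    v <- lapply(model[1:4], function(w) w * 0)  # Adam second moments
    b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
    step <- 0L
    best <- list(mae = Inf, model = model, epoch = 0L)
    wait <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n_train)
      for (start in seq(1L, n_train, by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, n_train)]
        Xb <- Xtr[bi, , drop = FALSE]; yb <- ytr[bi]
        nb <- length(bi)
        Z <- sweep(Xb %*% model$W1, 2L, model$b1, "+")
        Hh <- Z; Hh[Hh < 0] <- 0
        pred <- drop(Hh %*% model$W2) + model$b2
        dpred <- 2 * (pred - yb) / nb
        grad <- list(
          W1 = NULL, b1 = NULL,
          W2 = crossprod(Hh, dpred), b2 = sum(dpred))
        dH <- tcrossprod(dpred, model$W2)
        dH[Z <= 0] <- 0
        grad$W1 <- crossprod(Xb, dH)
        grad$b1 <- colSums(dH)
        if (!all(vapply(grad, function(g) all(is.finite(g)), TRUE)))
          stop("non-finite gradient at epoch ", epoch,
               "; reduce the learning rate")
        step <- step + 1L
        corr1 <- 1 - b1m^step; corr2 <- 1 - b2m^step
        for (w in c("W1", "b1", "W2", "b2")) {
          m[[w]] <- b1m * m[[w]] + (1 - b1m) * grad[[w]]
          v[[w]] <- b2m * v[[w]] + (1 - b2m) * grad[[w]]^2
          model[[w]] <- model[[w]] - cfg$learning_rate *
            (m[[w]] / corr1) / (sqrt(v[[w]] / corr2) + eps)
        }
      }
      mae_te <- mean(abs(mlp_forward(model, Xte) - yte))
      if (!is.finite(mae_te)) stop("non-finite held-out loss at epoch ", epoch)
      if (verbose && epoch %% 10L == 0L)
        message(sprintf("  epoch %3d  held-out MAE %.4f", epoch, mae_te))
      if (mae_te < best$mae) {
        best <- list(mae = mae_te, model = model, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }

    model <- best$model
    model$n_params <- n_in * h + h + h + 1L
    model$config <- cfg
    model$config_hash <- config_hash(cfg)
    model$best_epoch <- best$epoch
    class(model) <- "fn_regressor"
    model$eval <- evaluate_mae(model, Xte, yte)
    model
  })
}

#' @export
print.fn_regressor <- function(x, ...) {
  cat(sprintf(
    "<fn_regressor> %d -> %d (relu) -> 1, %d trainable parameters\n",
    nrow(x$W1), ncol(x$W1), x$n_params))
  cat(sprintf("  held-out MAE %.4f (n = %d, best epoch %d)\n",
              x$eval$mae, x$eval$n_eval, x$best_epoch))
  invisible(x)
}

#' Number of trainable parameters of a regressor
#'
#' @param model an `fn_regressor`.
#' @return Integer parameter count (46,209 for the reference 720->64->1
#'   architecture: 46,144 in the hidden layer and 65 in the output layer).
#' @export
n_params <- function(model) model$n_params

#' Predict the correlation exponent alpha from ordinal probabilities
#'
#' @param model an `fn_regressor`.
#' @param x an `ordinal_distribution`, a raw probability vector of length D!,
#'   or a series (from which the distribution is computed with the model's
#'   D and lag).
#' @return The raw network output alpha_e (unclamped); reference-curve
#'   lookups clamp it to the calibrated range themselves.
#' @export
predict_alpha <- function(model, x) {
  stopifnot(inherits(model, "fn_regressor"))
  p <- if (inherits(x, "ordinal_distribution")) x$probs
  else if (is.numeric(x) && length(x) == nrow(model$W1) &&
           abs(sum(x) - 1) < 1e-6) x
  else pattern_distribution(series_values(x), D = model$D,
                            lag = model$lag)$probs
  if (length(p) != nrow(model$W1))
    stop("feature length ", length(p), " does not match the model input (",
         nrow(model$W1), ")")
  mlp_forward(model, matrix(p * model$feature_scale, 1L))
}

#' Mean absolute error of alpha estimates
#'
#' `E = mean(|alpha_e - alpha|)` over a labeled feature set, plus the MAE
#' binned over the alpha grid (0.5-wide bins) to expose where the regressor
#' is least accurate.
#'
#' @param model an `fn_regressor`.
#' @param features matrix of ordinal probability rows (or a corpus list).
#' @param alphas true exponents (ignored when `features` is a corpus).
#' @return List with `mae`, `per_alpha_error` (data.frame bin/mae/n),
#'   `n_eval`.
#' @export
evaluate_mae <- function(model, features, alphas = NULL) {
  if (is.list(features) && !is.null(features$features)) {
    alphas <- features$alphas
    features <- features$features
  }
  pred <- mlp_forward(model, as.matrix(features) * model$feature_scale)
  err <- abs(pred - alphas)
  bins <- floor(alphas / 0.5) * 0.5
  agg <- tapply(err, bins, mean)
  list(mae = mean(err),
       per_alpha_error = data.frame(alpha_bin = as.numeric(names(agg)),
                                    mae = as.numeric(agg),
                                    n = as.integer(table(bins))),
       n_eval = length(err))
}

config_hash <- function(cfg) {
  # FNV-1a over the deparsed config; stable id, not cryptographic
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Save a regressor as JSON
#'
#' Explicit shapes, row-major weight arrays, activation names, config hash
#' and a format version; weights are written with 17 significant digits so a
#' load reproduces predictions bit-identically.
#'
#' @param model an `fn_regressor`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_regressor <- function(model, path) {
  stopifnot(inherits(model, "fn_regressor"))
  obj <- list(
    format = "chaostoch-regressor", version = 1L,
    layers = list(
      list(type = "dense", activation = "relu",
           shape = dim(model$W1),
           weights = as.vector(t(model$W1)), biases = model$b1),
      list(type = "dense", activation = "linear",
           shape = dim(model$W2),
           weights = as.vector(t(model$W2)), biases = model$b2)),
    feature_scale = model$feature_scale, D = model$D, lag = model$lag,
    alpha_range = model$alpha_range, n_params = model$n_params,
    config_hash = model$config_hash, best_epoch = model$best_epoch,
    heldout_mae = model$eval$mae)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Load a regressor saved by [save_regressor()]
#'
#' @param path JSON file path.
#' @return An `fn_regressor`.
#' @export
load_regressor <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "chaostoch-regressor"))
    stop("not a chaostoch regressor file: ", path)
  l1 <- obj$layers[1, ]; l2 <- obj$layers[2, ]
  s1 <- unlist(l1$shape); s2 <- unlist(l2$shape)
  model <- list(
    W1 = matrix(unlist(l1$weights), s1[1], s1[2], byrow = TRUE),
    b1 = unlist(l1$biases),
    W2 = matrix(unlist(l2$weights), s2[1], s2[2], byrow = TRUE),
    b2 = unlist(l2$biases),
    feature_scale = obj$feature_scale, D = obj$D, lag = obj$lag,
    alpha_range = obj$alpha_range, n_params = obj$n_params,
    config_hash = obj$config_hash, best_epoch = obj$best_epoch,
    eval = list(mae = obj$heldout_mae, n_eval = NA_integer_))
  class(model) <- "fn_regressor"
  model
}
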
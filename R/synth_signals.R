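# Seeded generators for the stochastic and deterministic signal families used
# to train and validate the method, plus the contamination / summation /
# shuffling transforms.

#' Generate flicker (colored) noise with spectrum P(f) ~ 1/f^alpha
#'
#' Frequency-domain synthesis: independent Gaussian Fourier coefficients on
#' the real-FFT grid are scaled by `f^(-alpha/2)` (the DC bin is treated like
#' the fundamental, i.e. no low-frequency cutoff beyond it), the spectrum is
#' normalized so the output has unit variance in expectation, and the inverse
#' transform is taken.  `alpha = 0` gives white noise, `alpha = 2` a
#' Brownian-like signal.  The returned series is mean-subtracted; ordinal
#' statistics are unaffected by the shift.
#'
#' @param alpha spectral exponent; the regressor is trained on `[-1, 3]`,
#'   values in the extended sanity range `[-2, 4]` are accepted.
#' @param n series length (>= 2).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A [new_series()] object of length `n`.
#' @export
generate_flicker <- function(alpha, n, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("`alpha` must be a single finite number")
  if (alpha < -2 || alpha > 4)
    stop("`alpha` = ", alpha, " outside the supported range [-2, 4]")
  n <- check_count(n, "n", min = 2L)
  vals <- with_seed(seed, {
    nf <- n %/% 2L + 1L                 # real-FFT bins, f = 0 .. 1/2
    f <- (seq_len(nf) - 1) / n
    s <- f
    s[1] <- f[2]                        # DC scaled like the fundamental
    s <- s^(-alpha / 2)
    # normalize so that the synthesized signal has unit variance
    w <- s[-1]
    if (n %% 2L == 0L) w[length(w)] <- w[length(w)] / 2
    sigma <- 2 * sqrt(sum(w^2)) / n
    re <- rnorm(nf) * s
    im <- rnorm(nf) * s
    im[1] <- 0; re[1] <- re[1] * sqrt(2)
    if (n %% 2L == 0L) { im[nf] <- 0; re[nf] <- re[nf] * sqrt(2) }
    spec <- complex(real = re, imaginary = im)
    full <- complex(length.out = n)
    full[seq_len(nf)] <- spec
    if (nf > 2L) {
      mirror <- if (n %% 2L == 0L) 2L:(nf - 1L) else 2L:nf
      full[n + 2L - mirror] <- Conj(spec[mirror])
    }
    y <- Re(fft(full, inverse = TRUE)) / n / sigma
    y - mean(y)
  })
  new_series(vals, "flicker", list(alpha = alpha), seed)
}

#' Generate fractional Gaussian noise or fractional Brownian motion
#'
#' fGn is sampled exactly by Davies-Harte circulant embedding of its
#' autocovariance; fBm is the cumulative sum of an fGn path.  The Hurst index
#' maps to the flicker exponent as `alpha = 2H - 1` (fGn, `-1 < alpha < 1`)
#' and `alpha = 2H + 1` (fBm, `1 < alpha < 3`); `H = 0.5` gives white noise /
#' classical Brownian motion respectively.
#'
#' @param family `"fgn"` or `"fbm"`.
#' @param hurst Hurst index in (0, 1).
#' @inheritParams generate_flicker
#' @return A [new_series()] object of length `n`.
#' @export
generate_fractional <- function(family = c("fgn", "fbm"), hurst, n,
                                seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(hurst) || length(hurst) != 1L || !is.finite(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop("`hurst` must lie strictly inside (0, 1)")
  n <- check_count(n, "n", min = 2L)
  vals <- with_seed(seed, {
    g <- fgn_sample(hurst, n)
    if (family == "fbm") cumsum(g) else g
  })
  new_series(vals, family, list(hurst = hurst), seed)
}

# One exact fGn path of length n (unit-variance increments) via Davies-Harte.
fgn_sample <- function(hurst, n) {
  h2 <- 2 * hurst
  k <- 0:n
  gamma <- 0.5 * ((k + 1)^h2 - 2 * k^h2 + abs(k - 1)^h2)
  m <- 2L * n
  row <- c(gamma[1:(n + 1L)], gamma[n:2])
  ev <- Re(fft(row))
  ev[ev < 0 & ev > -1e-8 * max(ev)] <- 0
  if (any(ev < 0))
    stop("circulant embedding failed (negative eigenvalue) for H = ", hurst)
  w <- complex(length.out = m)
  u <- rnorm(2L)                       # k = 0 and k = n bins
  w[1] <- sqrt(ev[1] / m) * u[1]
  w[n + 1L] <- sqrt(ev[n + 1L] / m) * u[2]
  if (n > 1L) {
    idx <- 2:n
    a <- rnorm(n - 1L)
    b <- rnorm(n - 1L)
    w[idx] <- sqrt(ev[idx] / (2 * m)) * complex(real = a, imaginary = b)
    w[m + 2L - idx] <- Conj(w[idx])
  }
  Re(fft(w))[seq_len(n)]
}

#' Generate independent identically distributed noise
#'
#' @param dist `"uniform"` (on \[0, 1\]), `"gaussian"` (standard normal) or
#'   `"cauchy"` (standard Cauchy).
#' @inheritParams generate_flicker
#' @return A [new_series()] object of length `n`.
#' @export
generate_iid <- function(dist = c("uniform", "gaussian", "cauchy"), n,
                         seed = NULL) {
  dist <- match.arg(dist)
  n <- check_count(n, "n", min = 2L)
  vals <- with_seed(seed, switch(dist,
    uniform  = runif(n),
    gaussian = rnorm(n),
    cauchy   = rcauchy(n)))
  new_series(vals, dist, list(), seed)
}

map_defaults <- c(betax = 2, logistic = 4, schuster = 1.5, skewtent = 0.1847)
map_ids <- c(betax = 0L, logistic = 1L, schuster = 2L, skewtent = 3L)

#' Iterate a chaotic interval map
#'
#' Supported maps (all on the unit interval):
#' \describe{
#'   \item{betax}{generalized Bernoulli map `x -> beta*x mod 1`, default
#'     `beta = 2`.}
#'   \item{logistic}{`x -> r*x*(1-x)`, default `r = 4`.}
#'   \item{schuster}{intermittent map `x -> x + x^z mod 1`, default
#'     `z = 1.5` (the intermittent 1/f regime requires `z > 1`; `z = 0.5` is
#'     also runnable).}
#'   \item{skewtent}{`x -> x/w` on `[0, w]`, `(1-x)/(1-w)` on `(w, 1]`,
#'     default `w = 0.1847`.}
#' }
#'
#' When `x0` is not given it is drawn uniformly on (0.01, 0.99) from `seed`
#' and `transient` iterations are discarded.  For the beta-x map with integer
#' `beta` the seeded orbit is built by the exact backward (inverse-branch)
#' construction, because forward iteration of `x -> beta*x mod 1` in binary
#' floating point exhausts the mantissa and collapses every orbit onto the
#' fixed point 0; the backward orbit follows the map's invariant (uniform)
#' measure and satisfies the forward rule to within 1 ulp.  An explicit `x0`
#' always requests plain forward iteration, which raises a degenerate-orbit
#' error if the iterate hits the fixed point.
#'
#' @param map one of `"betax"`, `"logistic"`, `"schuster"`, `"skewtent"`.
#' @param n number of post-transient iterates to return.
#' @param seed integer seed for the initial condition (and branch draws).
#' @param parameter map parameter (beta, r, z or w); `NULL` for the default.
#' @param x0 optional explicit initial condition in (0, 1).
#' @param transient iterations discarded before recording; defaults to 1000
#'   for a seeded draw and to 0 when `x0` is given explicitly (the orbit is
#'   then wanted from `x0` itself).
#' @return A [new_series()] object of length `n`.
#' @export
iterate_map <- function(map = c("betax", "logistic", "schuster", "skewtent"),
                        n, seed = NULL, parameter = NULL, x0 = NULL,
                        transient = NULL) {
  map <- match.arg(map)
  n <- check_count(n, "n", min = 1L)
  if (is.null(transient)) transient <- if (is.null(x0)) 1000L else 0L
  transient <- check_count(transient, "transient", min = 0L)
  if (is.null(parameter)) parameter <- map_defaults[[map]]
  if (map == "skewtent" && (parameter <= 0 || parameter >= 1))
    stop("skew tent parameter must lie in (0, 1)")
  vals <- with_seed(seed, {
    if (is.null(x0)) {
      x0_draw <- runif(1, 0.01, 0.99)
      if (map == "betax" && parameter == round(parameter)) {
        beta <- as.integer(round(parameter))
        branches <- sample.int(beta, n - 1L, replace = TRUE) - 1L
        betax_backward_cpp(x0_draw, branches, beta)
      } else {
        iterate_map_cpp(map_ids[[map]], parameter, x0_draw, n, transient)
      }
    } else {
      if (!is.numeric(x0) || length(x0) != 1L || x0 <= 0 || x0 >= 1)
        stop("`x0` must lie in the open unit interval")
      iterate_map_cpp(map_ids[[map]], parameter, x0, n, transient)
    }
  })
  new_series(vals, map,
             list(parameter = parameter, x0 = x0, transient = transient),
             seed)
}

#' Successive maxima of the Lorenz x variable
#'
#' Integrates the Lorenz flow (dx/dt = sigma(y-x), dy/dt = x(R-z)-y,
#' dz/dt = xy-bz) with a fixed-step 4th-order Runge-Kutta scheme and returns
#' the sequence of successive local maxima of x(t) after the transient, each
#' refined by a parabolic fit through the three bracketing samples.  The
#' defaults sigma = 16, R = 45.92, b = 4 place the flow in its chaotic
#' regime.
#'
#' @param n_maxima number of maxima to return.
#' @param seed integer seed for the initial condition.
#' @param sigma,R,b flow parameters.
#' @param dt integration step (time units); halving it should change each
#'   reported maximum by well under 1e-3 over short horizons.
#' @param transient_time initial time span discarded (time units).
#' @param max_time hard cap on total integrated time; if fewer than
#'   `n_maxima` maxima are found before the cap (e.g. sub-threshold `R`
#'   stabilizing a fixed point) an error reports the shortfall.
#' @return A [new_series()] object of length `n_maxima`.
#' @export
lorenz_maxima <- function(n_maxima, seed = NULL, sigma = 16, R = 45.92,
                          b = 4, dt = 0.01, transient_time = 100,
                          max_time = transient_time + 5 * n_maxima) {
  n_maxima <- check_count(n_maxima, "n_maxima", min = 2L)
  vals <- with_seed(seed, {
    ic <- c(runif(1, -10, 10), runif(1, -10, 10), R - 1 + runif(1, -10, 10))
    lorenz_maxima_cpp(n_maxima, sigma, R, b, dt, transient_time, max_time,
                      ic[1], ic[2], ic[3])
  })
  new_series(vals, "lorenz_maxima",
             list(sigma = sigma, R = R, b = b, dt = dt,
                  transient_time = transient_time),
             seed)
}

#' Mix a deterministic signal with noise
#'
#' Computes `Z_t = (1 - eta) * X_t + eta * Y_t` after standardizing both
#' inputs to zero mean and unit variance, so `eta` is a comparable amplitude
#' fraction: `eta = 0` returns (standardized) `x`, `eta = 1` returns `y`.
#' Ordinal statistics only see the relative scale of the two components, so
#' the standardization convention is fixed and documented here.
#'
#' @param x,y series or numeric vectors of equal length.
#' @param eta noise fraction in \[0, 1\].
#' @param standardize standardize inputs first (default `TRUE`; set `FALSE`
#'   only when the inputs are already on a common scale).
#' @return A [new_series()] object.
#' @export
mix_signals <- function(x, y, eta, standardize = TRUE) {
  vx <- series_values(x); vy <- series_values(y)
  if (length(vx) != length(vy)) stop("`x` and `y` must have equal length")
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0 || eta > 1)
    stop("`eta` must be a single number in [0, 1]")
  if (standardize) { vx <- standardize(vx); vy <- standardize(vy) }
  new_series((1 - eta) * vx + eta * vy, "mixture", list(eta = eta), NULL)
}

#' Sum of independent chaotic orbits
#'
#' Pointwise sum of `m` independent orbits of the same map (independent
#' initial conditions derived from `seed`), standardized to zero mean and
#' unit variance.  As `m` grows the sum approaches a Gaussian signal and the
#' deterministic structure is progressively washed out.
#'
#' @inheritParams iterate_map
#' @param m number of independent orbits to sum (>= 1).
#' @return A [new_series()] object of length `n`.
#' @export
sum_of_maps <- function(map = c("betax", "logistic", "schuster", "skewtent"),
                        m, n, seed = NULL, parameter = NULL,
                        transient = 1000L) {
  map <- match.arg(map)
  m <- check_count(m, "m", min = 1L)
  seeds <- child_seeds(seed, m)
  acc <- numeric(n)
  for (i in seq_len(m))
    acc <- acc + iterate_map(map, n, seed = seeds[[i]],
                             parameter = parameter,
                             transient = transient)$values
  new_series(standardize(acc), paste0("sum_", map),
             list(m = m, parameter = parameter), seed)
}

#' Randomly permute a series
#'
#' Destroys all temporal correlations while preserving the value multiset
#' exactly; the shuffled version of a chaotic orbit is the stochastic control
#' used in the noise-contamination experiments.
#'
#' @param x series or numeric vector.
#' @param seed integer seed for the permutation.
#' @return A [new_series()] object (length-1 inputs are returned unchanged).
#' @export
shuffle_series <- function(x, seed = NULL) {
  v <- series_values(x)
  if (length(v) <= 1L) return(x)
  perm <- with_seed(seed, sample.int(length(v)))
  new_series(v[perm], "shuffled", list(parent = class(x)[1]), seed)
}
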
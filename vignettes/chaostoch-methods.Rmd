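---
title: "Separating chaos from noise with ordinal patterns and a flicker-noise-trained regressor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating chaos from noise with ordinal patterns and a flicker-noise-trained regressor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Signals from chaotic deterministic systems and from stochastic processes can
be statistically indistinguishable at the level of marginal distributions
and even power spectra: the doubling map produces a uniform marginal like
white noise, and the Schuster map's spectrum decays like colored noise.
`chaostoch` implements a two-step method that separates the two classes and
simultaneously quantifies the strength of temporal correlation.

**Step 1 — a correlation exponent from ordinal statistics.**  Every window
of $D = 6$ consecutive samples is replaced by its ordinal pattern (the
permutation given by ranking the window's values), and the relative
frequencies $\mathcal{P}(i)$, $i = 1,\dots,D! = 720$, of the patterns form
the feature vector of the series.  A feed-forward network
$720 \to 64\,(\mathrm{relu}) \to 1$ — 46,209 trainable parameters — is
trained *exclusively on flicker noise*, i.e. Gaussian processes with power
spectrum $P(f) \propto 1/f^\alpha$, to regress the exponent $\alpha$ from
the pattern probabilities, with $\alpha$ drawn uniformly from $[-1, 3]$.
Applied to an arbitrary series, the network output $\alpha_e$ estimates the
strength of its temporal correlation ($\alpha_e \approx 0$: uncorrelated;
$\alpha_e \approx 2$: Brownian-like).

**Step 2 — distance to the flicker-noise entropy curve.**  The normalized
permutation entropy
$$\bar S = -\frac{1}{\ln D!}\sum_{i=1}^{D!} \mathcal{P}(i)\ln \mathcal{P}(i)$$
of flicker noise is a smooth function $\bar S_{\mathrm{fn}}(\alpha)$ of its
exponent, calibrated here by Monte-Carlo on an $\alpha$ grid.  Stochastic
signals sit on this curve; deterministic chaos, whose ordinal statistics are
constrained by forbidden patterns, falls well below it.  The classifier is
the normalized distance
$$\Omega(\alpha_e) =
  \frac{\lvert \bar S_{\mathrm{fn}}(\alpha_e) - \bar S \rvert}
       {\bar S_{\mathrm{fn}}(\alpha_e)},$$
with label *chaotic* iff $\Omega > \Omega^\* = 0.1$ (strict inequality; the
cutoff reflects the separation observed for series of ~100 points and is a
configurable argument, not a constant).

```{r pipeline}
library(chaostoch)
cfg <- training_config(seed = 1)       # 5000 flicker series of 2^16 samples
model <- train_regressor(build_corpus(cfg), cfg)
curve <- calibrate_fn_curve(series_length = 2^17, seed = 2)
analyze_series(iterate_map("logistic", 2^17, seed = 3), model, curve)
```

## Tunable parameters and defaults

* **Ordinal order `D = 6`, `lag = 1`** (dimensionless): $D!$ must be small
  enough that $N \gg D!$ for feature estimation yet large enough to expose
  forbidden patterns; 6 is the reference choice and fixes the 720-feature
  contract.  Windows advance by one sample, so consecutive windows share
  $D-1$ values.
* **Training corpus** (`training_config()`): 5,000 series of $2^{16}$
  samples, $\alpha \sim U[-1,3]$, 80/20 train/test split.  The reference
  study used 50,000 series of $2^{20}$ samples; the desk scale reaches a
  held-out mean absolute error $\mathcal{E} \approx 0.010$ in about five
  minutes on one core, already matching the full-scale figure
  ($\approx 0.01$), so the extra two orders of magnitude of compute buy
  little for this architecture.
* **Optimizer**: Adam, learning rate $10^{-3}$, batch 32, up to 200 epochs
  with early stopping (patience 30) on the held-out MAE, mean-square-error
  loss, Glorot-uniform initialization — standard deep-learning-framework
  defaults.  The epoch count, batch size and early-stopping rule are not
  prescribed by the method; they are package choices, exposed in
  `training_config()`.
* **Reference curve** (`calibrate_fn_curve()`): grid step 0.05 on
  $[-1, 3]$, 100 realizations per point, series length $2^{17}$.  The curve
  is precomputed rather than re-simulated per query, which makes
  `analyze_series()` deterministic given its two artifacts.
* **Decision threshold** `threshold = 0.1`, dimensionless.

## Why the features are fed raw

The network consumes the 720 probabilities exactly as estimated — no
centering, no rescaling.  This is not an oversight.  The probabilities are
$O(1/720)$, so with Glorot initialization every relu unit starts in the
neighbourhood of its switching point and Adam trains the network in a
smooth, nearly-lazy regime.  Empirically this regime reaches the same
held-out accuracy as aggressively scaled variants, but its *extrapolation*
— what the network returns for feature vectors far from the flicker
manifold, which is precisely what $\alpha_e$ of a chaotic signal is — is
stable from one training run to the next (run-to-run spread about
$\pm 0.1$), whereas scaled-input or high-learning-rate training produced
equally accurate interpolation with essentially arbitrary extrapolation
(spread of several units).  Since the whole second step hinges on
evaluating $\bar S_{\mathrm{fn}}$ at $\alpha_e$, extrapolation stability is
a correctness property here, not a nicety.

## The reference curve is length-dependent

With $w = N - (D-1)$ windows, the normalized PE of even perfectly white
noise cannot exceed $\ln(w)/\ln(D!)$: at $N = 64$ that ceiling is about
0.62.  A reference curve calibrated at $2^{17}$ samples would therefore
misclassify every short stochastic series as chaotic.  `FNCurve` objects
carry their calibration length, `analyze_series()` warns when the curve and
the series differ grossly in length, and the experiment drivers
(`run_length_sweep()`, the acceptance script) recalibrate one curve per
analyzed length.  This finite-size matching is what makes the short-series
claims hold: stochastic ensembles stay below $\Omega = 0.1$ already at
$N = 64$, chaotic ones exceed $\Omega = 0.2$ from $N = 1024$ on.

## Synthetic generators: what they emulate, and numerical care

`generate_flicker()` synthesizes $1/f^\alpha$ noise in the frequency
domain: independent Gaussian coefficients on the real-FFT grid scaled by
$f^{-\alpha/2}$, the DC bin treated like the fundamental, unit-variance
normalization — the construction of the generator used by the reference
study.  `generate_fractional()` draws exact fractional Gaussian noise by
Davies–Harte circulant embedding ($\alpha = 2H - 1$) and integrates it for
fractional Brownian motion ($\alpha = 2H + 1$).  The chaotic systems are
the doubling ($\beta x$, $\beta = 2$), logistic ($r = 4$), Schuster
($z = 1.5$ by default; see below) and skew-tent ($\omega = 0.1847$) maps,
and the Lorenz flow ($\sigma = 16$, $R = 45.92$, $b = 4$), analyzed through
the sequence of successive maxima of $x(t)$.

Numerical choices worth knowing:

* **Doubling map in floating point.**  $x \mapsto 2x \bmod 1$ shifts
  mantissa bits left, so *every* double-precision forward orbit collapses
  onto the fixed point 0 within ~1100 iterations.  Seeded ensemble orbits
  are therefore built backwards through uniformly chosen inverse branches
  and reversed — an orbit that satisfies the forward rule to within 1 ulp
  and follows the uniform invariant measure.  Forward iteration remains
  available with an explicit `x0` and raises a *degenerate orbit* error if
  it reaches the fixed point (so does the logistic orbit started at 0.5).
* **Lorenz integration**: fixed-step RK4 with `dt = 0.01`, 100 time units
  of transient, maxima detected as samples strictly above both neighbours
  and refined by a parabolic fit.  Because chaos amplifies integration
  error exponentially, the step-halving convergence guard is meaningful
  only over short horizons; the test suite checks the first few maxima at
  `dt` vs `dt/2` agree to $10^{-3}$.  An integration-time cap turns
  sub-threshold parameter choices (e.g. $R = 10$, which stabilizes a fixed
  point) into an informative error instead of an endless loop.
* **Mixing** `mix_signals()` standardizes both components to zero mean and
  unit variance before forming $Z = (1-\eta)X + \eta Y$, so $\eta$ is a
  comparable amplitude fraction.  Ordinal statistics respond only to the
  relative scale of the two components, so fixing one convention and
  documenting it is required for reproducibility.
* **Ties** are broken by temporal order (earlier sample ranks lower).  All
  the generators here are continuous-valued, so ties occur with probability
  zero in the study conditions; the rule matters only for quantized user
  data.  Constant series are rejected outright — a pure-tie ordinal
  distribution reflects the tie rule, not the signal.
* **Schuster parameter ambiguity.**  Published descriptions of this
  benchmark disagree between $z = 0.5$ and $z = 1.5$; only $z > 1$
  produces the intermittent $1/f^z$ regime the map is usually cited for,
  so the package defaults to 1.5 and leaves `parameter` exposed.  The
  Schuster row is reported by `run_table1()` but excluded from the
  quantitative benchmarks.

## Scales used by the tests and the acceptance script

All validation runs are desk-scale by design: training 2,000–5,000 series
of $2^{16}$ samples, benchmark ensembles of 25–100 replicates of $2^{17}$
samples (Lorenz: 20 replicates of $2^{15}$ maxima), curve calibration with
20–100 realizations per grid point, and short-series sweeps at $N = 64$ and
$N = 1024$ with 30–100 replicates.  The reference ensembles (1,000
replicates of $2^{20}$ points) change the ensemble *standard deviations*
but, as the error-vs-length analysis shows, move the means by less than the
quoted tolerances.  No shipped weights: every artifact is regenerated from
seeds, which keeps the whole pipeline reproducible from source.

## Known limitations

* **$\alpha_e$ far off the flicker manifold is network-specific.**  For
  strongly chaotic signals whose feature vectors lie far from any flicker
  distribution (logistic, skew tent), the value of $\alpha_e$ is an
  extrapolation that independently trained networks need not agree on, and
  desk-scale retraining reproducibly yields values differing from the
  published ones by ~1 unit for those two systems (while $\beta x$, Lorenz
  maxima, fBm and all stochastic systems agree closely).  $\Omega$ is
  barely affected, because $\bar S_{\mathrm{fn}}$ is nearly flat over
  $\alpha \in [-1, 1.4]$: the *classification* is robust, the *exponent*
  of a deeply chaotic signal is indicative only.
* **Closure at the upper training edge.**  Flicker noise at
  $\alpha \approx 3$ is strongly nonstationary; the desk-scale regressor's
  error there (0.02–0.05) combined with the curve's steepest slope yields
  self-classification distances $\Omega \approx 0.02$–0.04 at the
  $\alpha = 3$ grid end rather than the $\leq 0.01$ seen elsewhere on the
  grid.  A full-scale network ($\mathcal{E} \approx 0.01$ at the edge)
  closes this gap.
* **Noisy periodic signals** are outside the method's scope: their ordinal
  statistics resemble a large-$\alpha$ stochastic signal, and the method
  inherits this blind spot from its design.
* The synthetic generators emulate stationary (or controlled
  nonstationary) textbook systems; empirical data with trends,
  seasonality, or measurement quantization need pre-processing judgment
  that no test here validates.
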
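---
title: "Pairwise Gaussian scale mixtures and surround modulation of V1 correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise Gaussian scale mixtures and surround modulation of V1 correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pairgsm` studies how the statistics of natural images shape the
trial-to-trial covariability of pairs of V1 neurons, under the hypothesis
that instantaneous neural activity represents samples from a posterior
distribution over latent image features (the "neural sampling"
hypothesis). The generative model is a pairwise Gaussian scale mixture
(GSM): an observation vector $x \in \mathbb{R}^{36}$ — the outputs of two
sets of 18 oriented filters, one set per model neuron — is generated as

$$x = V\,g + \eta, \qquad g \sim \mathcal{N}(0, \Sigma_g), \qquad
\eta \sim \mathcal{N}(0, \Sigma_{\text{noise}}),$$

where $V$ couples a positive *global modulator* to the local features. In
the **shared** structure a single modulator scales all 36 features,
$V = v I$; in the **independent** structure each neuron has its own,
$V = \mathrm{diag}(v_1 I_{18}, v_2 I_{18})$, and the across-neuron blocks
of $\Sigma_g$ are constrained to zero. Modulators follow a Weibull prior
with shape 2 and scale $\sqrt 2$ — exactly a Rayleigh(1), so
$E[v^2] = 2$. (The shape/scale convention is chosen so the prior *is* the
Rayleigh distribution this model family traditionally uses; the two
parameters are configurable.) The modulator multiplies the Gaussian
features, producing the heavy-tailed, contrast-coupled filter statistics
characteristic of natural images.

Each model neuron is a set of 9 receptive-field positions (one center,
eight surround positions on a ring) $\times$ 2 phases. The two phases of
a position form a quadrature pair, and a phase-invariant (complex-cell)
response converts feature samples to spike counts:
$r = \alpha(\lfloor g_c^+ + \delta\rfloor_+ + \lfloor g_c^- +
\delta\rfloor_+)$, with gain $\alpha$ and rectification offset $\delta$.
Pairwise spike-count correlation $r_{sc}$ is the Pearson correlation of
the two neurons' responses across posterior samples ("trials").

## Filter bank

Kernels are Gabor quadrature pairs (cosine/even and sine/odd carriers
under an isotropic Gaussian envelope), evaluated analytically over the
patch, corrected to exactly zero mean and unit L2 norm. Defaults: carrier
period $=$ RF/2, envelope $\sigma =$ period/2 (about one octave of
bandwidth), support truncated at twice the period, surround ring at one
RF diameter — so the surround kernels abut the center kernel's effective
($2\sigma$) extent. A band `scale` index doubles the period per level. We
verified the quadrature property (energy ripple $<1\%$ for drifting
gratings), translation equivariance, and monotone orientation tuning in
the unit tests; the underlying theory is robust to the precise kernel
family, which is why a Gabor pair stands in for a steerable-pyramid band.

A *pair geometry* places a reference neuron (horizontal, at the patch
center) and a second neuron rotated by $\Delta\theta \in [0^\circ,
90^\circ]$ and displaced by $(\Delta x, \Delta y) \in [-3, 3]$ RF. All
positions are in RF-diameter units, mapped to pixels via `rf_diam_px`.

## Training by moment matching

Because $E[x x^\top] = E[v^2]\,\Sigma_g + \Sigma_{\text{noise}}$, both
covariances are estimated from image ensembles without iterative fitting:

1. $\Sigma_{\text{noise}}$ is the empirical covariance of filter outputs
   over white-noise images (pixel mean 0.5, SD 0.1), with the
   across-neuron blocks optionally rescaled by a `cross_set_scale`
   parameter (default 1, i.e. untouched) controlling shared additive
   noise.
2. Natural(-like) images are rescaled by one scalar so the RMS filter
   output ratio natural/noise equals the target signal-to-noise ratio
   (default 4.8; "RMS over all filters and images" is our reading of the
   ratio, recorded alongside the scalar).
3. $\Sigma_g = (S_x - \Sigma_{\text{noise}})/E[v^2]$, with the
   across-neuron blocks zeroed for the independent structure, and a
   symmetric eigenvalue floor (`1e-8 * trace / dim`) because the
   difference can be slightly indefinite at finite sample size; clipped
   eigenvalues are reported in a warning.

## Inference with the modulator marginalized

Conditional on the modulator the model is linear-Gaussian, so the
marginalized posterior $p(g \mid x)$ is a continuous mixture of Gaussians
indexed by $v$. The package exposes three consistent routes:

- `conditional_posterior()` — the exact Gaussian at fixed $v$.
- `posterior_oracle()` — deterministic quadrature: a log-spaced grid over
  the prior's $[10^{-6}, 1-10^{-6}]$ quantile range (128 points in 1-D,
  64 per dimension in 2-D), trapezoid weights, mixture moments in closed
  form. Because the conditional is exact, quadrature error is the only
  error; the normalized weight on the grid boundary is audited
  ($<10^{-6}$, otherwise an error instructs widening the grid). This is
  the reference implementation.
- `sample_posterior()` — a collapsed slice-within-Gibbs sampler: the
  modulator(s) are slice-sampled on the log scale under their *exact*
  marginal posterior (the features integrated out analytically), then $g$
  is drawn exactly from the Gaussian conditional. We chose this over
  Hamiltonian Monte Carlo in the joint $(g, v)$ space deliberately: the
  collapsed chain lives in 1 (shared) or 2 (independent) dimensions,
  mixes essentially instantly, has no step-size tuning, and is exactly
  reproducible under a seed. For the shared structure a one-time
  simultaneous diagonalization of $\Sigma_g$ against
  $\Sigma_{\text{noise}}$ makes every density evaluation and conditional
  draw $O(d)$; the independent structure's two-dimensional chain runs in
  compiled code. Split-$\hat R$ and effective sample sizes are computed
  for every dimension; $\hat R > 1.05$ is flagged (and warned) but the
  draws are still returned. Defaults follow the source model family: 2000
  posterior draws across 4 chains. We default warmup to 2000 as well, but
  the analyses here use a few hundred — a collapsed 1–2-dimensional slice
  chain forgets its initialization within tens of iterations, which the
  $\hat R$ diagnostics confirm.

The marginal likelihood $p(x)$ uses the same quadrature in the log
domain, and the shared-minus-independent log-likelihood ratio decides
which structure better captures an image ensemble for a given pair
geometry (`loglik_ratio_map()`).

## Why marginalization matters

At a fixed modulator the conditional covariance of $g$ does not depend on
the stimulus at all — linear-Gaussian conditioning leaves the posterior
covariance a function of $(v, \Sigma_g, \Sigma_{\text{noise}})$ only. All
stimulus- and size-dependence of model correlations therefore comes from
marginalizing the modulator: uncertainty about $v$ injects covariance
proportional to the products of the conditional means, and that
uncertainty shrinks as more context (a larger aperture) constrains $v$.
`simulate_pair(marginalize = FALSE)` operationalizes the ablation: the
modulator is fixed once per stimulus at the mode of its posterior given
the full-context (large) observation, and features are drawn from the
Gaussian conditional at both sizes. Fixing it per size instead would
smuggle the marginal information back in through the plug-in value, which
is why the full-context mode is used.

## Stimulus sizes

"Small" and "large" apertures cover, respectively, the center filters
only and the center plus surround ring. With the default kernels the
center kernel's effective extent is $\pm 0.5$ RF and the ring sits at 1
RF, so the defaults are 1 RF (small) and 4 RF (large) diameters, with one
RF mapped to one degree of visual angle. This mirrors the experimental
1° vs 6.7° conditions relative to parafoveal V1 RF sizes. The choice of
the small aperture matters: a small stimulus that leaks onto the
surround filters already pins the modulator and largely removes the
size-driven change in modulator uncertainty that produces correlation
modulation.

## Synthetic data

All inputs are generated in-package so every stage is testable without
downloads:

- **White-noise images** — i.i.d. Gaussian pixels (mean 0.5, SD 0.1,
  clipped to $[0,1]$; the clipped fraction, about $5\times10^{-7}$, is
  recorded).
- **Surrogate natural-like images** — a homogeneous random texture (1/f
  "pink" spectrum by default, optionally orientation-band-passed)
  multiplied region-wise by positive contrast samples: one global
  multiplier (`layout = "single"`, the statistical structure the shared
  model assumes) or independent multipliers in the left and right halves
  (`layout = "split"`, the independent structure). The multiplier
  distribution defaults to the model's own Rayleigh(1) prior. These
  surrogates reproduce the *non-stationarity* rationale — statistical
  dependencies varying across image regions — and the leptokurtic filter
  marginals of natural scenes, but none of the edge/contour structure,
  occlusions, or cardinal-orientation biases of photographs; model
  selection and correlation-modulation results on surrogates demonstrate
  internal consistency of the pipeline, not photographic generality.
  `rotate_augment()` applies the 4 × 45° rotation augmentation used to
  balance orientation statistics in ensembles that need it.
- **Forward-model observations** — exact draws of $(x, v, g)$ from either
  structure, with latents returned for recovery tests.
- **Spike-count sessions** — a Gaussian copula over Poisson margins
  plants Pearson spike-count correlations per pair class (centered /
  mixed / off-centered) at each stimulus size. The latent correlation is
  calibrated by an exact Hermite-polynomial expansion of the count
  covariance (the count is a staircase in the latent normal, so each
  Hermite coefficient is a finite sum over its jump points); infeasible
  targets are rejected with the attainable bound. RF centers are planted
  so the centered (<1°) and off-centered (>1.2°) groups are as
  configured; off-centered neurons get near-baseline small-size rates;
  per-image tuning (a two-factor log-rate model whose loadings follow RF
  polar angle) yields distance-graded signal correlations. Rates and
  correlations are class-level targets; individual pairs scatter around
  them.

Default session parameters mirror a typical planar-array recording: 270
images at 20 trials each and two sizes (1° and 6.7°), with planted
centered correlations 0.15 (small) / 0.10 (large) and mixed 0.04 / 0.08 —
suppression for centered pairs, facilitation for mixed pairs, with
rate confounds included (centered rates fall with size, off-centered
rates rise).

## The data-side pipeline

`classify_neurons()` applies the 1° / 1.2° distance thresholds (the gap
between them is excluded, as is anything not covered by the large
stimulus). `responsivity_filter()` implements the per-image inclusion
rule — evoked mean above both one baseline SD over the spontaneous mean
and 0.1 spikes/trial, with off-centered neurons additionally required
*not* to respond to the small size; high-density-probe recordings use 0.1
SD and a baseline mean capped at 0.1. `build_pair_table()` computes
$r_{sc}$ per (pair, image, size) across trials (missing when fewer than 3
trials or zero variance — never imputed), signal correlations from
across-image mean responses at the large size (the size that drives both
classes), and RF distances; off-centered–off-centered pairs are dropped.

`mean_matching()` controls for rate-driven estimation bias: pair-averaged
mean counts are histogrammed (20 equal-width bins over the pooled range)
separately per size, the common histogram (per-bin minimum) is retained
by random subsampling on each side, retained cases are paired within
bins, and a paired two-sided t-test compares sizes; a bootstrap over the
subsampling yields the distribution of matched means. Matching the
histograms exactly (rather than nudging means by dropping cases) is what
makes the matched histogram means *identical* by construction.

`subsampled_significance()` avoids pseudo-replication among the
$M(M-1)/2$ correlated pair estimates: per image, a factor-analysis
dimensionality $K$ (EM fit; $K$ chosen by 5-fold cross-validated
held-out likelihood over $K = 0\ldots10$, capped by the Ledermann bound)
sets a budget of $M \times K$ sampled pairs; sampled cases are aggregated
across images, t-tested, and the procedure repeated (default 1000 times)
with p-values averaged. With few trials the cross-validation is
conservative — weak factors often yield $K = 0$ or 1 — which shrinks the
pair budget rather than inflating significance.

`binned_modulation()` bins cases by signal correlation and RF distance
(equal-count edges, default 15 × 20 ≈ 300 candidate bins, bins with
fewer than 15 cases dropped) and `modulation_regression()` fits OLS of
bin-mean modulation on the z-scored predictors, reporting $R^2$,
coefficient p-values, and the $\Delta R^2$ from dropping either
predictor. The response is deliberately left unstandardized so noiseless
planted maps are recovered with their literal coefficients; z-scoring the
predictors alone does not change $R^2$ or the drop analysis.

## Numerical choices and degenerate inputs

- PSD repair everywhere is a symmetric eigenvalue floor at
  `1e-8 * trace/dim`; counts of clipped eigenvalues are surfaced as
  warnings, never silent.
- The degenerate geometry $\Delta\theta = \Delta x = \Delta y = 0$ makes
  the two filter sets identical and $S_x$ singular; the jitter floor
  handles it and such pairs behave as perfectly correlated twins
  ($r_{\text{signal}} = 1$).
- Singular innovation covariances in conditioning are jittered with a
  warning; a point-mass modulator "grid" of one value reduces every
  quadrature to the exact conditional.
- Zero-variance response vectors make $r_{sc}$ undefined; it is returned
  as `NA` with a warning and excluded from means downstream.
- Quadrature tails: analyses over bulk forward-model draws use a wider
  grid (`q_tail` down to 1e-12) when the boundary audit asks for it;
  the audit is never silenced in package code.

## Problem sizes used in the shipped analyses

The analyses and acceptance checks are scaled to run on a laptop-class
single core in minutes, as a deliberate design target: training ensembles
of 10,000 surrogate natural-like images (the size the source experiments
used; the heavy-tailed prior covariance genuinely needs this many — at
2,000 images the moment-matched covariances vary enough between
realizations to move predicted correlation modulations by a factor of
two) and 2,000 white-noise images (the noise covariance converges much
faster), a 96-pixel patch with an 8-pixel RF, 150-200 stimuli per
simulated condition with 2000 posterior draws over 4 chains (warmup 200),
10,000 held-out observations for model comparison, and synthetic sessions
of 16 + 10 neurons × 270 images × 20 trials. Pair simulations couple the
two stimulus sizes through common feature innovations — a standard
common-random-numbers device that leaves each size's posterior sample
distribution untouched while sharpening the paired small-minus-large
comparison. These sizes were chosen so that Monte-Carlo error is
comfortably below the effects being demonstrated; all of them are
arguments, not constants.

## Known limitations

- Surrogate images do not contain object structure; absolute
  log-likelihood-ratio magnitudes on real photographs will differ from
  the surrogate values even though the sign structure (shared best for
  overlapping pairs, independent for distant dissimilar pairs) is the
  prediction that matters.
- The offset default $\delta = 0.5$ is stated in units of the feature
  scale implied by unit-norm kernels and the 4.8 ensemble SNR (prior
  feature SD $\approx 0.33$). Strongly driven stimuli at the small size
  can still clip one phase heavily; this attenuates response-level
  correlations relative to feature-level ones, adds across-stimulus
  dispersion, and for rare stimuli clips a response to a constant, leaving
  that stimulus's $r_{sc}$ undefined (reported as `NA` and excluded from
  averages). This is why correlation-modulation analyses average over
  150-200 stimuli.
- The copula session generator calibrates class-level correlation
  targets at class-geometric-mean rates; individual pairs deviate by a
  few thousandths, which is below the resolution of the analyses that
  consume them.
- Factor-analysis dimensionality under 20-40 trials is noisy; the
  cross-validated choice errs low, making the subsampled test
  conservative rather than anticonservative.
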
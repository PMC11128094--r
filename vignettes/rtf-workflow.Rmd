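---
title: "Bayesian RTF modelling of sparse time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian RTF modelling of sparse time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtfbayes)
```

## The problem

Biological time-series experiments are often sparse (a handful of time
points), weakly replicated (4–6 replicates per group), and highly variable
between replicates — think perfusion MRI after portal vein ligation, or
drug-concentration curves in small animal cohorts. Point-wise summaries
(boxplots per time point) discard the temporal structure, and with so few
observations per group, classical tests on derived quantities are fragile.

`rtfbayes` treats each experimental condition as noisy observations of a
smooth latent response curve, fits that curve in a Bayesian framework, and
reports uncertainty as a time-continuous credible band ("tube"). Conditions
are then compared as dynamics — where do their tubes separate? — rather
than as collections of points.

## The simulation model

The default latent curve is the retarded transient function (RTF), a
closed-form response model flexible enough for most single-peak or
saturating dynamics:

$$
f(t) \;=\; \underbrace{A_{sus}\,\big(1 - e^{-t/t_1}\big)}_{\text{sustained}}
\;+\; \underbrace{A_{trans}\,\big(1 - e^{-t/t_{11}}\big)\,
e^{-t/t_2}}_{\text{transient}} \;+\; p_0 ,
$$

evaluated on a transformed time axis

$$
t \;=\; \log_{10}\!\big(10^{\,10\,t_{real}/T_{range}} + 10^{T_{shift}}\big)
\;-\; \log_{10}\!\big(1 + 10^{T_{shift}}\big).
$$

The transformation delays the response smoothly while leaving $t = 0$
invariant. Two properties pin this parse down: $t(0) = 0$ exactly for every
$(T_{shift}, T_{range})$, and as $T_{shift} \to -\infty$ the transformation
degenerates to the linear rescaling $10\,t_{real}/T_{range}$ (an immediate
response). With this scaling the observation interval $[0, T_{range}]$ maps
approximately onto transformed time $[0, 10]$, so $T_{shift} = -2$
($10^{-2} \ll 1$) is already effectively immediate; that value is the
package default and `Tshift` is only estimated when explicitly requested.
$T_{range}$ is not estimated either: it is set to the observation-interval
range $\max(t) - \min(t)$ of each dataset unless overridden.

Parameter meanings and units:

| parameter | meaning | units |
|---|---|---|
| `Asus` | sustained amplitude (may be negative) | observable |
| `t1` | sustained timescale | transformed time |
| `Atrans` | transient amplitude | observable |
| `t11` | transient rise timescale | transformed time |
| `t2` | transient decay timescale | transformed time |
| `Tshift` | response delay (log10 axis) | dimensionless |
| `p0` | baseline, the exact value at $t=0$ | observable |
| `Trange` | fixed observation range | real time |

A mechanistic two-compartment pharmacokinetic model (`"pk2c"`, first-order
absorption and elimination with an analytic $k_a \to k_e$ limit branch) is
registered alongside the RTF, and arbitrary user models can be added via
`register_model()`: an evaluator mapping `(time grid, named parameters)` to
a trajectory is all the sampler needs.

## Error model, likelihood, priors

Measurements are modelled as the latent curve plus additive i.i.d. Gaussian
noise, $m^{(j)}(t_k) = f(t_k) + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$, with a single pooled $\sigma$ shared by
all time points and replicates of a dataset — noise is attributed to the
measurement process, not to time. The log-likelihood sums over time points
$k$ and replicates $j$; the model curve is evaluated once per distinct time
point and reused across replicates. $\sigma$ is estimated jointly with the
curve parameters by default (`estimate_sigma = FALSE` with `sigma_fixed`
switches this off).

Priors are uniform with wide, data-informed bounds. With
$\Delta = \max(m) - \min(m)$ and $R$ the observation range:

* amplitudes `Asus`, `Atrans`: uniform on $[-2\Delta, 2\Delta]$;
* baseline `p0`: uniform on $[\min(m) - \Delta,\, \max(m) + \Delta]$;
* timescales `t1`, `t11`, `t2`: log10-uniform on $[R/100,\, 10R]$;
* noise `sigma`: log10-uniform on $[\Delta/1000,\, 2\Delta]$.

Positive scale-spanning parameters are sampled on the log10 scale
(uniformly, so the scale's Jacobian is implicit); amplitudes and baseline on
the linear scale. Constant data ($\Delta = 0$) make these rules degenerate,
so `default_priors()` refuses them and asks for manual priors.

## Posterior sampling

The posterior is sampled with an adaptive Metropolis–Hastings algorithm
written for this package:

* Gaussian random-walk proposal; covariance refreshed every 50 iterations
  after an initial window of 500 from the full chain history
  (Haario-style $2.38^2/d \cdot \hat\Sigma + 10^{-10} I$), plus a
  Robbins–Monro global log-scale factor with decay $i^{-0.7}$ targeting the
  canonical acceptance rate 0.234;
* chains are initialized at the best of 200 finite-posterior prior draws,
  polished by a short derivative-free search (Nelder–Mead, or Brent in one
  dimension) from the five best scouts. The RTF posterior can have local
  optima (sustained/transient trade-offs), and multi-start initialization
  puts every chain in the global basin instead of hoping a random walk
  finds it;
* defaults: 2 chains of 50,000 iterations, the first 30% of each chain
  discarded as burn-in, no thinning (tube construction is percentile-based
  and tolerates autocorrelation; ESS is reported so users can judge);
* the seed is mandatory — identical `(seed, config, data)` reproduce the
  draw sequences bit for bit.

For multimodal targets, `parallel_tempering()` runs a ladder of chains
targeting $L^{1/T}$ with stochastic even/odd neighbour swaps each
iteration; only the cold chain contributes draws and swap acceptance rates
are logged. A single-temperature ladder reduces exactly to plain sampling.

Convergence diagnostics are computed per parameter: effective sample size
with Geyer's initial-positive-sequence truncation of the autocorrelation
sum, and the split Gelman–Rubin $\hat R$ across chains. $\hat R > 1.1$
produces a warning, never a hard failure — sparse-data posteriors with
pronounced parameter trade-offs mix slowly along ridges, and a warning plus
reported ESS is more honest than refusing the result.

## From posterior to data space

Every retained draw $\theta^{(i)}$ is pushed through the model on a dense
grid (default 201 points over the observation interval) to give an ensemble
of trajectories $s^{(i)}(t)$ — *without* measurement noise. At each grid
point the empirical $\alpha/2$, $0.5$ and $1-\alpha/2$ percentiles form the
$(1-\alpha)$ credible tube (default 95%); between grid points the bounds
are linearly interpolated. Percentiles use linear interpolation between
adjacent order statistics (the "type 7" convention, `stats::quantile`'s
default); a brute-force sort-based oracle test pins this convention so it
cannot drift silently.

The posterior predictive distribution is obtained by adding
$N(0, \sigma_i^2)$ noise per draw and grid point; its pointwise variance is
by construction at least the ensemble's, so the ensemble tube is a lower
bound for predictive variability. Tubes are computed on the noiseless
ensemble by default — they describe the model state, not future data — and
predictive tubes are available by piping `posterior_predictive()` output
into `credible_tube()`.

Condition comparison is deliberately descriptive: two conditions are
flagged "credibly different" at a time point when their tubes are disjoint
(the upper bound of one below the lower bound of the other), and the
fraction of the common grid with disjoint tubes summarizes each pair. No
significance threshold is imposed on that fraction — it is reported, not
auto-thresholded. Marginal posteriors are compared the same way through
95% highest-density intervals (shortest window over the sorted draws; ties
resolved towards the smallest lower bound).

## The synthetic-data generator

`generate_dataset()` realizes exactly the assumed data model — latent curve
plus i.i.d. Gaussian replicate noise — and returns the truth alongside the
data, so recovery and calibration studies need no external datasets. Two
study presets mirror common in-vivo designs: `"pvl-like"` (5 conditions
× 5 time points × 5 replicates; sustained decreases of 30–50% next to
transient increases on a baseline of ~100 perfusion units, σ* = 8) and
`"steatosis-like"` (3 conditions with 4/6/6 replicates over 8 time points
in 0–6 h; peak-and-elimination curves whose decay timescale grows with
condition severity, σ* = 0.08 concentration units).

What the generator does *not* emulate: inter-replicate random effects
(replicates are exchangeable draws around one condition-level curve, exactly
as the fitting model assumes), time-varying noise, and non-Gaussian error
tails. Passing recovery and calibration tests therefore demonstrates
internal consistency of the workflow — data generated under the model's
assumptions are recovered — not robustness to violations of those
assumptions. Negative synthetic values are kept by default; the
negative-value filter (`drop_negative`) is an acquisition-specific
preprocessing step (e.g. arterial-spin-labelling subtraction artefacts),
not part of the data model.

## Numerical choices

* Exponentials in the public model evaluators are clipped at $|x| \le 700$
  so extreme MCMC excursions yield finite values instead of overflow; in
  the precompiled likelihood path the transformed time is nonnegative and
  timescales positive, so exponents are nonpositive and plain `exp`
  suffices (underflow to 0 is the correct limit).
* The two logarithmic terms of the time transformation are computed with
  the same stable log-sum-exp rule, which makes $t(0) = 0$ exact in
  floating point, not merely close.
* Non-finite model output during sampling returns $-\infty$ (the proposal
  is rejected); it never raises.
* The proposal-covariance Cholesky update is skipped (previous factor kept)
  if the adapted matrix is numerically non-positive-definite.
* Out-of-bounds proposals are rejected before evaluating the model.

## Problem sizes used in the tests

The validation suite works at deliberately modest sizes chosen to exercise
every claim at desk scale: recovery uses 10 time points × 20 replicates at
2% relative noise with 2 × 50,000-iteration chains; tube calibration uses
100 datasets of 10 × 4 observations at 5% relative noise with single
25,000-iteration chains and 500-draw ensembles on a 21-point grid; unit
tests use chains of 500–20,000 iterations. The non-equidistant test grid
(densified at early times) reflects how such experiments are actually
designed — fast dynamics are sampled where they happen — and is what makes
a fast transient plus a slow sustained rise jointly identifiable from 10
points.

## Known limitations

* The RTF can represent one activation peak and no oscillations; multi-peak
  or oscillatory dynamics need a user-registered model.
* Tubes are percentile-based in data space; joint highest-posterior-density
  tubes are out of scope.
* A single pooled σ cannot represent time-varying measurement noise.
* With very sparse or weakly informative data the sustained and transient
  terms trade off; expect broad marginals, large $\hat R$ warnings, and
  consider fixing `Atrans = 0` (or `Asus = 0`) when one component is known
  to be absent.
* The quadratic likelihood regresses extreme replicates towards the centre;
  this is the intended noise-filtering behaviour, not robustness to
  adversarial outliers.
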
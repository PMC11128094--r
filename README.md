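# rtfbayes

Bayesian fitting of retarded transient functions (RTFs) to sparse, highly
variable biological time series, with uncertainty reported as
time-continuous credible-interval tubes.

## What problem this solves

Many in-vivo datasets — perfusion imaging after surgery, drug-concentration
curves in small cohorts — have 5–10 time points, 4–6 replicates, and large
replicate-to-replicate spread. Summarizing each time point separately wastes
the temporal structure and leaves conditions visually indistinguishable.
`rtfbayes` instead assumes the measurements of each condition scatter around
one smooth latent response curve,

$$
f(t) = A_{sus}\,(1 - e^{-t/t_1})
     + A_{trans}\,(1 - e^{-t/t_{11}})\,e^{-t/t_2} + p_0 ,
$$

an RTF: a saturating sustained term plus a rise-then-decay transient term on
a nonlinearly transformed time axis (delay parameter `Tshift`, fixed range
constant `Trange`). Measurements follow
$m^{(j)}(t_k) = f(t_k) + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$
with a single pooled noise SD per condition. Parameters (including
$\sigma$) get wide data-informed uniform priors and are sampled with an
adaptive Metropolis–Hastings algorithm (parallel tempering available for
multimodal posteriors). Posterior draws are pushed through the model on a
dense grid; pointwise 95% percentile intervals of those trajectories,
linearly interpolated, form the credible tube. Conditions are compared by
where their tubes are disjoint and by disjointness of marginal 95%
highest-density intervals.

A mechanistic two-compartment pharmacokinetic model is included as an
alternative curve (`model_id = "pk2c"`), and arbitrary models can be
plugged in via `register_model()`.

## Worked example

Simulate a pharmacokinetics-shaped study (3 conditions with 4/6/6
replicates over 8 time points; drug clearance slows with condition
severity), fit every condition, and compare them:

```r
library(rtfbayes)

study <- generate_study("steatosis-like", seed = 1)
fit <- rtf_fit(study$measurements, seed = 1, chain_length = 20000,
               n_chains = 2)
tidy(fit)
#> # A tibble: 21 × 10
#>   condition   observable parameter   median     mean      sd hdi_lower hdi_upper
#>   <chr>       <chr>      <chr>        <dbl>    <dbl>   <dbl>     <dbl>     <dbl>
#> 1 control     drug_conc… Asus       0.0535   0.0766   0.190    -0.324     0.514
#> 2 control     drug_conc… t1        12.3     18.8     19.0       0.0601   54.6
#> 3 control     drug_conc… Atrans     1.19     1.18     0.244     0.777     1.61
#> 4 control     drug_conc… t11        0.446    0.452    0.150     0.176     0.736
#> 5 control     drug_conc… t2         1.23     1.29     0.286     0.836     1.86
#> 6 control     drug_conc… p0         0.00885  0.00799  0.0444   -0.0769    0.0919
#> 7 control     drug_conc… sigma      0.0904   0.0917   0.0122    0.0711    0.118
#> ...
```

Per condition you get one posterior median and HDI per parameter: the
control condition is dominated by its transient term (`Atrans` ≈ 1.2 with
rise `t11` ≈ 0.45 h and decay `t2` ≈ 1.2 h), its baseline `p0` is
indistinguishable from zero, and the pooled noise SD is ≈ 0.09
concentration units. `glance(fit)` gives one row per condition with
acceptance rate, minimum ESS and maximum split-R̂.

```r
compare_fit(fit)$pairs
#> # A tibble: 3 × 3
#>   condition_a   condition_b   fraction_disjoint
#>   <chr>         <chr>                     <dbl>
#> 1 control       steatosis_2wk             0.299
#> 2 control       steatosis_4wk             0.970
#> 3 steatosis_2wk steatosis_4wk             0.970
```

`fraction_disjoint` is the share of the common time grid on which two
conditions' 95% tubes do not overlap: the severe condition's dynamics are
credibly different from both others over 97% of the observation window,
while the mild condition separates from control over only ~30% of it.
`autoplot(fit)` overlays the tubes on the data; `plot_marginals(fit, "t2")`
shows which conditions differ in clearance timescale.

The same workflow is scriptable from a shell via the thin CLI wrapper
(`inst/cli/rtfbayes`): `simulate`, `fit`, `predict`, `compare`.

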
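# trampler

Tools for quantifying how trail-side trampling disturbance affects alpine
plant communities. The package serves ecologists and land managers
analysing paired disturbed/undisturbed transect surveys along elevational
gradients: it estimates percent plant cover from quadrat photographs,
derives growth and area-standardised reproduction traits from per-plant
field records, and fits hierarchical Bayesian disturbance x elevation
models with a built-in MCMC sampler and a full model-checking toolkit. A
synthetic-survey generator with known ground truth makes every stage
testable without field data.

## The models at the core

Every response is modelled as

```
response ~ disturbance * elevation + (1 | transect pair)
```

with disturbance coded on-trail = 1 and elevation in metres. Size traits
(maximum height and diameter, rounded to integer cm) use a negative
binomial likelihood with log mean link and shape `phi`
(`Var(y) = mu + mu^2 / phi`); relative reproductive output
(`(buds + flowers + fruits) / (height x diameter)`, scaled by the species
maximum) and quadrat percent cover use a Beta likelihood with logit mean
link and precision `phi`. The transect-pair random intercept
`u_j ~ Normal(0, sigma^2)` absorbs the non-independence of the two
transects in a pair. An effect is inferred when a parameter's equal-tailed
95% credible interval excludes zero.

Percent cover comes from the photograph algorithm: boost each pixel's HSV
saturation by a factor of 30 (clipped at 1), classify a pixel as
vegetation iff its green digital number strictly exceeds both red and
blue, and report the fraction of qualifying pixels.

Posterior sampling uses an adaptive Metropolis-within-Gibbs kernel with a
learned joint proposal for the fixed effects, translation moves that
decorrelate fixed and random effects, and a funnel move for the
random-intercept scale. Diagnostics include split R-hat, bulk/tail ESS,
a Fisher-Pearson skewness posterior predictive check, and PSIS-LOO with
per-observation Pareto-k values.

## Worked example

Simulate a survey from the published-estimate presets and fit the
*V. ovalifolium* height model:

```r
library(trampler)

cfg    <- sim_config(seed = 1)           # 14 pairs x 10 quadrats
design <- make_design(cfg)
params <- table1_defaults()
plants <- simulate_traits(design, params, seed = 2)

fit <- plants |>
  dplyr::filter(species == "V_ovalifolium") |>
  dplyr::mutate(height = round_for_nb(height_cm)) |>
  fit_trample_model("height", family = "negbin", prepare = FALSE,
                    chains = 3, iter = 1500, warmup = 500, seed = 3)
tidy(fit)
#> # A tibble: 4 x 9
#>   term        estimate std.error conf.low conf.high  rhat ess_bulk effect
#> 1 (Intercept)  5.47e-1  2.56     -4.43     5.23      1.00     659. FALSE
#> 2 disturbance -4.43e+0  0.890    -6.19    -2.64      1.01     294. TRUE
#> 3 elevation    5.76e-3  0.00142   0.00315  0.00855   1.00     659. TRUE
#> 4 dist:elev   -9.42e-5  0.000491 -0.00109  0.000882  1.01     300. FALSE
```

The disturbance row's credible interval excludes zero: trampling reduces
height (`effect = TRUE`), and the posterior mean -4.43 sits next to the
preset's generative truth of -4.58 on the log scale. Raw-scale
`disturbance` is the contrast extrapolated to elevation 0 m; the
interpretable contrast at the mean survey elevation is sharper:

```r
disturbance_effect(fit)
#> # A tibble: 1 x 6
#>   elevation estimate     sd lower upper effect
#> 1     1809.    -4.60 0.0536 -4.70 -4.49 TRUE
```

Cover estimation from a simulated quadrat photograph:

```r
imgs <- simulate_cover_images(design, params, seed = 4)
estimate_cover(imgs$image[[1]], quadrat_id = imgs$quadrat_id[1])
#> # A tibble: 1 x 4
#>   quadrat_id green_fraction n_green n_total
#> 1 P01_U_01            0.999    4091    4096
```

An undisturbed quadrat at ~99.9% cover; `green_fraction` is the exact
pixel fraction. `run_pipeline(pipeline_config(mode = "simulate", seed =
1))` chains all stages — simulation, cover estimation, trait derivation,
twelve model fits, diagnostics — and emits a combined report table;
`autoplot()` methods display coefficient intervals, predictive checks and
classification masks.

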
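# popcode

Population coding and decoding of orientation at perceptual limits.

## What this package is for

When an orientation stimulus is barely visible, the errors people make in
reproducing it are not normally distributed: the error distribution grows
long tails near detection threshold and collapses toward uniform below it.
`popcode` implements a neural account of this phenomenon and the analysis
machinery around it, for researchers modelling trial-level psychophysical
estimation data:

* an idealized population of `M` Poisson-spiking neurons with Von Mises
  tuning (concentration κ), population gain γ (spikes/s), and a
  Naka–Rushton contrast response `g(c) = c^α / (c^α + σ_c^α)`;
* maximum a posteriori decoding: with no baseline activity the decoded
  orientation is the resultant direction of the spikes' preferred
  orientations, and the decoding error is the resultant angle of a Von
  Mises random walk with one step per spike;
* the **analytic error distribution**: a Poisson(ξ) mixture over the spike
  count `m` of conditional Von Mises densities VM(0, κr), marginalized over
  the random-walk resultant length r, plus an `exp(-ξ)/2π` guessing floor,
  where `ξ = γ T g(c)` is the expected spike count in the decode window;
* maximum-likelihood fitting of this five-parameter model
  (σ_c, α, γ, κ, β) to trial tables, plus two rival observer models (a
  seen/unseen threshold mixture and a two-stage normal-then-encode model),
  compared by AICc/BIC;
* 2AFC detection predictions: the 75%-correct threshold solves
  `g(c) = ln 2 / (γT)` in closed form for the no-baseline model, Monte
  Carlo otherwise;
* confidence analyses: posterior precision, total spike count as its
  computable proxy, median splits, and confidence–error correlations;
* a synthetic behavioral-data generator that emulates a contrast-varying
  orientation estimation study (8 subjects, 280–480 trials each, contrasts
  at 50–400% of each subject's detection threshold, 5-level confidence
  ratings), so the entire pipeline is testable without any data download.

See the vignette (`vignettes/population-coding.Rmd`) for the model,
numerical choices, and design decisions.

## A worked example

```r
library(popcode)

## generate a synthetic study and fit one subject
ds <- generate_dataset(synth_config(n_subjects = 2, seed = 42))
trials <- ds$trials[ds$trials$subject == 1, ]
set.seed(1)
fit <- fit_popcode(trials)
fit
#> popcode model fit (326 trials)
#>    sigma_c = 0.1568, alpha = 8.24, gamma = 279, kappa = 1.786, beta = -0.01917
#>   logLik = -282.54, k = 5, AICc = 575.26, BIC = 594.01, converged: TRUE

## ground truth for that subject
ds$truth[[1]]$params
#> Population coding parameters
#>   M = 100 neurons, gain gamma = 208 Hz, tuning kappa = 1.95
#>   contrast response: alpha = 51.4, sigma_c = 0.111
#>   bias beta = -0.0379 rad, window T = 0.1 s, baseline eta = 0 Hz

## is the population model a better account than a seen/unseen threshold
## model or a two-stage (normal perception + population code) model?
compare_models(list(fit, fit_threshold_model(trials), fit_two_stage(trials)))
#>       model k    logLik     aicc      bic delta_aicc delta_bic
#> 1   popcode 5 -282.5362 575.2600 594.0070   0.000000   0.00000
#> 2 threshold 6 -292.6848 597.6329 620.0909  22.372894  26.08397
#> 3 two_stage 7 -283.7861 581.9244 608.0805   6.664458  14.07355
```

The fit tracks the subject's generating parameters from 326 trials (gain
and tuning width trade off along a likelihood ridge, so single-subject
estimates scatter around the truth; the recovery tests characterize this
over 20 replicates of 1600 trials), and both rival models lose by AICc on
data the population model generated.

The analytic error density and its long-tail signature:

```r
ed <- error_density(xi = log(2), kappa = 2.4)   # threshold regime
circ_kurtosis_excess(ed$grid, w = ed$density)   # > 0: heavier than normal
#> [1] 0.3774367
plot(ed)
```

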
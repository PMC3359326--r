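# lookaway

Tools for asking when an observer stops attending to a stream of discrete
events, and whether that moment is governed by the information content of
what they are watching. The package targets infant looking-time paradigms:
an infant watches reveal events (an object appears from behind an occluder,
or not; one of three objects pops up) until they look away, and the working
hypothesis is that the per-event probability of looking away is **U-shaped
in surprisal** — both highly predictable and highly surprising events
promote disengagement, with a preferred ("Goldilocks") information rate at
the minimum of the U, empirically around 1.25 bits.

Because infant gaze data of this kind are not public, the package ships a
synthetic-infant generator alongside the analysis chain, so the entire
method is testable end to end and validated by parameter-recovery
simulation.

## The model

Events come from a finite alphabet of `K` symbols. An ideal learner with a
symmetric Dirichlet prior of strength `α` and observed counts `n_i` assigns
the next event the posterior-predictive probability

    p(next = i) = (n_i + α) / (N + K·α)

and the *complexity* of an observed event is its surprisal,
`−log2 p(event)`, in bits. A *marginal* variant treats events as
exchangeable; a *transitional* variant conditions each prediction on the
immediately preceding event (first-order Markov). Look-away timing is
analyzed as discrete-time survival: each retained trial is expanded into
counting-process rows (one per at-risk event), a Cox proportional-hazards
regression with forward AIC covariate selection tests linear and squared
standardized complexity against control covariates, and a binomial-link GAM
of look-away on complexity and sequence position locates the
hazard-minimizing complexity.

## Worked example

Simulate a three-box cohort of 30 infants, apply the standard exclusions,
and run the analysis:

```r
library(lookaway)

design  <- generate_exp2_session(seed = 1)                   # 32 trials
records <- simulate_cohort(design, n_infants = 30,
                           mode = "marginal", seed = 2)
rows    <- event_table(records, design = design)             # exclusions + covariates

exclusion_report(rows)
#> # A tibble: 4 × 3
#>   category           n fraction
#>   <chr>          <int>    <dbl>
#> 1 retained         576  0.6
#> 2 timeout            4  0.00417
#> 3 false_stop       174  0.181
#> 4 too_few_events   206  0.215

stepwise_aic_cox(rows, default_candidates(2))
#> <lookaway_cox> 4881 at-risk events, 576 look-aways, AIC 5495.6
#> # A tibble: 5 × 6
#>   term              estimate exp_estimate std.error statistic  p.value
#>   <chr>                <dbl>        <dbl>     <dbl>     <dbl>    <dbl>
#> 1 first_appearance    1.98          7.23    0.237        8.35 6.63e-17
#> 2 posterior_entropy  -0.690         0.501   0.161       -4.28 1.84e- 5
#> 3 z_complexity        0.127         1.14    0.0809       1.57 1.16e- 1
#> 4 trial_number        0.0107        1.01    0.00470      2.27 2.32e- 2
#> 5 z_complexity_sq     0.0428        1.04    0.0307       1.39 1.64e- 1

fit_ushape(rows)
#> <lookaway_ushape> 3153 events, 576 look-aways
#>   complexity partial-effect minimum at 1.278 bits (interior), edf 4.39
```

Reading the output: about a fifth of simulated trials are lost to tracker
false stops and a fifth to the fewer-than-four-events rule, as in real
sessions of this paradigm. The stepwise Cox fit retains first appearance,
model uncertainty, complexity terms and fatigue (AIC-based selection keeps
weakly informative covariates without individual significance — expected
behavior). The smooth fit places the hazard-minimizing complexity at 1.28
bits, an interior minimum close to the generator's 1.25-bit optimum.

`autoplot(fit_ushape(rows), bins = bin_lookaway(rows))` draws the standard
figure: smooth curve, standard-error band, binned raw probabilities and a
data rug. `run_pipeline(run_config(...), out_dir = "out")` runs every stage
from one seeded config and writes CSV/JSON artifacts plus a manifest;
`recovery_experiment()` is the simulate-and-refit harness (bias, RMSE,
coverage, sign agreement).

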
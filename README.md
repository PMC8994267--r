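# movescape

Carnivores moving through mountain valleys respond to towns, roads, and
trails twice over: development changes *where* they go (habitat selection)
and *how* they move (behavioural state). movescape is an R package for
quantifying both effects and their consequences for landscape connectivity.
It is written for movement ecologists and connectivity analysts who have
GPS telemetry, raster covariates, and development scenarios, and want a
tested, reproducible chain from fixes to connectivity numbers — and for
methodologists who want every stage of that chain checkable against ground
truth.

The pipeline has four stages:

1. **Movement states.** A two-state hidden Markov model on step lengths and
   turn angles: ℓₜ ~ Gamma(μₛ, σₛ), θₜ ~ von Mises(mₛ, κₛ), with
   covariate-dependent transitions
   logit γ_slow→fast(x) = β₀ + β₁ cos(2πh/24) + β₂ d_town + β₃ ρ_trail
   (and a second row for fast→slow). Competing distance-to-town transforms
   (linear or exponential decay, 500 m–5 km ranges) are compared by AIC.
   Forward–backward smoothing yields p_Fast, the posterior probability of
   the fast (travelling) state at each step.
2. **Step selection.** Each observed step is paired with 20 available steps
   drawn from the pooled empirical step-length/turn-angle distributions, and
   a conditional logistic regression (softmax over the 21 candidates per
   stratum) estimates selection for endpoint covariates, on/off linear
   features (30 m buffer), and movement terms, each interacted with p_Fast
   and time of day. Variances are cluster-robust over animals (GEE-style
   sandwich); backward selection uses QIC. Effects are summarised as
   relative selection strength, RSS = exp(βᵀ(x₁ − x₀)).
3. **Path simulation.** An individual-based simulator replays the fitted
   models: at each 2-h step it samples 20 candidate states/steps from the
   movement model, rejects candidates that touch unavailable habitat
   (barren slopes > 35°, towns) at four points along the step, and picks one
   survivor by softmax on the SSF score. Scenarios: *reference* (all
   anthropogenic coefficients zeroed, development footprint restored),
   *current* (as fitted), *future* (expanded town footprint + informal
   trails).
4. **Habitat use and Merriam connectivity.** Path ensembles become
   utilization distributions on the 120 m grid, ten equal-area habitat bins
   (rank ≥ 7 = high quality, validated against GPS locations by Spearman
   rank correlation), percent intact habitat relative to reference, and
   connectivity ratios n_traverse/n_reference from unique-path patch
   traversals and cross-valley transect crossings.

A synthetic valley generator (`generate_landscape()`,
`generate_labelled_tracks()`) produces landscapes and ground-truth-labelled
tracks from known parameters, so every estimator in the chain is tested by
parameter recovery rather than by fiat.

## Worked example

```r
library(movescape)

# a synthetic valley: two towns, road/rail/trail network, steep barren flanks
land <- generate_landscape(list(n_rows = 120, n_cols = 200), seed = 1)

# ground-truth tracks from known movement + selection parameters
tracks <- generate_labelled_tracks(land$stack, land$scene,
                                   default_true_hmm(), default_true_ssf(),
                                   n_animals = 10, n_steps = 400, seed = 2)

# movement model
steps <- build_steps(tracks, land$stack)
#> 52 step length(s) floored at 1 m
hmm <- fit_hmm(steps, seed = 3)
hmm$params
#> <hmm_params> slow/fast gamma mean: 46.8 470.7  sd: 46.1 376.1
#>   kappa: 0.635 2.331  mean angle: -0.038 0.001
#>   transition coefficients:
#>              (Intercept)  c_hour  d_town trail_density
#> slow_to_fast     -0.7990  0.8806 -1.3762        1.2379
#> fast_to_slow     -1.2279 -0.8264  1.1064       -0.8035
```

The slow state (feeding/resting) makes ~50 m steps between 2-h fixes, the
fast state (travelling) ~500 m steps with more directional persistence
(κ ≈ 2.3). The negative `d_town` coefficient on slow→fast says animals are
more likely to switch into fast movement close to town; positive
`trail_density` says the same for trail-dense areas. The generating values
were 50/500 m, κ = 0.5/2, and ±1 for every transition coefficient — all
recovered to the precision ten short tracks allow.

```r
# step selection with state interactions
steps <- smoothed_state_probs(steps, hmm)
strata <- sample_available_steps(steps, land$stack, seed = 4)
ssf <- fit_conditional_logit(assemble_design(strata, land$stack, land$scene,
                                             ssf_design()))
tidy(ssf)          # broom-style coefficients with cluster-robust SEs
#> # A tibble: 25 x 5
#>   term             estimate std.error statistic  p.value
#> 1 habitat           2.93        0.817    3.58   0.000341
#> 2 town_prox        -5.74        2.12    -2.71   0.00672
#> 3 trail_density    -0.157       0.433   -0.364  0.716
#> 4 trail_density_sq -0.00465     0.338   -0.0138 0.989
#> 5 on_trail          0.478       0.655    0.730  0.465
#> # 20 more rows

relative_selection_strength(ssf, c(town_prox = 1), c(town_prox = 0))
#>       rss  conf.low conf.high log_rss se_log
#> 1 0.00321 0.0000507     0.204   -5.74   2.12
```

A cell at the town edge (`town_prox` = 1) is selected about 300 times less
than an otherwise identical cell far from town — avoidance in the slow
state, since the interactions hold `p_fast` at zero here.

```r

# simulate scenarios and summarise connectivity
cfg <- sim_config(n_paths = 400, days = 60, seed = 5)
bundle <- scenario_bundle(land$stack, land$scene, ssf, hmm, ssf_design(),
                          scenario = "current", config = cfg)
ens <- simulate_ensemble(bundle)
ud <- utilization_distribution(ens, land$stack, clip_buffer_m = 2500)
bins <- equal_area_bins(ud, mask = land$stack$mask)
spearman_validation(bins, tracks, land$stack)   # model fit vs GPS locations
transect_crossing_count(ens, land$scene$transects[[1]])
```

`run_pipeline(config)` chains all stages (landscape → HMM → SSF →
scenario ensembles → summaries) with every random draw derived from one
master seed, writing per-stage artifacts and a manifest so reruns are
byte-identical.

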
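---
title: "Movement states, step selection, and simulated connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement states, step selection, and simulated connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(movescape)
```

movescape chains three models that are usually fitted and used separately:
a two-state hidden Markov movement model (HMM) for GPS telemetry, a
state-interacted step selection function (SSF), and an individual-based path
simulator that feeds utilization-distribution and Merriam-connectivity
summaries. This vignette explains the models, the conventions and numerical
choices behind the implementation, and what the synthetic landscape can and
cannot tell you about real data.

## The movement model

Steps are built from regularised 2-h GPS fixes: step length $\ell_t$ is the
Euclidean distance between consecutive fixes and the turn angle $\theta_t$ is
the signed change in bearing, wrapped into $(-\pi, \pi]$. A two-state HMM
emits $\ell_t \sim \mathrm{Gamma}(\mu_s, \sigma_s)$ (mean/sd
parameterisation) and $\theta_t \sim \mathrm{vonMises}(m_s, \kappa_s)$, with
state 1 the slow (foraging/resting) and state 2 the fast
(travelling/hunting) state; $\mu_\mathrm{fast} > \mu_\mathrm{slow}$ is the
identifiability convention, enforced by relabelling after the fit.

Transitions are logit-linear in covariates at each step's start:

$$\mathrm{logit}\, \gamma_{s\to s'}(x_t) = \beta_{0} + \beta_1 \cos(2\pi h_t/24)
  + \beta_2\, d_\mathrm{town}(x_t) + \beta_3\, \rho_\mathrm{trail}(x_t),$$

one row of coefficients per direction (slow to fast, fast to slow). The
time-of-day covariate is the cosine of the hour, so midnight maps to $+1$
and noon to $-1$. The town covariate is a *capped-linear distance*
$\min(d, r)/r$ (default range 5 km), so a negative slow-to-fast coefficient
means animals switch to fast movement *near* town; the competing transforms
(exponential decay, other ranges between 500 m and 5 km) are compared by
AIC in `decay_model_selection()`. Trail-road density is the total length of
trails and roads within 500 m of a point divided by the circle area
(km/km²), computed by exact circle-segment clipping.

The likelihood is the scaled forward recursion with per-step transition
matrices; each track (and each contiguous run of 2-h fixes within a track —
gaps longer than 2 h ± 15 min split a track into independent segments)
contributes an independent block whose initial distribution is the
stationary distribution of $\Gamma(x_1)$. This replaces a free initial
distribution: with two states and geometric memory, the information about
$\delta$ in one step is negligible and the constraint removes two
parameters. The first turn angle of a segment is undefined and contributes
its length density only. Zero step lengths (stationary GPS jitter) are
floored at 1 m so the gamma density stays finite; the count of floored
steps is reported.

Optimisation is BFGS on a working scale ($\log \mu$, $\log \sigma$,
$\log \kappa$, unconstrained mean angles and transition coefficients). The
first start is data-informed (gamma moments of the steps below/above the
median length split); additional seeded random restarts (default
`n_restarts = 3`) jitter that start. In recovery experiments the informed
start converges to the global optimum essentially always, which is why the
default restart count is small; raise it for ill-separated states.
Covariances come from the inverted numerical Hessian of the working-scale
likelihood; a non-invertible Hessian flags the covariance as unavailable
rather than failing silently. `smoothed_state_probs()` runs the
forward-backward recursion and appends `p_fast`, the posterior probability
of the fast state, to the step series.

## The step selection function

For every observed step with a defined prior bearing, 20 available steps
are drawn with replacement from the *pooled* empirical distributions of
observed lengths and turn angles, projected from the step's start along the
prior bearing. Available steps inherit the used step's `p_fast` and
`c_hour`: the behavioural state and the time of day belong to the decision
moment, not to the candidate endpoint. Endpoints falling outside the grid
are redrawn up to 10 times, then the stratum is dropped (counted and
reported).

The design matrix holds endpoint covariates (habitat quality, exponential
town proximity with a 500 m range — 1 at the town edge, decaying outward —
trail-road density and its square), on/off indicators for being within
30 m of a trail, road, or railway, movement terms (step length in km,
cosine of the turn angle), and interactions of the anthropogenic and
movement terms with `p_fast` and `c_hour`. Under this orientation a
negative town-proximity coefficient means avoidance near town, and a
positive `town_prox:p_fast` interaction means that avoidance relaxes when
travelling.

The conditional logistic likelihood is the softmax over each stratum's 21
candidates; `fit_conditional_logit()` maximises it by Newton iterations to
a gradient norm below $10^{-8}$, damping steps larger than 10 on the
coefficient scale and flagging divergence (complete separation) instead of
returning a silent "fit". Covariates constant within every stratum carry no
information; their coefficients are pinned at zero and flagged `aliased`.
The cluster-robust covariance is the sandwich $A^{-1} M A^{-1}$, with $A$
the observed information and $M$ the outer-product sum of per-animal score
totals — the GEE-style correction for the serial dependence of steps within
an animal. Model selection uses
$\mathrm{QIC} = -2Q + 2\,\mathrm{tr}(A V_\mathrm{robust})$ with $Q$ the
independence-model conditional log-likelihood; the published sources that
name this criterion do not print a formula, so the package fixes this
standard form. Backward selection removes the single term whose removal
most lowers QIC, never removing a main effect while its interaction or
quadratic remains, and stops at a local minimum.

## Path simulation and scenarios

Each simulated path starts in the top third of the SSF prediction surface
(`predict_habitat_map()` with movement terms excluded; ties at the tertile
broken by row-major cell index so the mask is deterministic) at a uniform
fix time. Every 2-h step then:

1. computes the transition row at the current location and hour and samples
   20 candidate states from it;
2. draws each candidate's length and turn from its state's gamma/von Mises
   laws, projecting endpoints from the current bearing;
3. rejects candidates whose segment touches unavailable habitat at
   fractions 0.25, 0.5, 0.75, 1.0 of the step (the origin is known
   available; the endpoint is included);
4. selects one survivor by softmax on the SSF linear predictor, using the
   candidate's binary state in place of `p_fast` in the interactions (the
   smoothed probability exists only for fitted data; in simulation the
   state is known exactly);
5. advances, accumulating the proportion of proposed endpoints that fell
   outside the study area; the path terminates when that running proportion
   exceeds 0.40 (`boundary_rule = "cumulative"`; a per-step variant is a
   config switch, since "more than 40% of proposed steps" is ambiguous
   between the two readings).

If all 20 candidates are rejected the set is redrawn up to 5 times; after
that the animal holds its position for that fix (state still resampled) and
a path held more than 10 consecutive fixes terminates as "stuck". Both
counts are reported per ensemble so the frequency of this fallback is
auditable; on the synthetic valley it is rare.

Scenarios: *reference* zeroes every anthropogenic SSF term (and its
interactions) and the anthropogenic transition coefficients, and restores
developed cells to available habitat — simulated movement with the same
movement physiology but no development response. *Current* uses the fitted
coefficients and layers unchanged. *Future* applies
`apply_future_development()`: an expanded town footprint becomes
unavailable, informal trails are merged into the formal network (duplicate
segments de-duplicated) and the density layers recomputed; green spaces
stay available. Unavailable habitat elsewhere is barren/ice terrain steeper
than 35 degrees.

All randomness descends from one master seed through named substreams
(`derive_seed(master, name)`), with one substream per path, so ensembles
are bit-reproducible and scenario pairs can share start points.

## Habitat use, validation, and connectivity

Utilization distributions count simulated locations per 120 m cell after
clipping a 5 km edge buffer (2.5 km on the smaller synthetic valley), then
normalise. Ten equal-area bins partition the available cells by UD value
(ties by row-major index; bin sizes equal within one cell); bin rank at
least 7 defines high-quality habitat, and percent intact habitat is the
scenario's high-quality proportion inside the focal polygon divided by the
reference proportion. Validation is the Spearman correlation between bin
rank and the proportion of GPS locations per bin, pooled and per animal.

Merriam connectivity counts *unique* paths: a patch traversal requires at
least one location in each of the two patches (either order, no time
constraint); a transect crossing is a geometric intersection of any step
segment with the transect polyline (endpoint touches count; crossing is
decided by exact segment intersection rather than cell bookkeeping, which
matters at 120 m resolution). Ratios divide scenario counts by reference
counts; fewer than ten reference paths flag the ratio as unreliable, and a
zero reference leaves it undefined.

## The synthetic valley

`generate_landscape()` builds the study system the models are exercised on:
an east-west valley with flat floor and 42-degree barren flanks (so the
slope/landcover unavailability rule bites), two rectangular towns on the
floor, a meandering road, a parallel railway, a main trail plus
`trail_intensity` random spurs, and a habitat-quality field that is a
Gaussian random field (correlation length 6 cells) plus a valley-bottom
bonus. Habitat patches sit at the valley's two ends, cross-valley transects
pass through each town, and the focal polygon spans the inter-town
corridor. `generate_labelled_tracks()` drives the simulator with *known*
parameters and keeps the hidden state, so every fitting stage has ground
truth.

Default ground truth: slow state 50 m mean steps (sd 50 m, kappa 0.5), fast
state 500 m (sd 400 m, kappa 2) — magnitudes typical of 2-h carnivore
telemetry; transition coefficients of unit magnitude on `c_hour`, town
distance, and trail density; selection for habitat and against town
proximity and trail density, relaxed in the fast state. These defaults are
the package's study conditions and are not tuned per experiment.

What the generator does *not* emulate: missing fixes and location error,
inter-individual heterogeneity (one parameter set for all animals),
home-range attraction or memory, real covariate structure (13 correlated
remote-sensing layers reduce here to one habitat field plus the
anthropogenic layers), and seasonal parameter shifts. Passing recovery
tests therefore demonstrate that the estimators are correct for the model
they claim to fit — not that the model is adequate for any particular
dataset.

## Problem sizes and numerical choices

The test-suite and acceptance-script sizes are chosen as the smallest
designs whose Monte-Carlo error is well below each tolerance: emission
recovery uses 100 tracks of 720 steps (72,000 steps; relative errors well
under the 5% bound), transition-coefficient coverage uses 20 replicates of
20 tracks, conditional-logit calibration uses 2,000 strata and 200
replicates, and scenario ensembles use 400-1,000 paths of 720 steps —
against 200,000 paths in a full-scale application, which changes Monte-Carlo
noise but nothing structural. Likelihood recursions and the step-by-step
simulator are implemented in C++ (Rcpp) with all draws routed through R's
RNG; the forward recursion is scaled per step, the von Mises normaliser
uses the exponentially scaled Bessel function so large concentrations stay
finite, and gamma densities floor lengths at 1 m as described.

Known limitations: two states only; gamma/von Mises emissions only; the
two-stage design (HMM then SSF with plug-in `p_fast`) propagates no state
uncertainty into the selection fit; no random or individual coefficients;
QIC selection is greedy and can stop at a local minimum; bins are
cell-count (not area) weighted where the focal polygon cuts cells; the CRS
is a tag, with all computation in projected metres.
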
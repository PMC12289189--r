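---
title: "Movement HMMs for 3-D search flights: models and methods"
author: "flightHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement HMMs for 3-D search flights: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific problem

When a territorial hummingbird returns to a flower it has emptied and
finds the flower gone, its flight around the former location is a
read-out of its spatial memory. Stereo video of such test flights gives
a time-regular sequence of 3-D head positions (one per frame, in cm).
This package models those tracks with a two-state hidden Markov model
(HMM) to separate two behavioural modes -- fast, directed **Travel**
and slow, sinuous **Search** -- and to ask how the odds of switching
between them depend on the bird's current distance to the flower's
former location and on the presence of nearby visual landmarks.

## Observation streams

Each movement step (frame $t$ to $t+1$) contributes a three-component
observation $z_t$:

* **step length** $s_t = \lVert p_{t+1} - p_t \rVert$ (cm/frame);
* **yaw** $\psi_t$: the wrapped change in heading azimuth
  ($\mathrm{atan2}(\Delta y, \Delta x)$) between consecutive steps;
* **pitch** $\phi_t$: the wrapped change in heading elevation
  ($\arcsin(\Delta z / s_t)$) between consecutive steps.

The yaw/pitch decomposition extends the planar step-and-turn
representation of terrestrial movement HMMs to flight in a volume.
Pitch is defined as the *change* in elevation (the vertical analogue of
yaw), which gives a zero-mean stream compatible with fixing the angular
means at zero; the alternative reading (the absolute elevation of each
step) is available via `derive_movement_series(pitch_type =
"elevation")`. Digitised positions produce exact zeros when the bird
hovers; a zero step leaves the heading undefined, so the heading is
carried forward and any angle bounded by a zero-length step is treated
as missing (its likelihood factor is 1). Zeros themselves are carried
by a point mass in the step distribution, with no tolerance band: a
0.3 cm step is a genuine small movement, not a zero.

Two per-step covariates accompany $z_t$: the distance (in metres --
positions are cm, the conversion is explicit) from the step's
*starting* position to the flower's former location, and a 0/1
landmark indicator. Using the position at the start of the step means
the covariate acting on the transition into the state occupied during
step $t$ is information available before the move; at ~30 frames per
second the off-by-one alternatives are practically indistinguishable.
The frame interval (default NTSC video, 1/29.97 s) never enters the
model -- all quantities are per frame -- and only matters when
reporting speeds in physical units.

## State-dependent distributions

Conditional on the state, the three streams are independent
("contemporaneous conditional independence"):

* step length: gamma with state-specific mean $\mu$ and standard
  deviation $\sigma$ (shape $\mu^2/\sigma^2$, scale $\sigma^2/\mu$)
  plus a state-specific probability mass $\pi_0$ at exactly zero;
* yaw and pitch: wrapped Cauchy with concentration $\rho \in [0, 1)$
  and mean direction fixed at 0 by default ($\rho = 0$ is the circular
  uniform). Models estimating the angular means are available
  (`hmm_spec(yaw_mean_estimated = TRUE)`) and can be compared by AIC.

## Transition model and likelihood

Transition probabilities follow a multinomial logit with the diagonal
as reference category:
$$\ln\frac{\gamma_{ij}(t)}{\gamma_{ii}(t)} =
\beta_0^{ij} + \beta_1^{ij}\,\mathrm{Distance}_t +
\beta_2^{ij}\,\mathrm{Landmark} +
\beta_3^{ij}\,\mathrm{Distance}_t\,\mathrm{Landmark},$$
with absent covariates dropped and the landmark-absent condition
absorbed into the intercept. A landmark effect on the log of the
state-dependent step mean, $\ln \mu_{\mathrm{step},i} = b_{0,i} +
b_{1,i}\,\mathrm{Landmark}$, is the other supported covariate route
(per-state coefficients with a log link). The likelihood is the matrix
product
$$L = \delta P(z_1) \prod_{t=2}^{T} \Gamma_t P(z_t) \mathbf{1}',$$
evaluated by a scaled forward recursion (per-step normalisation with
accumulated log scale factors, rather than per-entry log-sum-exp; the
recursion is oracle-tested against exhaustive path enumeration). Birds
are fitted jointly -- one parameter set, log-likelihoods summed across
tracks, no random effects. The initial distribution $\delta$ is
estimated as free working parameters shared across tracks: with
covariate-dependent $\Gamma_t$ there is no canonical stationary start.

## Estimation and numerics

Fitting maximises the likelihood by BFGS on an unconstrained working
scale: log for positive parameters, logit for probabilities and
concentrations (clamped to $[10^{-8}, 1 - 10^{-8}]$ at the boundary;
concentrations additionally kept below 1 by $10^{-12}$ because the
logistic saturates in floating point), $\tan(\mu/2)$ for circular
means. The default is 10 restarts (a moment-based, data-driven start
plus seeded Gaussian perturbations, SD 0.4 on the working scale); all
restart log-likelihoods are recorded so multimodality is visible.
Replicated simulation experiments in the test suite use 1--2 restarts,
which the moment-based start makes sufficient there. A known failure
mode of gamma mixtures -- a state collapsing onto a zero-width spike
over the smallest steps -- is a genuine local optimum; the moment-based
start and restarts are the remedy, and the restart table exposes it.
After fitting, states are relabelled so state 1 is the faster state
(Travel). Uncertainty comes from the inverse numerical Hessian
(central differences, working scale); a singular Hessian degrades to
`se_ok = FALSE` rather than failing. An infeasible point during a line
search (overflowed exponential, zero total density) is given a large
finite objective value so the optimiser backs off. `AIC = -2\ell + 2k`
with $k$ the number of free working parameters; model ranking uses AIC
weights (AIC, not AICc, for the HMM comparison). Candidates must share
the data (checked by fingerprint).

Decoding uses the Viterbi dynamic program in log space (ties broken
toward the lower state index) and forward--backward smoothing for
per-time state probabilities; both are oracle-tested by enumeration.
Forecast (one-step-ahead) pseudo-residuals map each observation's
predictive CDF value -- the predictive-weight mixture of state
marginal CDFs -- through the standard normal quantile; the zero-step
atom uses seeded randomised quantile residuals, and CDF values are
clamped to $[10^{-12}, 1-10^{-12}]$. Forecast rather than ordinary
pseudo-residuals were chosen because they are well defined under the
covariate-dependent transition matrices and serially independent under
a correct model.

## Stationary curves and the crossover distance

At a fixed covariate value the transition matrix has a stationary
distribution; for two states $\pi_{\mathrm{Search}} =
\gamma_{TS}/(\gamma_{TS} + \gamma_{ST})$ (general case: left
eigenvector, with an error if the chain has no unique stationary law).
The **crossover distance** is the root of $\pi_{\mathrm{Search}}(d) -
1/2$, found by bracketing on a 512-point grid plus bisection to
$10^{-9}$ m; a curve that never reaches 1/2 is reported as "no
crossover" -- the expected signature when landmarks are removed and
switching no longer depends on distance. The confidence interval is a
parametric bootstrap: working-parameter draws from the asymptotic
normal, root recomputed per draw, percentile limits; the fraction of
draws without a crossing is reported alongside.

## The synthetic-track generator

`simulate_tracks()` generates the study conditions the analysis
assumes, with ground truth for every test: 14 birds per experiment and
mean steps per bird of 191, 131 and 125 (matching datasets of 2679,
1830 and 1748 locations across 14 birds in the three experiments);
landmark present for every bird in experiment 1 and for half (7/7) in
experiments 2--3. Default state phenotypes are fixtures chosen for
biological plausibility, not published values: Travel at 7 cm/frame
(about 2.1 m/s at 29.97 fps, SD 3, zero mass 0.15 -- brief hovers
occur even in transit) versus Search at 1.5 cm/frame (SD 1.2, zero
mass 0.30 -- hover-rich searching); yaw concentration 0.85 vs 0.40
(directed vs sinuous); pitch concentration 0.95 vs 0.85, tighter than
yaw because up-down turning is mechanically more constrained than
side-to-side. Transition truth for experiment 1 is
$\eta_{TS} = 0.5 - 1.5 d$, $\eta_{ST} = -2 + 0.8 d$, making Search
favoured near the flower with a 50% crossover at $2.5/2.3 \approx
1.09$ m; experiments 2--3 use a distance-by-landmark interaction in
which landmark-present birds keep that structure and landmark-removed
birds switch at the same rate at all distances (flat Search
probability ≈ 0.37). The zero masses are deliberately not tiny so that
a single study-scale fit estimates them with useful precision.

Geometry: the distance covariate is *endogenous* -- recomputed from
the simulated position each step, exactly as the analysis derives it
from real tracks. Start positions lie in a radial band (default
0.3--1.5 m) around the flower and the initial heading points at the
flower with wrapped Cauchy noise, emulating a memory-guided return;
without some goal-directedness a random walk rarely samples the
near-flower region that identifies the distance effect. Pitch draws
that would carry the heading past vertical are rejected and redrawn,
keeping elevation in $[-\pi/2, \pi/2]$ so that the spherical heading
is canonical; the recorded ground-truth streams are exactly the
accepted draws, which makes
`derive_movement_series(simulate_tracks(cfg))` reproduce the recorded
step/yaw/pitch streams to numerical precision (the round-trip
property). The rejection slightly truncates the far tails of the pitch
distribution relative to a pure wrapped Cauchy -- one reason the
default pitch concentrations are high -- so fitter-calibration
experiments use `simulate_series()`, the exogenous mode: emissions
drawn directly from the model with the distance covariate following a
reflected random walk on 0--3 m. The geometric generator does not
emulate digitisation noise, camera-volume occlusion, or the feeding
and training phases of the field protocol; per-bird track-length
variability in the real data is unknown (only totals are printed), so
dispersion is a free negative-binomial knob.

## Analysis pipeline

`run_experiment()` mirrors a per-experiment analysis: fit every
candidate covariate structure (default lattice per experiment:
experiment 1 compares `~1` and `~distance`; experiments 2--3 add
landmark main effects, the transition interaction and a step-mean
landmark effect), rank by AIC weight, decode with the best model,
compute stationary curves and crossovers per landmark condition, bin
Viterbi-Search points into 5 cm square cells anchored at the flower
("5 cm diameter squares" is read as 5 cm side length; the plan view is
the natural projection since landmarks and flower are horizontal
features) counting *distinct birds* per cell, compute stop and fly-by
metrics (a stop is a maximal run of steps under 1 cm, its location the
segment's mean position -- robust to sub-centimetre jitter; the
fly-by uses sampled positions, not interpolated segments), and run
pseudo-residual diagnostics. Reports are deterministic given the seed
and serialise to JSON. A candidate that fails to fit is recorded and
skipped; only failure of every candidate is fatal. Mixed-model
(GLMM) comparison of the stop/fly-by metrics across experiments is
out of scope here: the metrics are computed, their population-level
regression belongs to standard mixed-model tooling.

## What passing tests do and do not show

The validation suite works at the study's scale: likelihood, Viterbi
and smoothing oracles on 200 short random instances (exhaustive
enumeration); quadrature checks of both emission families; parameter
recovery and Wald-interval coverage over 50 replicates of 14 birds ×
~191 steps; AIC-weight selection over 30 replicates each for an
interaction truth and a covariate-free truth; crossover recovery on a
symmetric construction (analytic root at 1 m) and bootstrap-interval
coverage over 50 fits; pseudo-residual calibration at $T = 10^4$; and
an end-to-end synthetic landmark-removal experiment that must show a
finite crossover with landmarks and none without. These establish that
the estimator, decoder and diagnostics are correct *under the model*.
They do not show that real hummingbird flights follow zero-inflated
gamma/wrapped Cauchy emissions, that two states suffice, or that
digitisation noise is ignorable -- those are modelling judgements
carried over from the study design.

## Known limitations

* Two states are assumed throughout; the machinery accepts general
  `n_states` but model counts beyond two are unexplored here.
* No random effects: one parameter set across birds within an
  experiment.
* The wrapped Cauchy mean, when estimated, uses a $\tan(\mu/2)$
  working scale that cannot represent a mean of exactly $\pi$.
* The bootstrap CI for the crossover conditions on the Hessian-based
  normal approximation; it is unavailable when the Hessian is
  singular.
* Whether yaw and pitch should be derived from displacement vectors or
  from digitised head orientation is a data-collection question the
  package cannot settle; displacement-derived angles are assumed.
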
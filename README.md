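# flightHMM

Hidden Markov models for three-dimensional animal flight trajectories,
built for a recurring question in movement ecology and spatial
cognition: when a bird returns to a remembered food location and finds
it empty, **where and how does it search**, and what visual information
controls the switch from travelling to searching?

The package targets time-regular 3-D tracks (x, y, z per video frame,
in cm) of individual birds — e.g. stereo-video reconstructions of
hummingbirds revisiting the former location of a flower — and provides:

* **Observation streams**: per step, a 3-D step length, a yaw angle
  (side-to-side turning) and a pitch angle (up-down turning), plus the
  distance to the goal location (m) and a landmark indicator as
  covariates (`derive_movement_series()`).
* **A two-state multivariate HMM**: zero-inflated gamma step lengths
  (gamma plus a point mass for exact hovering zeros) and wrapped Cauchy
  angles, conditionally independent given the state; covariates act on
  the transition probabilities through a multinomial logit link

  ```
  ln(γ_ij(t)/γ_ii(t)) = β0_ij + β1_ij·Distance_t + β2_ij·Landmark + β3_ij·Distance_t·Landmark
  ```

  and optionally on the log of the state-dependent step mean. The
  likelihood `L = δ P(z1) ∏ Γ_t P(z_t) 1'` is evaluated by a scaled
  forward recursion (C++), maximised jointly across birds
  (`fit_hmm()`).
* **Decoding and assessment**: Viterbi state sequences, forward–
  backward state probabilities, forecast pseudo-residuals with
  randomised quantile handling of the zero mass, and AIC-weight model
  comparison (`viterbi()`, `state_probabilities()`,
  `pseudo_residuals()`, `aic_weights()`).
* **Behavioural read-outs**: stationary Search-probability curves and
  the 50% **crossover distance** with parametric-bootstrap CIs
  (`stationary_curve()`, `crossover_distance()`); stops (step < 1 cm
  between frames), closest stop, closest fly-by and inter-stop
  distances (`detect_stops()`, `search_metrics()`); search-state heat
  maps on 5 cm cells counting distinct birds (`build_heatmap()`).
* **A matched simulator**: `simulate_tracks()` generates 3-D tracks
  with the model's own statistical structure (two states, endogenous
  distance feedback, landmark groups, ground-truth states) at the scale
  of the motivating experiments; `simulate_series()` is the exogenous
  emission-level mode used for fitter calibration. `run_experiment()`
  chains fitting, selection, decoding, crossovers, heat maps, metrics
  and diagnostics into one reproducible report.

## Worked example

Simulate a landmark-present experiment (8 birds here for speed), fit
the distance-covariate model, and ask at what distance birds cross 50%
probability of being in Search:

```r
library(flightHMM)

cfg <- study_default_config(1, n_birds = 8, steps_mean = 150, seed = 42)
sim <- simulate_tracks(cfg)
sim
#> simulated dataset: 8 tracks, 1501 locations (experiment 1, seed 42)

fit <- fit_hmm(sim$tracks, hmm_spec(~ distance), n_restarts = 2, seed = 1)
fit
#> Two-state movement HMM (tpm ~ distance)
#>   log-likelihood -4086.016, k = 15, AIC = 8202.03, n = 1493 steps over 8 tracks
#>   Travel: step mean 7.002, sd 3.065, zero mass 0.156; yaw rho 0.846; pitch rho 0.953
#>   Search: step mean 1.525, sd 1.201, zero mass 0.293; yaw rho 0.357; pitch rho 0.877

crossover_distance(fit, landmark = 1, n_boot = 500, seed = 2)
#> 50% Search crossover at 0.985 m (95% CI 0.815-1.136) (landmark = 1)

search_metrics(sim$tracks[[1]])
#> closest fly-by: 77.10 cm; closest stop: 77.64 cm; difference: 0.55 cm; 45 inter-stop distance(s)
```

Reading the output: the fit recovers a fast, directed Travel state
(7 cm/frame ≈ 2.1 m/s at 29.97 fps, concentrated yaw) and a slow,
sinuous, hover-rich Search state (1.5 cm/frame, 29% exact-zero steps);
the generating values were 7 / 1.5 cm/frame with zero masses
0.15 / 0.30. The crossover says these simulated birds became more
likely to be Searching than Travelling once within about 1 m of the
flower's former location (the generating curve crosses at 1.09 m, inside
the bootstrap interval). `search_metrics()` summarises one bird's
spatial accuracy: how close its path and its closest hover came to the
goal.

See the methods vignette (`vignettes/movement-hmm-methods.Rmd`) for the
model, its numerical details and the design of the synthetic generator.

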
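# cliffhmm

Behavioural-state analysis of mouse locomotion in a circular visual-cliff
arena, for researchers quantifying depth perception and visually guided
behaviour from pose-tracking video.

The traditional visual-cliff readout — the fraction of time on the shallow
side — is noisy and confounded by wall-hugging and corner preference; in a
circular arena it settles near 0.5 even for sighted mice. `cliffhmm` instead
models the *structure* of movement: a hidden Markov model with three
behavioural states — Resting, Exploring, Navigating — whose transition
probabilities and directional persistence depend on where the animal is
relative to the cliff line, the arena wall, and the arena centre.

## The model

Steps are summarised by length `l_t` (gamma-distributed per state, means
`m_1 < m_2 < m_3`) and wrapped turning increment `phi_t` (wrapped Cauchy
centred at 0 with state- and context-dependent concentration `rho`). Spatial
context enters through logistic influence functions of the feature distances,

    I_f(d) = 1 / (1 + exp(-beta_f (d - x_f))),   beta_f < 0,

with the cliff pair fixed at `x = 6` cm, `beta = -1` and the symmetric cliff
distance `d_cliff = |x|`. Influences shift the banded (adjacent-state-only)
transition logits and blend the angular concentrations. The headline derived
statistic is the **HMM cliff effect**: the per-state difference in stationary
state probabilities between a point on the cliff line and a reference point
on the shallow side, evaluated along a circular path at the wall where only
the cliff influence varies.

The package covers the full workflow: DeepLabCut-style CSV ingestion,
confidence filtering / thinning / gap segmentation, arena calibration by
iterative grid search, coordinate standardisation (cliff on `x = 0`, shallow
side `x < 0`), feature extraction, multi-start MAP fitting with Laplace 89%
intervals (optional Metropolis refinement and partial pooling across
animals), local/global state decoding, stationary-state profiles and cliff
effects, the shallow-side rate, time-window splits, and a generative
simulator with WT-, RD- (blind), and OF- (no cliff) like parameter sets.

## Worked example

Simulate two sessions from the sighted-condition defaults, fit the model,
and read off the cliff effect:

```r
library(cliffhmm)

params <- cliff_params_preset("WT")
sessions <- lapply(1:2, function(i) simulate_session(params, n_steps = 1500, seed = i))
series <- lapply(sessions, `[[`, "series")

fit <- cliff_hmm(series, K = 3, starts = 2, seed = 1)
print(fit)
#> Covariate-modulated movement HMM (K = 3), MAP fit
#>   2 session(s), 3000 steps; log-likelihood -6524.65, log-posterior -6589.30
#> Movement HMM parameters (K = 3 states)
#>              mean_cm    shape basal cliff  edge center
#> Resting    0.2994194 2.019867 0.136 0.232 0.503  0.703
#> Exploring  1.2332318 3.801854 0.501 0.820 0.739  0.523
#> Navigating 2.2737573 6.884804 0.816 0.847 0.829  0.264
#> Influence functions (offset cm / slope 1/cm):
#>   cliff  x =  6.000  beta = -1.000
#>   edge   x =  4.066  beta = -1.599
#>   center x =  5.730  beta = -0.578
```

The state step means (0.299 / 1.233 / 2.274 cm against generating values
0.3 / 1.2 / 2.2) and the Exploring-state cliff concentration (0.820 vs 0.8)
are recovered even at this small scale; the influence offsets need more data
(their 89% intervals from `summary(fit)` are wide here, and tighten at the
12-session scale used by the acceptance script).

```r
prof <- state_profile(make_path("circular", arena_geometry()), fit$par)
cliff_effect(prof)
#>        state       delta
#> 1    Resting -0.06255424
#> 2  Exploring  0.03824766
#> 3 Navigating  0.02430659
```

Approaching the cliff, the fitted model moves a few percent of stationary
occupancy out of Resting into Exploring/Navigating — the modest, specific
signature of depth perception. Running the same pipeline on the `"RD"` or
`"OF"` presets gives a cliff effect of exactly (0, 0, 0), because those sets
carry no cliff terms. The traditional metric on the same session,

```r
shallow_side_rate(as.data.frame(sessions[[1]]$track))
#> [1] 0.187
```

illustrates its weakness: a single session's side occupancy wanders far from
0.5 because positions are strongly autocorrelated.

Decoding, residuals and simulation follow the usual generics:
`predict(fit)` (posterior state probabilities / Viterbi path),
`residuals(fit)` (one-step-ahead pseudo-residuals), `simulate(fit)`,
`plot(fit)`.

A command-line front end over the same functions lives at
`inst/cli/cliffstate.R` (subcommands `simulate`, `ingest`, `calibrate`,
`features`, `fit`, `decode`, `analyze`, `pipeline`).

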
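---
title: "Modelling visual-cliff locomotion with covariate-modulated hidden Markov models"
author: "cliffhmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling visual-cliff locomotion with covariate-modulated hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 3)
library(cliffhmm)
```

## The problem

The visual cliff assay places a mouse on a transparent floor over an apparent
drop and asks whether it perceives depth. The traditional readout — the
fraction of time spent on the shallow (table) side — is noisy and conflates
depth perception with thigmotaxis, corner preference and general exploratory
drive. In a circular arena the corner confound disappears and shallow-side
occupancy settles near 0.5 even in sighted animals, so the informative signal
has to be sought in *how* the animal moves near the cliff boundary, not in
*where* it sits.

`cliffhmm` implements a state-space answer: locomotion is segmented into three
latent behavioural states — Resting (short, weakly directed steps), Exploring
(intermediate steps) and Navigating (long, persistent steps) — and both the
switching between states and the directional persistence within states are
allowed to depend on where the animal is relative to three spatial features:
the cliff line, the arena wall, and the arena centre.

## The model

Movement is reduced to per-interval step lengths $l_t$ and turning increments
$\varphi_t = \theta_t - \theta_{t-1}$ (wrapped into $(-\pi, \pi]$). Given the
latent state $Z_t \in \{1, \dots, K\}$ (default $K = 3$):

* $l_t \mid Z_t = k \sim \mathrm{Gamma}(a_k,\ a_k / m_k)$, so $m_k$ is the
  state's mean step length in cm and the ordering $m_1 < m_2 < m_3$ anchors
  the state labels;
* $\varphi_t \mid Z_t = k \sim \mathrm{wrappedCauchy}(0,\ \rho_{\mathrm{eff}})$,
  a persistence model centred on the previous heading. Concentration
  $\rho = 0$ is the circular uniform (density $1/2\pi \approx 0.159$);
  $\rho \to 1$ is straight-line motion.

Spatial context enters through logistic *influence functions* of the distances
to the three features,
$$I_f(d) = \frac{1}{1 + \exp(-\beta_f (d - x_f))}, \qquad f \in \{\text{cliff},
\text{edge}, \text{center}\},$$
with negative slopes $\beta_f$ (units 1/cm) so that $I_f \approx 1$ at the
feature, exactly $1/2$ at the offset $x_f$ (cm), and $\approx 0$ far away. The
cliff distance is symmetric, $d_{\text{cliff}} = |x|$ in the standardised
frame, and the cliff pair is *fixed* at $x_{\text{cliff}} = 6$ cm,
$\beta_{\text{cliff}} = -1$: freeing it lets the cliff term absorb
centre-distance structure and produces spurious "cliff effects" in blind and
open-field controls, so holding it fixed is part of the model definition
rather than a computational convenience.

Influences act in two places:

1. **Transitions.** Each row of the transition matrix is a multinomial logit
   with the diagonal as reference:
   $\eta_{ij} = \alpha_{ij} + \beta_{ij} \cdot (I_{\text{cliff}}, I_{\text{edge}},
   I_{\text{center}})$ for adjacent $j$, and $\Gamma_{ij} = 0$ whenever
   $|i - j| > 1$. The band reflects that activity levels change gradually;
   it also makes every per-step chain a birth–death chain, whose stationary
   distribution has a closed form used in the compiled likelihood.
2. **Angular concentration.** Each state carries four concentrations
   (basal and one per feature), blended on the $\mathrm{atanh}$ scale with
   precedence edge > cliff > centre:
   $w_e = I_e$, $w_c = I_c(1 - I_e)$, $w_{ce} = I_{ce}(1 - I_e)(1 - I_c)$,
   remainder basal, and
   $\rho_{\mathrm{eff}} = \tanh\big(\sum_f w_f \,\mathrm{atanh}\,\rho_{k,f}\big)$.
   The precedence order encodes that the physical wall dominates behaviour
   whenever the animal is against it, the cliff dominates the remaining
   interior, and the centre acts only where neither applies. The exact
   combination rule for overlapping influences is a genuinely open design
   point; this blend is monotone in each component, bounded by the largest
   component, and reduces exactly to the basal value when all influences
   vanish, which is what the identifiability of the control conditions needs.

Covariates are evaluated at each step's *start* point: the state in force
"decides" the upcoming movement. The initial state distribution of each
session is the stationary distribution at the first step's covariates, which
avoids a free parameter per session. The likelihood is the exact marginal
forward recursion with per-step rescaling, implemented in C++; a pure-R
implementation of the same recursion is kept as an independent cross-check and
the tests verify both against brute-force path enumeration on small instances.

## What the estimates mean

| parameter | units | default (WT set) | role |
|---|---|---|---|
| $m_1, m_2, m_3$ | cm | 0.3, 1.2, 2.2 | state mean step lengths at 10 fps |
| $a_k$ | — | 2, 4, 6 | gamma shapes (dispersion of steps) |
| $\rho_{k,\cdot}$ | — | 0.2–0.9 | directional persistence per state/feature |
| $x_{\text{edge}}$ | cm | 3.2 | half-effect distance of the wall |
| $x_{\text{center}}$ | cm | 6.1 | half-effect distance of the centre |
| $\beta_{\text{edge}}, \beta_{\text{center}}$ | 1/cm | −2 | influence steepness |
| $\alpha_{ij}, \beta_{ij,f}$ | logit | see presets | transition intercepts and spatial slopes |

The sign structure is easiest to read through the derived quantities below
rather than through individual logit coefficients.

## From a fit to a cliff effect

At any arena location the fitted model implies a local transition matrix and
hence a stationary state distribution $\pi(x, y)$. `state_profile()` traces
$\pi$ along a synthetic path; two stock paths are provided. The *horizontal*
path spans the diameter on $y = 0$ and mixes edge, centre and cliff gradients.
The *circular* path at the wall radius holds $d_{\text{edge}}$ and
$d_{\text{center}}$ constant so that only the cliff influence varies — it
isolates the cliff response. The **cliff effect** is the per-state difference
$\Delta\pi_k = \pi_k(a) - \pi_k(b)$ between a marked point $a$ on the cliff
line and a reference point $b$ on the shallow side far from the cliff; its
components sum to zero by construction. With posterior draws the full
distribution of $\Delta\pi_k$ is reported with 89% intervals (the reporting
convention used throughout the package).

The default marks place $a$ at the circle's cliff-line crossing $(0, r)$ and
$b$ at the shallow extreme $(-r, 0)$. Published figures mark these points only
graphically, so the marks are configurable and recorded in the outputs. An
inset circular path (e.g. 27 cm) is supported because at exactly the wall
radius the edge influence is saturated.

```{r profile, fig.alt = "stationary state profile along the circular path"}
p <- cliff_params_preset("WT")
prof <- state_profile(make_path("circular", arena_geometry()), p)
plot(prof, main = "WT-like stationary profile along the wall")
cliff_effect(prof)
```

## Estimation

The default estimator is multi-start MAP: L-BFGS-B on an unconstrained
parameterization (log-increment means for the ordering constraint, logit
concentrations, log offsets, log negative slopes), with a short exploratory
stage from 5 starts followed by a full polish of the best start. Priors are
weakly informative and scale-matched to the 30 cm arena:
$\log m_k \sim N(\log 1, 1.5)$, $\log a_k \sim N(0, 1)$,
$\mathrm{atanh}\,\rho \sim N(0, 1)$, transition coefficients $\sim N(0, 2.5)$,
$x_{\text{edge}}, x_{\text{center}} \sim N(5, 10)$ truncated positive,
$\beta_{\text{edge}}, \beta_{\text{center}} \sim N(-1, 1)$ truncated negative.
The MAP is taken in the constrained space (no change-of-variable Jacobian),
matching the usual practice of posterior-mode optimisers. Uncertainty comes
from a Laplace approximation at the mode, summarised as 89% quantile
intervals of transformed multivariate-normal draws; an adaptive random-walk
Metropolis refinement is available behind `mcmc = TRUE` for posteriors where
the quadratic approximation is suspect. Starting values are data-driven
(quantile-split step scales), and refitting with the same seed reproduces the
estimates exactly.

Two estimation-adjacent tools mirror the standard model-building workflow:
`mixture_screen()` fits independent 1–3-component mixtures (gamma/lognormal
for steps, wrapped Cauchy/von Mises for angles) by EM and ranks them by the
small-sample-corrected Akaike criterion — the route by which three states and
the gamma/wrapped-Cauchy families are justified before any HMM is fitted —
and `posterior_predictive()` replicates step/angle data along the observed
covariate paths for overlay checks, including autocorrelation envelopes.
`fit_hierarchical()` adds partial pooling across animals as a two-stage
normal-normal random-effects model on the unconstrained per-animal estimates
(REML via `metafor`), shrinking animal-level parameters toward the group mean;
it is an approximation to a joint hierarchical likelihood, adequate when each
animal's own fit is informative.

## The simulator and what passing tests show

`simulate_session()` is the generative twin of the model: at each step the
influences at the current position drive the transition matrix, a state is
sampled, a gamma step and wrapped-Cauchy increment are emitted, and the
position advances. Its defaults *are* the study conditions: a 30 cm circular
arena with the cliff through the centre, 10 fps effective sampling (a 30 fps
video thinned by 3 — thinning preserves the distributional shape of the
metrics while smoothing trajectories; a factor of 5 to 6 fps is also
supported), sessions of 6000 steps, and the WT/RD/OF parameter sets built
from the reported estimates: step means 0.3/1.2/2.2 cm, Exploring cliff
concentration 0.8, edge offsets 3.2/3.0/4.4 cm and centre offsets
6.1/23.6/12 cm for the sighted-cliff, blind, and open-field conditions, with
all cliff terms zeroed in the two control sets. Transition intercepts were
calibrated once, by script, so that unconditional state occupancy is roughly
0.4/0.35/0.25 with Resting-dominant dwell at the wall, and the WT cliff
slopes so that the circular-path cliff effect on Resting and Navigating falls
in the 2–4% band; exact occupancies are not targets.

Boundary handling is the one deliberate model/simulator mismatch: proposals
leaving the arena are specularly reflected at the wall and the realized step
is recomputed from realized positions, so near-wall steps are not exactly
gamma under the generating state. Reflection keeps the interior emission
distributions unbiased (the alternatives — rejection or truncation — distort
them globally), at the price of a small localized bias that the recovery
tests absorb. Zero-length steps carry the previous heading and are excluded
from both emission terms by weight.

Simulated data share the real assay's sampling structure (confidence dropout,
frame gaps, arena geometry) but not its biology: no session-to-session
behavioural drift, no habituation within a session, no body-pose error
correlated with posture. Passing recovery tests therefore demonstrates that
the estimator inverts the generative model at realistic sizes — not that the
model is true of mice. Conversely, the control presets (RD/OF) demonstrate
specificity: with cliff terms zeroed the circular-path cliff effect is
identically zero and shallow-side occupancy is balanced.

A note on that occupancy check: frames of a trajectory are strongly
autocorrelated (a session's shallow-side fraction has an effective sample
size of a few tens, not thousands), so the package's tests compare the
simulated rate to 0.5 using a binomial standard error scaled by the
autocorrelation-implied effective sample size computed from the simulation
itself.

## Numerical choices and degenerate inputs

* Forward recursion in linear space with per-step renormalisation; emission
  densities computed in closed form without per-state logarithms (the C++
  path), log-space accumulation of the normalisers.
* Arena calibration: for a fixed centre the smallest circle covering a
  fraction $q$ (default 0.995) of points has radius equal to the $q$-quantile
  of the distances, so the iterative grid search walks centres only
  (coarse-to-fine, halting at 0.05 cm) and reads the radius off the quantile.
  The coverage fraction and convergence limits are package choices; the
  pixel scale derives from the fitted radius against the known 30 cm arena
  when not supplied.
* Quality filtering keeps frames with tracking confidence ≥ 0.9, then thins,
  then segments at gaps longer than 5 source frames (filter → thin → gap
  order; steps across longer holes are not single-interval movements and
  segments are modelled as independent chains). Segments shorter than 3
  retained frames are dropped at feature extraction.
* Ties in decoding break toward the lowest-numbered state, deterministically.
* Concentrations are clamped below 1 − 10⁻¹² when transforming unconstrained
  draws so that extreme Laplace draws remain valid parameter sets.
* Degenerate circle fits (collinear or clustered points), coincident cliff
  points, empty tracks and constant series raise errors rather than
  propagating nonsense; out-of-arena points beyond a 1 cm tolerance are
  clamped to the wall with a warning.

## Known limitations

* The tangent direction at the wall ($\theta_{\text{edge}}$) is computed and
  exported but does not enter the angular emission: biasing the angular mean
  toward the tangent near the wall is a plausible extension, left as a hook.
* The cliff effect of the fitted model is only as identifiable as the spatial
  coverage of the data; an animal that never approaches the cliff band
  constrains the cliff terms only through the prior.
* Partial pooling is two-stage, not a joint hierarchical likelihood; with
  very short sessions the Laplace standard errors that feed the pooling are
  themselves rough.
* Sessions are assumed stationary within a fitting window; the
  `window_split()` tool (default 3-minute windows) exists precisely because
  state definitions drift over a long trial, and per-window fits should be
  compared with that drift in mind.

## Problem sizes used by the packaged checks

The recovery experiment fits 12 sessions of 6000 steps (72,000 steps, the
scale at which the reported estimates are recovered within ±15%); unit tests
use sessions of 600–6000 steps, and the exhaustive-enumeration oracles run at
6 steps × 3 states where all 729 paths can be summed directly.
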
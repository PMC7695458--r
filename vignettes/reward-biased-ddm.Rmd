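---
title: "Reward-biased drift diffusion and its neural signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-biased drift diffusion and its neural signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardDDM)
```

# The problem

Monkeys discriminating the direction of a random-dot motion stimulus, with a
block-wise asymmetry in the reward attached to the two choice targets, bias
their choices and reaction times toward the large-reward option. In a
drift-diffusion account there are two distinct levers for that bias: a
constant offset added to the momentary evidence (a *drift-rate bias*, `me`)
and an asymmetric placement of the starting point between the two decision
bounds (a *bound bias*, `z`). The two levers leave different signatures in
choice/RT data and make different predictions for single-neuron activity in
oculomotor structures: a drift bias appears as a reward-context modulation of
the *slope* of firing-rate build-up during motion viewing, while a bound bias
should appear as a congruent offset of baseline firing before motion onset
(or an opposite-signed offset before the saccade).

`rewardDDM` implements the full analysis chain: the behavioural model and its
fitting, the spike-count regressions, the slope and congruency analyses, the
baseline trial-splitting comparison, and a synthetic-data generator with
known ground truth so every stage can be validated by parameter recovery.

# The decision model

The decision variable integrates scaled evidence,

$$\mathrm{DV}(t) = \int_0^{t} k\,(E + me)\,ds, \qquad E \sim
\mathcal{N}(\text{coherence}, 1),$$

with unit diffusion, so the drift at signed coherence $c$ in reward context
$r$ is $k\,(c + me_r)$. The total bound separation collapses logistically,

$$B(t) = \frac{a}{1 + e^{\beta_\alpha t - \beta_d}},$$

and the relative bound height $z_r \in (0,1)$ places the start point a
fraction $z_r$ of the separation above the lower bound: with accumulation
starting at 0 the bounds sit at $(1-z_r)B(t)$ and $-z_r B(t)$, so $z > 0.5$
puts the upper (reference-choice) bound closer to the start. The response
time adds a non-decision time $t_0$. Two reward contexts are distinguished:
`ref-large` (reference choice paired with the large reward) and `ref-small`;
$k, a, \beta_\alpha, \beta_d, t_0$ are shared between contexts while
$me_r, z_r$ are context-specific. The reward biases are the context
differences

$$\Delta\text{Drift} = me_{\text{ref-large}} - me_{\text{ref-small}},
\qquad \Delta\text{Bound} = z_{\text{ref-large}} - z_{\text{ref-small}},$$

positive values meaning a bias toward the large-reward choice.

## Design choices in the model

Several aspects of this model family are genuinely open and were fixed as
follows.

* **Noise convention.** The diffusion coefficient is 1 (momentary evidence
  has unit variance and is scaled by `k` only in the drift). Scaling the
  noise by `k` as well would simply rescale $a$; only relative geometry is
  identifiable.
* **Geometry of `z`.** `z` is realised as an asymmetric start-to-bound
  distance with the start fixed at 0. A starting-point offset between fixed
  symmetric bounds is equivalent; only relative distances matter.
* **Collapse clock.** The bound collapse runs on accumulation time ($t=0$ at
  motion onset); $t_0$ is not subtracted from the collapse clock.
* **Non-decision time.** $t_0$ is a free parameter with a
  normal(0.3 s, 0.1 s) prior truncated to $(0, \min \mathrm{RT})$, since
  measured RTs (motion onset to saccade onset) must exceed the decision
  time.
* **Horizon and lapses.** Simulated trials not absorbed within 10 s are
  flagged and excluded from likelihoods; with collapsing bounds this is a
  vanishing fraction.

# Numerics

## First-passage solver

`first_passage_grid()` propagates the accumulator's probability mass on a
state grid by discrete Gaussian transition-kernel convolution with
absorption applied per transition: mass landing beyond a (collapsing)
bound is absorbed outright, and mass staying inside is absorbed with the
Brownian-bridge within-step crossing probability
$\exp(-2 (b - x_{start})(b - x_{end})/\Delta t)$. Three properties of this
scheme matter:

* the grid always contains the start point as an exact node, which makes
  mirror-symmetric problems (negated coherence and `me`, `z` reflected to
  `1 - z`) produce exactly mirrored solutions;
* because the bridge probability rises continuously to 1 as a bound
  approaches a node, the solution — and hence the fitted likelihood — is a
  smooth function of the bound parameters, which gradient-free
  optimisation and finite-difference curvatures both require;
* without the bridge term the crossing probabilities converge only as
  $O(\sqrt{\Delta t})$, which is visible at the default resolutions.

The discrete kernel is renormalised so each step conserves probability
exactly; the conservation invariant (absorbed + interior mass = 1) holds to
$10^{-6}$ and is tested. Propagation stops early once the interior mass
falls below $10^{-7}$. The resolution rule `dx <= sqrt(dt)` (one kernel
standard deviation) is enforced with an error. Defaults: `dt` 1 ms and `dx`
0.025 for stand-alone use; the likelihood inside the MAP fit uses `dt` 5 ms,
`dx` 0.06, which keeps one likelihood evaluation near 15 ms and leaves the
bias parameters' recovery unbiased at the session sizes used here.

`simulate_trials()` is the Euler counterpart (`dDV = k(c+me)dt +
\sqrt{dt}\,\eta`) with the same Brownian-bridge within-step crossing test;
when a step's endpoint lies beyond a bound, the crossing time is located by
linear interpolation of the path against the linearly interpolated bound,
and the earliest interpolated crossing wins. Every trial consumes its own
counter-based random stream derived from the seed, so results do not depend
on trial order and are bit-reproducible.

## MAP fitting

`fit_ddm_map()` maximises the log posterior over the nine parameters on
unconstrained scales (log for $k, a, \beta_\alpha$; logit for $z$ and
$t_0/\min\mathrm{RT}$). Priors are weakly informative: $k$ half-normal(10),
$a$ gamma(2, 1), $z$ beta(10, 10), $me$ normal(0, 0.3), $\beta_\alpha$
half-normal(3), $\beta_d$ normal(5, 3), $t_0$ as above; all overridable.
Optimisation is Nelder-Mead from five (or more) starts — one default start
plus prior draws — with the best run polished by a restart; every run's log
posterior is reported, and the fit is deterministic given (data, seed,
n_runs). Trial likelihoods interpolate the solver's crossing density
linearly in time with a floor of $10^{-10}$.

A practical identifiability note: the collapsing-bound family has a
likelihood ridge among $(k, a, \beta_\alpha, \beta_d)$ — fits pin down the
collapse midpoint $\beta_d/\beta_\alpha$ and the bias parameters precisely,
while the individual structural parameters can trade off along the ridge.
Recovery tests therefore assert accuracy for $me_r$ and $z_r$ (and the
derived $\Delta$Drift/$\Delta$Bound), not for individual structural
parameters. The `fixed =` argument of `fit_ddm_map()` can hold structural
parameters at known values, which the trial-splitting analysis uses to
stabilise refits on half-sized trial groups.

# Neural analyses

Spike counts are analysed with ordinary least squares (matching the
multiple linear regression used in this literature), in eight task epochs
and in 150 ms windows stepped every 10 ms, over correct trials only.
The coherence design regresses counts on choice, reward context, reward
size, choice-split coherence magnitudes and their reward-size interactions;
the RT design replaces the coherence terms with choice-split mean-subtracted
RTs (means per reward-context-by-choice cell). Windows with fewer than 10
qualifying correct trials are excluded. Neurons are included when their peak
rate reaches 5 Hz and every signed-coherence-by-context cell has at least 5
finished and 3 correct trials; they are *choice-selective* when the
RT-design choice coefficient is significant with a consistent sign during
motion viewing (epoch 5) and immediately before the saccade (epoch 6).

Because reward contexts alternate in blocks, slow firing drift can
masquerade as reward-context coding. `serial_correlation_null()` replaces
the reward-context regressor with random contiguous segments of a pool of
context sequences concatenated across neurons — preserving the blocked
autocorrelation — and adjusts the p-value by the one-tailed magnitude rank
$(1 + \#\{|\beta_{null}| \ge |\beta_{obs}|\})/(1 + n_{null})$ with
$n_{null} = 100$. Only the reward-context column is shuffled; the other
regressors, including reward size, keep their observed values.

The slope analysis smooths condition-averaged rates (coherence magnitude by
context, preferred-choice correct trials, truncated at each condition's
median RT) with a 20 ms Gaussian, measures per-window slopes by linear
regression in 200 ms windows every 20 ms, and regresses condition slopes on
coherence, context and their interaction per window. Each neuron's summary
is the context:coherence coefficient ratio at the window with the largest
absolute coherence coefficient among significant windows (centers at or
after +0.1 s for motion alignment, imposing a visual latency). One
refinement: a window enters the series only when *every* condition still
contributes (no condition has been truncated), because modulation
coefficients estimated from different condition subsets are not comparable —
windows near the truncation edge otherwise dominate the peak search with
selection artifacts. Interaction coefficients are computed and reported but
no downstream inference is built on them.

Congruency and splitting test the bound-bias predictions: before motion
onset a significant reward-context coefficient (preferred-choice frame) is
congruent when it shares the sign of $\Delta$Bound, before the saccade when
it opposes it; fractions are tested against 0.5 per bin by chi-square,
uncorrected. `split_by_baseline()` halves each context's trials at the
median pre-motion (epoch 3) rate — rank-based, ties broken by trial index,
the median trial going to the low half, which keeps the two groups equal
and deterministic — and `split_ddm_compare()` refits the DDM per group and
t-tests the bound-bias difference across neurons.

# The synthetic generator

`generate_behavior_session()` produces task behaviour from a ground-truth
parameter set: contexts alternating in blocks (40-trial blocks, 8 blocks by
default), coherences drawn uniformly from a per-monkey-style set, choices
and RTs from the simulator, correctness by sign agreement (0%-coherence
trials rewarded by a fair coin, the standard convention), and event times
with a uniform 0.5-1.0 s target-to-motion delay. The default parameters
(`k = 6`, `a = 1.8`, `beta_alpha = 3`, `beta_d = 5`, `t0 = 0.3`,
`me = (+0.03, -0.03)`, `z = (0.48, 0.52)`) give coherence-dependent
accuracy and RTs in the 0.4-1.2 s range typical of this task, a drift bias
toward and a bound bias away from the large-reward choice — the sign
pattern the behavioural analyses single out.

`generate_spike_trains()` produces inhomogeneous-Poisson spikes whose rate
combines a baseline with a reward-context offset (preferred-choice frame), a
build-up from motion onset plus 100 ms latency whose initial slope follows
`g0 + g_coh * coh + g_ctx * I_context` (optionally saturating with time
constant `ramp_tau`, mimicking accumulation toward a bound; the
context:coherence slope ratio is then invariant across windows), an optional
RT-coupled slope term, and a Gaussian peri-saccadic burst. Rates are clamped
at zero. A per-trial latent `u ~ N(0,1)` can couple the session's bound
bias (`z_coupling_gamma`) to the neuron's baseline modulation (`mod_gain`),
which is what the trial-splitting analysis is designed to detect.

What the generator does *not* emulate: non-Poisson count dispersion,
spike-history structure, slow excitability drift (except where injected
deliberately for the shuffle-null validation), correlated noise across
neurons, and eye-movement kinematics beyond a threshold-crossing saccade
profile. Passing recovery tests therefore demonstrates the correctness of
the estimators under the stated generative assumptions, not robustness to
every property of real recordings.

## Fixture presets and study sizes

`fixtures()` freezes the configurations used by the tests and docs:

* `monkeyA/C/F-like` — single 320-trial sessions with plausible log-spaced
  coherence sets (e.g. 0-51.2%) and the default reward biases.
* `null` — no reward bias, no encoding modulation; used for type-I-error
  checks.
* `drift-coupled` — 30 sessions of 3,000 trials whose drift bias spans
  0.02-0.20; each neuron's build-up uses a saturating ramp
  (`ramp_tau` 0.25 s, `g_coh` 300 spikes/s^2, baseline 10 Hz, no burst) with
  context gain `g_ctx/g_coh = 2 * delta_drift` — twice the
  decision-variable prediction, within the range of modulation ratios seen
  in frontal recordings, chosen so per-neuron ratio noise does not swamp
  the across-session spread. The preset omits the peri-saccadic burst to
  isolate the build-up component that the slope analysis targets.
* `bound-coupled` — sessions with a +0.10 bound bias, neurons whose
  baseline context offset (6 spikes/s on 20 Hz) shares that sign, and
  trial-wise coupling (`z_coupling_gamma = 1`, `mod_gain = 1`) between the
  latent modulation of the bound bias and of the baseline rate.

Validation suites run at desk scale: solver-simulator equivalence uses six
parameter sets with $10^5$ simulated trials each; DDM recovery uses six
sessions of 2,000 trials; the logistic recovery uses twenty sessions of
10,000 trials; regression calibration uses 800 null neurons plus 200 with
injected coefficients; the shuffle-null validation uses 200 drifting
neurons; the slope pipeline uses the 30 drift-coupled neurons and a
context-independent variant; congruency uses 150 simulated sign-independent
neurons and 12 bound-coupled ones; trial splitting uses 12 neurons under
exchangeable halves and four 12-neuron populations under coupling. These
sizes keep the full suite within a desktop run while leaving each check
statistically meaningful.

# Limitations

* The MAP fit reports posterior-curvature standard errors; along the
  structural-parameter ridge these understate marginal uncertainty. For
  inference on structural parameters a hierarchical or sampling-based fit
  would be needed (deliberately out of scope).
* OLS on counts mirrors the published analyses; a Poisson GLM would be the
  natural alternative but would change coefficient scales throughout.
* The congruency and splitting analyses inherit the sign conventions of the
  preferred-choice frame; neurons without consistent choice selectivity are
  excluded because the accumulator makes no prediction for them.
* The per-neuron source-data ingestion (`read_slope_source_data()`) expects
  the tabular layout produced by `slope_summary_table()` plus a
  `delta_drift` column; deposited tables with other headers need renaming.

# Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates the synthetic
study data, runs the full chain (solver-vs-simulation gap, logistic and DDM
biases, slope-ratio correlation, congruent fraction, split bound-bias
difference) and writes the quantities as JSON. All randomness flows from
the single seed.
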
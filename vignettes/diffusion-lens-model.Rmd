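---
title: "A two-level diffusion model of multiple-cue probability learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-level diffusion model of multiple-cue probability learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The scientific problem

In multiple-cue probability learning (MCPL) tasks of the
weather-prediction type, a participant repeatedly predicts a binary
outcome (truth/lie, win/loss) from a subset of four probabilistic cues and
receives feedback after each trial. Each cue carries an *ecological
validity* — the probability with which its presence signals the positive
outcome — and each trial shows one to three of the four cues, so the
outcome is *vicariously mediated* by changing, partially substitutable cue
patterns. A learner starts with no knowledge of the validities and, over a
few hundred trials, comes to weight the cues roughly in proportion to
them.

`diffusionlens` implements a process model of this adjustment in which
*both* choices and response times are modelled, together with the
canonical 14-pattern task environment, a full synthetic-data generator,
likelihood-based inference, and the classical baselines (the lens model
equation and the take-the-best heuristic).

## The model

The model is a two-level ("superstatistical") stochastic process. At the
low level, each trial's binary choice and response time arise from a
four-parameter Wiener diffusion: evidence accumulates at drift rate $v_t$
between absorbing boundaries $0$ and $a_t$, starting at $\beta \, a_t$,
and the hitting time plus a non-decision time $\tau_t$ gives the RT. The
upper boundary codes the positive outcome. Two linear maps tie the trial
parameters to the presented cue pattern:

$$v_t = v_0 + b_{v,t} \cdot \big(P(\text{positive} \mid \text{pattern}_t) - 0.5\big),
\qquad
\tau_t = \tau_{0,t} + b_\tau \cdot n_{\text{cues},t}.$$

The signed validity regressor $P - 0.5$ makes a pattern that favours the
negative outcome drive the accumulator downwards; $b_{v,t}$ is the
learner's current *sensitivity* to the ecological validities, $v_0$ a
cue-unrelated dynamic bias, and $b_\tau$ the extra encoding time per
presented cue (seconds/cue). At the high level, three parameters follow
independent Gaussian random walks across trials,

$$b_{v,t} = b_{v,t-1} + \sigma_v \xi_t, \qquad
a_t = a_{t-1} + \sigma_a \xi_t, \qquad
\tau_{0,t} = \tau_{0,t-1} + \sigma_\tau \xi_t, \qquad
\xi_t \sim \mathcal N(0,1),$$

so uncertainty reduction appears as a rising $b_v$ trajectory, and
practice effects as falling $a$ and $\tau_0$ trajectories, without
committing to any particular learning rule.

Model assumptions worth keeping in mind: the diffusion coefficient is
fixed at 1 (the standard identifiability convention; all evidence units
are relative to it); $v_0$, $\beta$ and $b_\tau$ are time-invariant; the
three walks are mutually independent (the transition equations share the
innovation symbol, but a common innovation would perfectly correlate the
walks, which is not the intended reading); and there are no across-trial
variability parameters of the full Ratcliff model ($s_v$, $s_{t0}$,
$s_z$).

## The task environment

`canonical_environment()` returns the 14 admissible 4-cue patterns with
their per-session presentation counts (246 trials), unconditional
probabilities, realized positive/negative outcome counts and designed
conditional outcome probabilities. Two facts about this table shape the
implementation:

* For four patterns the printed designed probability differs from the
  realized ratio `a/(a+b)` (e.g. one pattern has 9/11 = 0.818 realized
  but 0.773 designed). We store both: `iid` sampling uses the designed
  probability, `exact_counts` sampling reproduces the realized counts.
* The single-cue marginal validities recompute from the table to
  0.805/0.602/0.398/0.203 for cues 1–4, confirming the intended
  0.8/0.6/0.4/0.2 hierarchy and fixing the cue-position coding (bit 1 =
  strongest positive cue).

Patterns are grouped for reporting by the absolute validity
$|P - 0.5|$, rounded to 3 decimals, which yields 7 distinct levels. (The
level containing the 0.773/0.227 patterns is sometimes referred to by the
probability 0.227 rather than the distance 0.273; we group by distance and
keep the label separate.)

```{r}
library(diffusionlens)
env <- canonical_environment()
env
```

## Simulation and the synthetic-data generator

`simulate_participant()` composes the two levels: draw a session sequence
(`exact_counts` reproduces one designed 246-trial session; `iid` draws
patterns and outcomes independently), evolve or fix the latent trajectory,
map each trial to $(v_t, a_t, \tau_t, \beta)$, and draw (choice, RT) from
the Wiener process by Euler–Maruyama simulation.

The generator's defaults are the study conditions the package is tested
under: 246 trials/participant, statics $v_0 = 0$, $\beta = 0.5$,
$b_\tau = 0.15$ s/cue (an encoding cost of about 150 ms per cue is the
typical magnitude in this paradigm), and condition presets whose latent
trajectories emulate the characteristic learning-curve shapes: a
saturating sensitivity rise (asymptote 6 over ~60 trials for the
supportive "congruent" preset, 3.5 over ~90 trials for the adverse
"incongruent" one) with boundary separation decaying 2.0→1.3
(2.2→1.5) and base non-decision time 0.40→0.25 s (0.45→0.30 s).
With validity regressors up to ±0.437 these values produce drifts up to
about ±2.6, accuracies near 0.9 on the most valid patterns, and mean RTs
between roughly 1 and 2 s — the magnitudes typical of this task. The
presets are test fixtures with a convenient functional form, not fitted
curves; parameter recovery always uses random-walk trajectories or known
fixed trajectories.

```{r}
cfg <- synthetic_config(n_participants = 2, preset = "congruent", seed = 7)
d <- simulate_experiment(cfg)
correct_rt_by_ncues(d)
```

What the generator does *not* emulate: contaminant responses (lapses,
fast guesses), within-trial attention shifts, the facial-salience
mechanism that produces congruence effects in real data (congruence
enters only as a preset), and any cue-level decomposition of the drift
beyond the pattern's overall validity. Passing recovery tests on
synthetic data therefore shows that the inference machinery works where
the model is true — not that the model is true of any real dataset.

## Numerical choices

* **Density.** The Wiener first-passage density is evaluated by the
  standard small-time/large-time series for the standardised density,
  switching by the number of terms each series needs at a per-term
  truncation tolerance of $10^{-7}$. The large-time exponential and sine
  terms are advanced by recurrences, so one evaluation costs a handful of
  transcendental calls. Impossible observations ($rt \le \tau$) and
  underflows return a log-floor of $-700$ instead of erroring, so a
  likelihood is always defined.
* **Choice probability.** The absorption probability uses the analytic
  `expm1` form with the exact limit $\beta$ at $v a \to 0$, avoiding the
  0/0 of naive evaluation.
* **Simulator.** Euler–Maruyama with default step 1 ms and a
  Brownian-bridge boundary-crossing test inside each step: even when both
  step endpoints lie inside $(0, a)$, the continuous path crosses the
  upper boundary with probability $\exp(-2(a-x_0)(a-x_1)/dt)$ (and the
  lower analogously), and accepting those crossings removes the naive
  scheme's $O(\sqrt{dt})$ boundary-overshoot bias. The remaining error is
  the $O(dt)$ quantisation of the recorded hitting time. At
  $dt = 10^{-4}$ the simulator matches the exact density to defective-CDF
  KS distance below 0.01 at $2\times10^4$ samples; that step is used
  whenever simulation is compared against the density.
* **Supports.** The walks on $a$ and $\tau_0$ are reflected at
  $a_{\min} = 0.1$ and $\tau_{0,\min} = 0$. Reflection (rather than
  clipping) preserves the innovation magnitude and avoids sticky
  boundaries that would distort the walk's variance; whether the original
  formulation constrained these parameters by transform instead is not
  determinable, so this is our design choice and is documented as such.
  $b_v$ is unbounded — early sensitivity may be negative (below-chance
  utilization driven by invalid cues).
* **Initial state.** $b_{v,1} \sim N(0, 0.5)$ encodes initial absence of
  cue knowledge; $a_1 \sim N(1.5, 0.5)$ and $\tau_{0,1} \sim N(0.3, 0.1)$,
  truncated to their supports, encode generic speeded-decision values.
  All are configuration-overridable.

## Inference

The likelihood of a participant's session integrates over the latent
trajectory, so we use sequential Monte Carlo. `particle_filter()` is a
bootstrap filter: particles propagate by the prior transition, are
weighted by the trial's WFPT density, and are systematically resampled
when the effective sample size falls below half the particle count. Its
log marginal likelihood estimate is unbiased in expectation and collapses
*exactly* (to floating-point accuracy) to the closed-form static
likelihood when all walk scales are zero and the initial state is
degenerate — the main correctness oracle for the filter.

`pmmh()` wraps the filter in particle-marginal Metropolis–Hastings over
the six time-invariant quantities $(v_0, \beta, b_\tau, \sigma_v,
\sigma_a, \sigma_\tau)$. This samples the exact posterior despite the
noisy likelihood estimate. Design choices that matter in practice:

* Proposals are independent Gaussian random walks on transformed
  parameters (log for positive ones, logit for $\beta$), with scales
  adapted during burn-in towards 20–40% acceptance. Each adaptation step
  is clamped so one noisy window cannot collapse or explode the scales —
  pseudo-marginal chains are prone to sticking when a proposal's
  likelihood is overestimated, and runaway proposal scales make this much
  worse.
* The chain initialises at the best of several prior draws; if no prior
  draw yields a usable likelihood (e.g. RTs below any feasible
  non-decision time) the fit aborts with an explicit initialization
  error rather than producing a silent degenerate chain.
* Default priors: $v_0 \sim N(0,1)$, $\beta \sim \text{Beta}(5,5)$,
  $b_\tau \sim$ half-$N(0, 0.3)$, each $\sigma \sim$ half-$N(0, 0.1)$.
  These are weakly informative on the scales the task operates on
  (seconds, unit-diffusion evidence).
* One latent trajectory per thinned retained iteration is sampled from
  the accepted filter's ancestral paths. Ancestral paths are degenerate
  near $t = 1$ (resampling coalesces lineages), so trajectory estimates
  for the first trials mostly reflect the initial prior and should not be
  over-interpreted.
* Participants are fitted independently; there is no hierarchical
  pooling.

The default chain keeps 2000 post-burn-in samples. The recovery studies
in the package's tests run 10 participants at 512 particles and 1500
iterations (500 burn-in), and the acceptance script runs 5 participants
at the same settings — sizes chosen so a full check completes on a single
CPU in minutes while still giving stable 90% intervals; they are
reduced-setting checks, not converged reference analyses.

## Diagnostics and baselines

`posterior_resimulate()` implements the posterior-predictive check used
for model validation: 500 draws per participant (the default) from the
joint posterior of statics and trajectory, each forward-simulated through
the participant's observed stimulus sequence and aggregated by validity
level and condition. `moving_average()` (trailing window, default lag 20,
truncated at the series start), `rt_accuracy_by_validity()` and
`correct_rt_by_ncues()` (correct trials only, millisecond rounding,
empty cells flagged `NA`) reproduce the standard summary figures and
tables for this task. Whether RT summaries should use correct trials only
is not fixed by convention; we default to correct-only (consistent with
correct-RT tables) and expose `rt_trials = "all"`.

Two baseline formalisms are included for comparison, not fitting:
`lens_model_equation()` evaluates the classical achievement decomposition
$r_a = G R_e R_i + C\sqrt{(1-R_e^2)(1-R_i^2)}$ given its components
(estimating the components from data by regression is deliberately out of
scope), and `take_the_best_predict()` adapts the lexicographic
take-the-best heuristic to single-profile prediction: present cues are
ranked by marginal-validity extremity; a rank of cues pointing to
opposite outcomes does not discriminate and the search falls through.
Because the canonical environment's strongest positive and strongest
negative cues are *almost* equally extreme (0.805 vs 0.203 from the
realized counts), the tie tolerance defaults to 0.01 so that these two
cues tie — the intended reading of the designed 0.8/0.2 symmetry — and a
pattern showing only them is a guess. A stricter tolerance is available
via the `tol` argument.

## Known limitations

* The Euler simulator records hitting times at step ends, so simulated
  RTs carry a sub-millisecond positive quantisation bias at the default
  1 ms step. Use $dt = 10^{-4}$ where exactness matters and runtime
  allows.
* Pseudo-marginal chains at 512 particles have noticeable autocorrelation;
  interval estimates at the reduced settings are serviceable but not
  publication-grade. Increase particles and iterations for real analyses.
* The random-walk prior on $b_v$ is exploratory: it can track any smooth
  trajectory but has no learning-rule content, so fitted trajectories
  describe *that* adjustment happened, not *why*.
* Achievement-level quantities (lens-model components) are evaluated, not
  estimated; connecting them to fitted diffusion parameters is left to
  the analyst.
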
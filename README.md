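# diffusionlens

Process modelling of multiple-cue probability learning (MCPL) with joint
choice and response-time data. In weather-prediction-style tasks a
participant predicts a binary outcome (truth/lie, win/loss) from one to
three of four probabilistic cues and learns the cues' ecological
validities from trial-by-trial feedback. `diffusionlens` is for
researchers in judgment/decision-making and mathematical psychology who
want to model that adjustment process rather than only its endpoint.

## The model

Each trial's choice and RT follow a four-parameter Wiener diffusion
process,

    x_t ~ wiener(v_t, a_t, tau_t, beta)

whose drift tracks the ecological validity of the presented cue pattern
and whose non-decision time grows with the number of presented cues:

    v_t   = v_0 + b_{v,t} * (P(positive | pattern_t) - 0.5)
    tau_t = tau_{0,t} + b_tau * n_cues_t

Across trials, the drift sensitivity `b_v`, boundary separation `a` and
base non-decision time `tau_0` evolve as Gaussian random walks
(`sigma_v`, `sigma_a`, `sigma_tau`), so learning appears as a rising
`b_v` trajectory and practice as falling `a` and `tau_0` trajectories.
The package provides:

* the canonical 14-pattern, 246-trial task environment (designed
  conditional outcome probabilities and realized counts), with sequence
  generation in `exact_counts` and `iid` modes;
* exact Wiener first-passage-time log densities, analytic choice
  probabilities, and an Euler–Maruyama trial simulator (Rcpp);
* a full synthetic-experiment generator with congruent/incongruent
  learning-curve presets;
* a bootstrap particle filter and particle-marginal Metropolis–Hastings
  (PMMH) for posterior inference on the statics and walk scales, with
  latent trajectories sampled from the filter's ancestral paths;
* posterior re-simulation and the standard summary tables (correct RT by
  cue count, RT/accuracy by validity level, trailing moving averages);
* the lens model equation and a take-the-best baseline.

## Worked example

```r
library(diffusionlens)

env <- canonical_environment()
sum(env$total)                       # 246 trials per session
marginal_cue_validity(env, 1)        # 0.804878: cue 1 favours "positive"

# simulate two learners under the supportive (congruent) preset
cfg <- synthetic_config(n_participants = 2, preset = "congruent", seed = 7)
d <- simulate_experiment(cfg)
correct_rt_by_ncues(d)
#>    condition n_cues n_trials rt_mean rt_sd
#>    congruent      1       96   0.798 0.280
#>    congruent      2      174   0.990 0.369
#>    congruent      3      114   1.127 0.276

# fit one participant (reduced settings for illustration)
fit <- pmmh(d[d$participant == 1, ],
            config = fit_config(n_particles = 256, n_iter = 600,
                                burn_in = 200, seed = 1))
round(vapply(fit$samples[, 1:6], median, numeric(1)), 3)
#>      v0    beta   b_tau sigma_v sigma_a sigma_tau
#>  -0.247   0.541   0.175   0.244   0.031     0.009
```

Mean correct RT rises by roughly 165 ms per added cue, reflecting the
per-cue encoding cost `b_tau = 0.15` s/cue used by the generator. The
short illustration chain recovers `b_tau` near its true value with a
roughly symmetric starting point and a clearly positive
sensitivity-walk scale `sigma_v` tracking the rising `b_v` trajectory —
at these deliberately reduced settings the posterior medians are still
noisy; the package's recovery study uses 512 particles and 1500
iterations. (The RT table and posterior medians above are the actual
output of these commands at the seeds shown.)

A command-line wrapper is installed with the package
(`inst/exec/diffusionlens`) with subcommands `env`, `simulate`, `fit`,
`resim` and `report`.

## See also

The methods vignette (`vignettes/diffusion-lens-model.Rmd`) documents the
model assumptions, the numerical choices (series truncation, reflection
at supports, Euler step), the priors, and what the synthetic-data tests
do and do not establish.
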
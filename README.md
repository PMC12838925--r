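# pixssm

Valence-guided keep/reset agents in a stochastic binary grid-world — a
minimal, fully inspectable computational analogue of the somatic marker
hypothesis, for researchers studying lightweight evaluative heuristics as
an alternative to planning or exhaustive search in combinatorially large
state spaces.

## The model

The environment is an `n × n` binary grid (default `n = 3`, `2^9 = 512`
configurations) whose cells flip independently with probability
`flip_prob = 0.30` per step. The agent never sees the grid; it sees the
row-count *signature* `σ(P_t) = (r_1, …, r_n)` — 64 distinct signatures at
`n = 3`. A synthetic somatic marker stores one scalar valence per observed
signature, zero when unseen, updated after every visit by

    V(σ_t) ← clip(V(σ_t) + α · outcome, −1, 1),   α = 0.1

where the outcome is an external oracle's label: on *keep* the grid
transitions and scores `+1` iff it has ≤ 3 active cells (`−1` otherwise);
on *reset* the grid is redrawn uniformly and the outcome is a forced `−1`,
the cost of abandoning the trajectory. The decision rule is a fixed
threshold: reset iff `V(σ_t) < θ` with `θ = −0.5`. Three baselines — a
calibrated random policy, an empirical good-frequency rule, and tabular
Q-learning over signatures — share the environment, oracle, protocol and
log schema.

## Worked example

```r
library(pixssm)

logs <- run_experiment(ssm_agent(),
                       protocol_config(steps = 100, n_runs = 30,
                                       base_seed = 1))
summarize_experiment(logs)
#> <experiment_summary: ssm agent, 30 runs>
#>   total_resets       1.67 ± 1.95
#>   prop_good          0.26 ± 0.06
#>   top_avg_valence   -0.36 ± 0.22
```

Over 30 independent runs of 100 steps the marker agent resets about 1.7
times per run, spends 26% of steps in good (≤ 3 active cells) states —
essentially the stationary good-rate `130/512 ≈ 0.254` of an untouched
grid, achieved while resetting two orders of magnitude less than the
degenerate frequency baseline — and the three most-visited signatures end
each run with clearly negative valence (≈ −0.36): the agent has learned
which compressed states precede bad outcomes without ever seeing the
oracle's rule.

Comparing all four agents under one protocol:

```r
p <- calibrate_reset_prob(logs)        # SSM marginal reset rate, ≈ 0.017
summaries <- list(
  ssm    = summarize_experiment(logs),
  random = summarize_experiment(run_experiment(random_agent(p),
             protocol_config(base_seed = 2001))),
  freq   = summarize_experiment(run_experiment(frequency_agent(),
             protocol_config(base_seed = 1001))),
  qlearn = summarize_experiment(run_experiment(qlearning_agent(),
             protocol_config(base_seed = 3001))))
make_tables(summaries)
#>    agent        resets   prop_good   top_valence
#>      ssm   1.67 ± 1.95 0.26 ± 0.06 -0.36 ± 0.22
#>   random   1.40 ± 1.19 0.24 ± 0.06 -0.05 ± 0.06
#>     freq 100.00 ± 0.00 0.00 ± 0.00 -0.10 ± 0.00
#>   qlearn  31.33 ± 3.95 0.20 ± 0.06 -0.19 ± 0.14
```

The frequency rule provably degenerates (a cold start plus the forced −1
on reset means no signature's good-frequency ever exceeds 0.5), and the
Q-learner's row is qualitative — its hyperparameters are conventional
defaults, not tuned values. `run_sweep()` runs the 27-cell
`α × θ × flip_prob` sensitivity grid and `failure_diagnostics()` screens
logs for excess resetting, low-valence cycles and signature aliasing. See
`vignettes/synthetic-somatic-markers.Rmd` for the full account of the
model, metric definitions and known limitations.

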
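# cbgtpolicy

Spiking cortico-basal-ganglia-thalamic (CBGT) networks, dopamine-dependent
corticostriatal plasticity, and the analysis pipeline that links circuit
activity to decision policies.

## The scientific problem

When an animal learns which of two options pays off, it does not just become
more accurate — it also changes *how* it decides: how much evidence it
requires, how quickly it engages, and how strongly it commits. In
drift-diffusion model (DDM) terms, learning moves an agent through a space of
decision policies parameterized by the drift rate `v` (evidence quality), the
boundary height `a` (evidence required), and the onset time `t` (engagement
latency). The question this package addresses by simulation: when a simple
dopaminergic plasticity rule at corticostriatal synapses drives learning in a
biologically structured spiking CBGT circuit, which behavioral objective do
the resulting policy changes follow — speed, accuracy, or reward rate
(accuracy per unit time, `RR = (1 - p(err)) / RT`)? And through which
low-dimensional circuit *control ensembles* (responsiveness, pliancy, choice)
are those changes expressed?

The package is aimed at computational neuroscientists who want a desk-scale,
fully scripted version of this modeling program: every stage — network
simulation, learning protocol, parameter search, DDM fitting, manifold
analysis, canonical-correlation ensembles, driver decomposition — is an
exported, tested function.

## What is inside

* **Spiking network** (`network_params()`, `build_network()`,
  `simulate_trial()`): two action channels of conductance-based
  integrate-and-fire populations (Cx, CxI, FSI, dSPN, iSPN, GPe, STN, GPi,
  thalamus) with Ornstein-Uhlenbeck background drive, a ramping cortical
  stimulus input, and a 30 Hz thalamic threshold decision rule. Compiled
  core; a full trial simulates in tens of milliseconds.
* **Plasticity** (`plasticity_params()`, `update_traces()`,
  `update_eligibility()`, `update_weight()`, `f_kda()`, `reward_event()`):
  spike-timing eligibility traces gated by a phasic dopamine signal built
  from the reward prediction error, with soft-bounded multiplicative weight
  updates — potentiating eligible direct-pathway synapses and depressing
  indirect-pathway ones under positive feedback, and conversely.
* **Task protocol** (`run_session()`, `classify_speed()`,
  `outcome_sequence()`): 15-trial two-armed bandit sessions with frozen
  probe blocks after 0, 2, 4, 6 and 15 learning trials.
* **Genetic algorithm** (`grid_values()`, `ga_decode()`, `ga_mate()`,
  `ga_mutate()`, `ga_evolve()`): binned-index search over synaptic
  efficacies under timeout, corticostriatal-correlation, and firing-rate
  constraints.
* **DDM engine** (`simulate_ddm()`, `fpt_density()`, `fit_ddm_mle()`,
  `qq_check()`): exact first-passage-time likelihood (small/large-time
  series), profile-likelihood fitting, quantile-based fit checks.
* **Policy manifolds** (`build_manifold()`, `gradient_at()`,
  `cosine_distance()`, `compare_objectives()`): RT/accuracy/reward-rate
  surfaces over `(v, a)` and gradient-alignment scoring of learning
  trajectories.
* **Control ensembles** (`build_features()`, `fit_cca()`,
  `label_ensembles()`): canonical correlation between 16 firing-rate
  features and fitted DDM parameters, with k-fold and shuffle-null
  component selection.
* **Drivers** (`pca_delta()`, `project_delta()`, `solve_drivers()`,
  `weighted_driver()`, `sequence_drivers()`): the least-squares (normal
  equation) decomposition `S = (C'C)^{-1} C'P` of learning-induced
  firing-rate changes into control-ensemble contributions, including the
  two-trial outcome-sequence analysis (U-U, U-R, R-U, R-R).
* **Synthetic surrogates** (`gen_cca_cohort()`, `gen_driver_cohort()`,
  `gen_ddm_cohort()`, `gen_toy_network()`): seed-deterministic generators
  with planted structure that make every estimator testable without spiking
  simulation.

The `analysis/` directory holds the numbered study drivers
(`01_sample_networks.R` … `06_drivers.R`); each writes plain CSV/JSON under
`results/`. `run_study()` orchestrates the same stages from one master seed
with per-stage checkpointing.

## Worked example

Simulate a naive network, run one learning session, and fit its decision
policy per stage:

```r
library(cbgtpolicy)

net <- build_network(network_params(seed = 3))
session <- run_session(net, plasticity_params(),
                       session_config(probe_trials_per_stage = 100L,
                                      seed = 7))
session_stage_summary(session)
```

```
  stage   n  accuracy mean_rt_s reward_rate
1     0  99 0.5050505 0.3662283    1.379059
2     1 100 0.7500000 0.2801910    2.676746
3     2 100 0.7900000 0.3170130    2.492011
4     3  99 0.7272727 0.3935879    1.847803
5     4 100 0.9100000 0.3009430    3.023828
```

Stage 0 is the naive network: accuracy at chance (0.51 over 99 decided
probe trials). Over the four freeze stages (after 2, 4, 6 and 15 learning
trials) accuracy climbs to 0.91 while the reward rate (accuracy per second)
roughly doubles; individual stages wobble because each probe block is only
100 trials. Fitting the DDM to the first and last probe blocks shows the
policy change — the drift rate grows from near zero to about 3 while the
boundary height and onset time barely move:

```r
f0 <- fit_ddm_mle(behavior_from_session(session, 0))
f4 <- fit_ddm_mle(behavior_from_session(session, 4))
rbind(baseline = unlist(f0$params[c("v", "a", "t0")]),
      trained  = unlist(f4$params[c("v", "a", "t0")]))
```

```
             v     a    t0
baseline 0.024 0.851 0.187
trained  3.116 0.826 0.192
```

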
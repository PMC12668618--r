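---
title: "Dopaminergic plasticity and decision policies in a spiking CBGT network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dopaminergic plasticity and decision policies in a spiking CBGT network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbgtpolicy)
```

# Overview

`cbgtpolicy` simulates value-based learning in a two-channel spiking model of
the cortico-basal-ganglia-thalamic (CBGT) circuit and provides the analysis
chain that turns the resulting behavior into statements about *decision
policies*: drift-diffusion model (DDM) fits per learning stage, policy
manifolds over drift rate `v` and boundary height `a`, canonical-correlation
*control ensembles* linking firing-rate features to DDM parameters, and a
least-squares decomposition of learning-induced firing-rate changes into
control-ensemble *drivers*. This vignette records the model, its assumptions,
the tunable constants and their defaults, and the design decisions taken where
the design was genuinely open.

# The spiking network

Nine cell types are modeled: excitatory cortex (Cx), inhibitory cortex (CxI),
striatal fast-spiking interneurons (FSI), direct- and indirect-pathway spiny
projection neurons (dSPN, iSPN), external and internal globus pallidus (GPe,
GPi), subthalamic nucleus (STN), and thalamus. All except CxI and FSI are
duplicated into two *action channels*; the two channels share all efficacies
and mirrored connectivity masks, so a naive network is exactly
channel-symmetric and its choice probabilities are 0.5 by construction.

Neurons are conductance-based leaky integrate-and-fire units,

$$\tau_m \dot V = -(V - V_L) - g_{AMPA}(V - V_E) - g_{GABA}(V - V_I) -
  S_{ext}(V - V_E),$$

with exponential synapses (AMPA 2 ms, GABA 5 ms), threshold −50 mV, reset
−55 mV, and short refractory periods. The external drive `S_ext` is a
mean-reverting (Ornstein–Uhlenbeck) conductance whose stationary mean and
variance are those of Poisson bombardment at rate `f_ext` over `N_ext`
connections of efficacy `E_ext`:

$$\mu = 10^{-3} E\, f\, N\, \tau, \qquad
  \sigma = E \sqrt{5\times10^{-4} f N \tau}, \qquad
  dS = \frac{\mu - S}{\tau}dt + \sigma\sqrt{2/\tau}\, dW.$$

The diffusion scaling $\sigma\sqrt{2/\tau}$ is the standard choice that makes
the stationary law Normal($\mu$, $\sigma^2$). The external connection count defaults to `N_ext = 100` per neuron:
with the matched Poisson statistics above this places every population in a
fluctuation-driven regime (coefficient of variation of the drive near 1),
which keeps population rate-versus-input curves smooth — a mean-driven
configuration turns them into near-step functions and makes the genetic
search needlessly brittle. Per-region `E_ext` defaults were calibrated once so
baseline rates sit at conventional values (Cx ≈ 5, CxI ≈ 8, FSI ≈ 12,
SPN ≈ 2, GPe ≈ 60, STN ≈ 15, GPi ≈ 70, thalamus ≈ 4 Hz) and were then frozen.

## Trials and the decision rule

Each trial starts from a 200 ms warmed-up baseline. After an input-onset
latency (150 ms by default, standing in for upstream sensory processing and
conduction delays; reaction times are measured from trial start and include
it), both cortical populations receive an identical ramping input
$f_{ext}(t) = f_{baseline} + f_{ramp}(t)$, with $f_{baseline}$ drawn per
trial from Normal(2.5, 0.06) Hz (clipped at zero) and

$$f_{ramp}(t) = f_{ramp}(t - \Delta) + 0.1\,[f_{target} - f_{ramp}(t-\Delta)],
  \qquad f_{target} = 1.$$

The recurrence is applied once per millisecond of simulated time
($\Delta = 1$ ms): the printed per-step form would otherwise make the ramp's
time course depend on the integrator step (0.1 ms Euler by default), and the
per-millisecond reading is the only step-size-invariant one.

A choice is registered for the first channel whose thalamic population rate
estimate reaches 30 Hz; a trial with no crossing within 1000 ms is a timeout.
The rate estimate is an exponentially smoothed population spike count. Its
smoothing constant defaults to 25 ms: with the 20-neuron thalamic populations
used at desk scale, a 5 ms window has a standard deviation of several Hz at
baseline and produces frequent false threshold crossings, so the crossing
would reflect estimator noise rather than sustained thalamic activation.

Because evidence is identical for the two channels, choices arise from noise
amplified by the network's winner-take-all loop (cortex → dSPN → GPi ↓ →
thalamus ↑ → cortex/striatum). The default efficacies place this loop just
below self-ignition at baseline and above it once the ramp arrives, which is
what produces realistic, right-skewed reaction-time distributions
(≈ 410 ± 190 ms at default parameters, including the 150 ms onset latency)
rather than instant transitions.

## Dopamine-dependent corticostriatal plasticity

Each corticostriatal synapse carries spike traces `A_PRE`, `A_POST`
(exponential decay, fixed increments per spike), an eligibility trace

$$\dot E = \big(X_{POST} A_{PRE} - X_{PRE} A_{POST} - E\big)/\tau_E,$$

a conductance that jumps by the current weight at each presynaptic spike, and
a soft-bounded weight

$$\dot w = \big[\alpha_w E f(K_{DA})(w_{max} - w)\big]_+ +
           \big[\alpha_w E f(K_{DA})(w - w_{min})\big]_-,$$

with $\alpha_w > 0$ for dSPN targets and $\alpha_w < 0$ for iSPN targets, and
$f(K_{DA})$ the piecewise-linear dopamine gain (slope $\gamma/\mu$, saturating
at $-\gamma$ for dSPN below $-\mu$ and at $\varepsilon\gamma$ for iSPN above
$\mu$). After each decision the reward prediction error $r - Q_i$ updates the
chosen action's value ($\alpha_Q$) and moves the dopamine pool $K_{DA}$
toward the increment by the fraction `c_scale` (the literal integral of the
impulse formulation; an alternative "pure increment" semantics exists, and
the literal reading is used). The
trial continues for a 300 ms feedback window after the decision so that the
phasic dopamine acts on the eligibility left by the decision itself; between
trials $K_{DA}$ decays over the inter-trial interval.

The numerical constants of this rule are all configuration parameters.
Defaults were chosen once against the intended operating regime — learning
saturates within about 15 trials and cohort accuracy approaches ≈ 90 % —
and then frozen:
`tau_pre = tau_post = 20 ms`, `d_pre = 15`, `d_post = 5`, `tau_e = 150 ms`,
`tau_da = 200 ms`, `c_scale = 1`, `gamma = mu = 1`, `eps = 0.5`,
`alpha = ±0.2`, `w ∈ [0, 0.08]` (initial 0.04), `alpha_q = 0.2`. Two of these
deserve comment:

* `d_pre > d_post` biases eligibility toward potentiation of co-active
  pairs. With symmetric increments the expected eligibility of uncorrelated
  pre/post trains is exactly zero and learning rides only on the (weak)
  causal spike correlations; the asymmetric default gives eligibility a
  rate-covariance (Hebbian) component, concentrated on the winning channel
  because its SPNs fire most around and after the decision.
* Action values start at `Q = 0.5`, an uninformed prior midway between the
  possible rewards, so that both early successes (positive prediction error)
  and early failures (negative prediction error) drive plasticity from the
  first trial — with `Q = 0` an unrewarded first choice would generate no
  teaching signal at all.

Operator ordering within a time step is traces → eligibility → conductance →
weight; delta-function terms are discrete jumps at spike times. The identical
equations run inside the compiled session simulator and in the exported
pure-R reference operators (`update_traces()`, `update_eligibility()`,
`conductance_step()`, `update_weight()`, `f_kda()`, `reward_event()`), which
define the semantics and are what the unit tests exercise against closed
forms.

# Task protocol

Sessions implement a deterministic two-armed bandit (reward probability 1 for
the optimal channel, 0 for the other, both configurable) over 15 learning
trials, frozen after 2, 4, 6 and 15 trials for probe blocks (plasticity off;
weights bit-identical before and after, which is tested). A baseline probe
block precedes learning. Probe blocks default to 300 trials; the desk-scale drivers and tests use 40–80 per stage and state so
where they do. Networks are classed fast / intermediate / slow by an
equal-count tertile split of baseline mean reaction times. Between-channel
difference features are aligned as rewarded-minus-unrewarded after learning
and channel 1 − channel 2 at baseline, where no reward is defined.

# Genetic-algorithm sampling

Free efficacies (corticostriatal, striatopallidal, pallido-nigral,
pallido-subthalamic, subthalamo-pallidal, nigro-thalamic and thalamocortical
projections, nine parameters by default) are discretized onto 30-point
endpoint-inclusive grids spanning ±30 % multiplicative bands around the
default efficacies; genomes are index vectors, so crossover (one-point,
offspring overwrite parents) and mutation (index shuffling, probability 0.2)
can never leave the declared ranges. Tournament selection (size 3) uses
lexicographic fitness: timeout fraction first, then corticostriatal
correlation — the lexicographic order reflects that policy fits are
impossible without decided trials, so timeouts dominate.
A candidate is archived when, over its evaluation probe block, (a) fewer than
1 % of trials time out, (b) the Pearson correlation between binned summed
excitatory cortical rate and binned summed dSPN+iSPN rate is positive
(the circuit is basal-ganglia-driven, not cortico-thalamic), and (c) all
trial-averaged region rates lie within a configurable physiological table
(reconstructed defaults; see `default_rate_ranges()`). The acceptance
correlation uses summed excitatory cortex against summed SPN activity over
whole trials; the per-channel alternative is not used.

# DDM engine

Probe behavior (rewarded channel = upper boundary; seconds; timeouts
dropped) is fit by maximum likelihood with the exact first-passage-time
density of the two-boundary diffusion (small/large-time series with
automatic truncation, validated against closed-form absorption probabilities
and simulation). Hierarchical Bayesian fitting is the common choice for such
cohorts; because every network is fit independently here, per-network MLE
yields the same per-network point estimates without cross-network pooling. `sigma` is
fixed at 1 and `z` at 0.5 (networks are constructed unbiased); `t0` is
constrained below the smallest observed RT by a logistic transform and `a`
kept positive by a log transform; five Nelder–Mead starts with moment-based
initialization guard against local optima. Goodness of fit is summarized by
the Pearson correlation of choice-signed RT percentiles (5, 10, …, 95)
between observed and model-generated samples (`qq_check()`). No inter-trial
variability parameters are included.

# Policy manifolds and gradient alignment

`build_manifold()` estimates mean RT, accuracy and reward rate
(`RR = accuracy / RT`, RT in seconds) on a `(v, a)` grid by DDM simulation
(15 seeds × 200 trials per node by default; the desk-scale drivers use 5 × 200
and say so), with `t0` and `z` fixed at cohort baseline means. Surfaces are
smoothed with a 3-node moving-average kernel before central-difference
gradients — finite differences on unsmoothed Monte-Carlo surfaces are
dominated by node noise.
Gradients are interpolated bilinearly and evaluated at each step's start
point (the alternative midpoint convention is not used); the RT gradient is
negated so that every objective's gradient points toward improvement.
Alignment of a trajectory step with an objective is the cosine distance
`1 − cos(angle)`, invariant to rescaling of either vector. `compare_objectives()`
pools one observation per (network, stage) and reports a one-way
repeated-measures F-test across the three objectives plus paired t-tests.

# Control ensembles

The feature matrix has 16 columns: channel sums and aligned channel
differences for Cx, dSPN, iSPN, GPe, STN, GPi and thalamus, plus the shared
CxI and FSI rates. Features and DDM parameters `(a, t, v)` are standardized
(means and scales recorded, and reused later so that firing-rate *changes*
live in the same basis: a common basis is required for the projections to be
comparable across stages and classes). `fit_cca()` wraps
`stats::cancor` with 4-fold held-out canonical correlations and a
row-shuffle null; components whose mean held-out correlation exceeds the
null mean + 2 SD are retained (the operationalization of "the set of
components giving rise to the maximum CCA score"). Reported loadings are
*structure* loadings — correlations between each variable and the canonical
variate, unit-normalized, signs fixed so the largest-magnitude feature
loading is positive. Structure loadings are preferred over raw canonical
weight vectors because the weights involve the inverted feature covariance
and are unstable at realistic cohort sizes, while the structure pattern is
what loading plots display; the weight vectors are also returned. For
cohorts with fewer rows than features the feature block is first reduced to
its leading principal components (with a warning); this is a small-cohort
safeguard, not the intended operating regime. Components are labeled
responsiveness (`a` and `t` loadings share sign), pliancy (opposing signs)
or choice (dominated by `v`); unresolved patterns are flagged, never forced.

# Drivers

Learning-induced feature changes ΔF (post − pre, divided by the baseline
feature scales) are decomposed per cohort or per class X ∈ {all, fast,
intermediate, slow}: `P = ΔF V` (top-5 PCs of ΔF; always 5, even when fewer
suffice, for cross-class comparability), `C = ΔF U` (U = baseline ensemble
loadings of the **full** cohort, also for class-restricted analyses), and
`S = (CᵀC)⁻¹CᵀP` from the normal equation, with a condition-number check and
a flagged pseudo-inverse fallback. Net per-ensemble drivers are the
variance-fraction-weighted column sums of S. Reconstruction quality is the
Spearman rank correlation between actual and reconstructed PC projections.
The outcome-sequence analysis groups networks by the reward labels of their
first two learning trials (U-U, U-R, R-U, R-R; a timed-out learning trial
counts as unrewarded), recomputes ΔF → S → weighted drivers per group from
the 2-trial freeze, and summarizes reward-rate changes (always against the
naive baseline, not between consecutive stages) with a two-way ANOVA
(sequence × speed class) and pairwise t-tests. Groups smaller than five
networks are flagged and skipped.

# Synthetic surrogates

Because the ensemble and driver analyses are population-level (hundreds of
networks at full scale), those stages are tested primarily on latent-factor
surrogates with known structure: `gen_cca_cohort()` plants orthonormal
feature/policy loadings driven by shared factors with distinct scales
(defaults 2, 1, 0.5; distinctness keeps individual factor directions
identifiable rather than only their span) and observation noise 0.2 — chosen
so that canonical correlations are well separated and recovery tests are
sharp without being brittle; `gen_driver_cohort()` builds ΔF from a known
driver matrix inside an orthonormal 8-dimensional frame so the
projection-plus-normal-equation pipeline recovers it exactly in the
noiseless case; `gen_ddm_cohort()` draws behavior from known DDM parameters;
`gen_toy_network()` returns symmetric or deterministically biased network
parameterizations. What these surrogates do *not* emulate: the joint
distribution of real spiking cohorts, nonlinear feature/parameter
relationships, and fit noise correlated across stages — passing recovery
tests therefore validates the estimators, not the biological claims.

# Problem sizes and numerical choices

The desk-scale study (`run_study()`, `analysis/` scripts, and the acceptance
checks) uses populations of tens of neurons (330 in total), cohorts of ~10
GA-accepted networks, 40–80 probe trials per stage, 12×12 manifold grids with
5 seeds × 200 trials per node, and 50-permutation CCA nulls; these sizes were
chosen so a full pass completes on a single CPU in minutes while leaving
every qualitative contrast testable. Integration is fixed-step Euler at
0.1 ms; DDM simulation uses Euler–Maruyama at 1 ms (manifolds) or 0.1 ms
(oracle checks). The trial simulator draws its high-volume background noise
from a xoshiro256+ stream seeded from R's RNG, so all results are
reproducible under `set.seed()` while the integration stays fast. Weight
bounds are enforced both by the multiplicative rule and by a final clamp
against floating-point overshoot. Ties in the speed tertile split are broken
by input order; `cosine_distance()` refuses zero vectors; degenerate DDM
samples (single choice, < 50 trials) are flagged as weakly identified rather
than refused.

# Known limitations

* Population sizes are far below biological counts; rate fluctuations are
  correspondingly larger, and probe blocks of a few dozen trials give noisy
  DDM parameter estimates (especially `a`).
* Ensemble recovery on spiking cohorts of ~10 networks is under-determined
  (16 features); the CCA stage is quantitatively meaningful only at larger
  cohort sizes or on the surrogate generators.
* The neuron model is a single-compartment conductance-based LIF without
  NMDA dynamics; no plasticity exists outside the corticostriatal
  projections; only two action channels are supported.
* The plasticity constants are calibrated defaults, not measured values;
  conclusions that depend on their precise values (e.g., the exact trial at
  which learning saturates) should be read accordingly.
* Independent per-stage maximum-likelihood DDM fits sit on a nearly flat
  boundary/onset trade-off ridge when decision-time distributions are short
  and narrow, so stage-to-stage estimates of `a` and `t0` carry substantial
  ridge noise at probe-block sizes of a few hundred trials (hierarchical
  pooling, which the full-scale study used, shrinks exactly this ridge). The
  fitter therefore profiles the likelihood over the onset time, which makes
  convergence robust but cannot remove the underlying flatness.
* At the parameter scales this desk-scale cohort occupies (baseline drift
  near zero, boundary 0.6–1.2, short decision times), the reward-rate
  surface gradient is strongly boundary-dominated while the accuracy
  gradient at zero drift points purely along the drift axis. Learning steps
  are predominantly drift growth, so pooled over all stages the trajectories
  align *best* with the accuracy gradient here, with the reward-rate
  gradient winning only in the middle stages where accuracy has saturated
  and speed is still improving; at full scale (hundreds of networks in a
  different region of the policy space) the reward-rate gradient is less
  boundary-dominated, and the overall reward-rate-first ordering is
  reproduced here against RT but not against accuracy.
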
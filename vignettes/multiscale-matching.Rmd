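---
title: "Multi-timescale reward integration and undermatching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale reward integration and undermatching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtforage)
```

## The scientific problem

In a dynamic foraging task an animal chooses repeatedly between two color
targets rewarded on a concurrent variable-interval (baiting) schedule: each
target is stochastically armed with a reward at a rate that is constant
within a block of trials, and an armed target keeps its reward until chosen.
The two baiting rates sum to about 0.35 rewards per trial, their ratio is
drawn unpredictably from {8:1, 6:1, 3:1, 1:1} at unsignalled block changes,
and a changeover delay (COD) withholds reward on the first choice after a
switch. Under this schedule the matching law — allocating choices in
proportion to obtained rewards, a unit slope of block-wise choice fraction
against reward fraction — is the optimal stochastic policy when the rates
are known and fixed. Real subjects systematically *undermatch* (slope below
one), and this package implements a quantitative account of why: an agent
that combines reward integrators with fast and slow time constants trades a
bias toward the long-run balanced reward distribution (undermatching)
against the variance of its value estimates, and the tradeoff has an
interior optimum in a volatile world.

## The choice model

Each target's local income on timescale $\tau_i$ is a leaky integrator of
its reward stream,
$$I^t_i = \left(1 - \tfrac{1}{\tau_i}\right) I^{t-1}_i +
  \tfrac{1}{\tau_i}\, r^{t-1},$$
updated every trial for both targets, with $r = 1$ only for a rewarded
choice of that target. The decision variable per target is the weighted sum
$I = \sum_i w_i I_i$ with simplex weights, and choice follows the local
matching rule $P_G = I_G / (I_G + I_R)$ (0.5 when both incomes are zero).
With a single timescale this is the classic single-integrator matching
model; the package's interest is in a slow integrator whose
$\tau_{\text{slow}}$ far exceeds the block length, so its incomes are nearly
equal for the two targets and pull choice toward indifference by the
first-order relation $1 - S \propto w_{\text{slow}}
(I^{\text{slow}}_G + I^{\text{slow}}_R)$.

### Simulator policy: committed switches and a lapse floor

Two policy-level details of `run_session()` deserve explanation, because
the bare ratio rule does not by itself produce sustained matching:

* **Committed switches.** With the COD enabled, the trial after a switch
  repeats the new color and is flagged as not free. Trained subjects behave
  exactly this way (completing switches far more often than chance), and
  the analysis convention of treating the first two choices of a switch as
  a single free choice then becomes literal in the simulator.
* **Lapse floor.** Sampling probabilities are clipped to
  $[p_{\text{floor}}, 1 - p_{\text{floor}}]$ with $p_{\text{floor}} = 0.01$.
  Between rewards both targets' incomes decay at the same rate, so the
  income *ratio* drifts monotonically away from parity; without a floor a
  purely fast agent is absorbed into exclusive choice (the lean target's
  income underflows and the agent never samples it again), which is neither
  what subjects do nor the matching regime of interest. A 1% lapse keeps
  the lean target minimally sampled; the agent's internal incomes are not
  touched, and the floor applies only to the sampling policy.

The initial income is `total_bait_rate / 2` per target and timescale — an
unbiased start at the schedule's mean payoff.

## Harvesting efficiency

Efficiency is rewards obtained divided by the maximum collectable. Because
baits never expire, an ideal harvester collects every bait the schedule
arms, and arming pauses only while a bait is waiting; the ceiling over $n$
trials is therefore `total_bait_rate * n` up to 1–2% of edge effects, and
that product is the denominator. The count of baits the schedule actually
armed during the agent's own session cannot serve: arming is
agent-dependent (an armed target is not re-armed until chosen), so assigned
baits equal delivered rewards plus at most one pending bait per target for
*any* agent, and the ratio would be identically close to one.

## Bias–variance analysis

The reduced inference problem (`estimation_task()`) is to track a Bernoulli
reward probability that steps through the block reward levels
$0.35 \times \{8/9, 6/7, 3/4, 1/2\}$ every $L$ trials. For the
two-timescale estimator
$\hat p_t = (1 - w) I^{\text{fast}}_t + w I^{\text{slow}}_t$ the first and
second moments obey exact linear recursions (means, variances, and the
cross-covariance of the two filters each follow an AR(1)-type law driven by
$p_{t-1}$ and $p_{t-1}(1 - p_{t-1})$), which `moment_recursion()`
propagates and time-averages over one deterministic cycle of blocks after a
ten-block burn-in. The decomposition `mse = bias² + variance` holds exactly
at every grid point, and `monte_carlo_moments()` provides the independent
stochastic cross-check.

Defaults are $\tau_{\text{fast}} = 5$ and $\tau_{\text{slow}} = 1000$
trials. The slow constant sits *between* the two volatility conditions
analyzed ($L = 100$ and $L = 10{,}000$): that is what makes the stable
condition reward slow integration more than the volatile one (a larger
MSE-minimizing $w_{\text{slow}}$) while both optima remain interior. A much
faster fast filter ($\tau = 2$) is so noisy that the stable optimum reaches
the boundary, and a slow constant far beyond both block lengths erases the
distinction between the conditions.

## Per-session model fitting

`fit_session()` fixes the time constants at 2, 20, and 1000 trials and
estimates only the simplex weights, by BFGS on a softmax reparameterization
with random restarts. Because the per-timescale income trajectories do not
depend on the weights, they are filtered once per session and each
likelihood evaluation is a vectorized pass over free choices with
probabilities clipped at $10^{-6}$. Only the slow integrator's final
incomes carry over as the next session's initial condition; the fast
integrators restart at the unbiased initial income. Degenerate sessions
(every scored choice the same color) are returned flagged rather than as
errors, since they carry no information about the weights.

The identifiability confound is reproduced as stated: datasets generated by
the random-bias alternative (fast integration plus session-random additive
color biases, `bias_agent()`) also yield a significant correlation between
the fitted slow weight and undermatching, so session-level fits cannot by
themselves attribute undermatching to slow reward integration.

## The LMIT statistic

The longest measurable integration timescale asks over how many sessions a
color reward imbalance ($R_G - R_R$ over $N$ trials) still influences the
color choice bias (the matching line's value at reward fraction 0.5, minus
0.5). For each 25-session reference window, Pearson correlations are taken
at session lags 0 through −5, a weighted least-squares line with geometric
weights $0.5^i$ is fitted, and the lag where the line crosses zero — times
the window's mean session length — is the LMIT in trials. Conventions for
degenerate fits: a negative crossing is clamped to 0; a non-negative fitted
slope means no measurable decay, giving 0 if the line starts at or below
zero and the maximum lag (flagged) otherwise. The first 25 sessions are
excluded, so $N$ sessions yield $N - 55 + 1$ windows. Significance uses the
conservative piece-wise permutation test: blocks of five consecutive
sessions are shuffled whole, preserving within-block order and hence
short-range dependence.

Two properties of the estimator shape its use here. First, the
least-squares crossing is invariant to rescaling the correlation profile,
so in the noiseless limit the LMIT depends only on the profile's *shape*.
Second, with realistic per-session bias noise the profile of a weakly slow
agent sinks below the sampling floor at deep lags while a strongly slow
agent sustains it — and this signal-to-noise transition, not the noiseless
shape, is what makes the LMIT grow with $w_{\text{slow}}$. It is in this
sense a *measurable* (lower-bound) timescale. `lmit_weight_sweep()`
therefore averages the lagged correlations over all windows of a dataset
before fitting (single windows are far too noisy), and its default study
condition uses sessions of 5 blocks of 180–200 trials: long enough sessions
that the per-lag decay is steep (about $e^{-1}$ per session at
$\tau_{\text{slow}} = 1000$), few enough blocks that per-session bias
estimates retain the noise level the statistic needs for its graded
response. 85 sessions per dataset give 31 windows after exclusions.

## The cascade (metaplastic synapse) model

Each synapse has binary strength and an ordered plasticity level; a
rewarded choice potentiates the chosen pathway's depressed synapses at
level-dependent rates $\alpha_i$ (landing in the most plastic level) and
deepens already-potentiated ones with metaplastic rates $q_i$; an
unrewarded choice applies the mirror image. Choice is a logistic readout of
the two pathways' potentiated fractions. The mean-field occupancy update is
the default engine; a binomial per-synapse engine (`n_synapses`) provides
the stochastic cross-check.

For the multi-day experiment, `cascade_experiment_params()` uses five
levels in two tiers: a plastic tier (rates 0.5, 0.25) that tracks rewards
within blocks, and a consolidated tier entered through a slow bottleneck
($q_2 = 5 \times 10^{-4}$) whose own strength-transition rates are tiny.
The geometry matters: if deepening rates ride the same ladder as the
strength rates, consolidation either completes within the first day or
loses the race against strength flips and never happens; a slow bottleneck
into a sticky tier is what spreads consolidation over weeks. Deep states
store the long-run — balanced — reward statistics, so as deep occupancy
grows the readout compresses toward indifference: matching is good in early
days and undermatching grows, while choice variance falls. Forgetting
between sessions is modeled as spontaneous activity *not* funneled through
the reward-gated ladder: with probability `forget_rate` per break unit a
synapse resets to the most plastic level at random strength, so occupancies
relax exponentially toward the naive state, long breaks re-plasticize the
network, and the effective integration timescale tracks the recent schedule
(longer recent days lengthen it, longer recent breaks shorten it).

## Synthetic data: what it does and does not emulate

`generate_dataset()` reproduces the structural features the analyses need:
multi-day experiments with several sessions per day, variable inter-day
breaks, block-structured baiting with the task's rate constants, the COD,
and slow drift of the integrator weights across sessions. It does not
emulate eye-movement dynamics, fixation breaks and timeouts, satiety or
motivational trends within a day, or any neural noise beyond the model's
own stochasticity. Passing tests on these data therefore validate the
*computational pipeline* — the estimators recover what the generative
models put in — and the models' qualitative phenomenology; they cannot
certify quantitative agreement with any particular animal's records.

## Numerical choices

* Exponential filters run through `stats::filter` recursions (exact, O(n)).
* Matching fits are ordinary least squares; blocks with fewer than 5
  rewards are excluded by default to limit leverage from extreme reward
  fractions (configurable).
* Choice-variance kernels are causal discrete half-Gaussians
  ($\sigma = 8$ and $50$, span 200 past trials) renormalized to unit sum
  over the available history at the start of a series.
* The likelihood clips probabilities at $10^{-6}$; the optimizer uses
  `reltol = 1e-8`, 5 restarts, and `maxit = 500`.
* All randomness flows through R's global RNG; every entry point that
  simulates documents its draw order, and `run_pipeline()` writes a
  manifest of MD5 content hashes so a seed + config pair is bit-for-bit
  reproducible.

## Problem sizes used by the verification suite

The test suite and `scripts/acceptance.R` run the analyses at desk scale:
100,000-trial sessions for the slow- and fast-limit checks, 15-point weight
sweeps at 100,000 trials per point, 20 recovery fits on 5,000-trial
sessions, 50 replicate 85-session datasets per weight for the LMIT sweep,
1,000 replicate permutation tests for calibration, and a 30-day cascade
experiment. These sizes were chosen so every claim is measured with
meaningful Monte-Carlo precision while a full run stays comfortably on a
laptop.

## Known limitations

* The lapse floor and committed switches are modeling choices for the
  simulator policy; fitted likelihoods ignore the floor (its effect is
  confined to probabilities within $10^{-2}$ of the boundary).
* The LMIT's graded dependence on the slow weight is a signal-to-noise
  phenomenon and hence depends on session structure; configurations with
  very precise per-session bias estimates compress it toward a constant.
* The cascade experiment's rate ladder is calibrated for the multi-day
  protocol simulated here, not fitted to any data.
* With $\tau_{\text{slow}}$ of order $10^4$ trials, 100,000-trial runs
  retain long-memory fluctuations; quantities conditioned on the slow
  income (like the slow-limit mean choice probability) carry Monte-Carlo
  error of a couple of percent at that scale.
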
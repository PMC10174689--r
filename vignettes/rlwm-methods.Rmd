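---
title: "Modeling reinforcement learning and working memory in stimulus-response learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reinforcement learning and working memory in stimulus-response learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When people learn which response a stimulus demands from trial-and-error
feedback, two systems contribute: a slow, capacity-unlimited reinforcement
learning (RL) process that accumulates stimulus-action values from reward
prediction errors, and a fast but fragile working memory (WM) that stores
the last outcome outright and forgets it within a few trials. Because both
systems can solve the same task, behavioral deficits — for example the lower
learning accuracy of older adults — cannot be attributed to either system
from raw accuracy alone. The task this package models dissociates them by
varying the number of concurrent associations per block (the set size, 3 or
6): WM dominates when the load is small, RL when the load exceeds WM
capacity, and a feedback-free test phase after a delay isolates what RL
alone retained.

`rlwm` implements the full analysis pipeline around this design: the task
generator, the hybrid RL-WM computational model and its likelihood,
hierarchical Bayesian estimation in three variants with WAIC comparison,
parameter-recovery and posterior-predictive validation, model-independent
trial-level regressions, and a cross-validated elastic-net pipeline linking
regional neurochemical measures (glutamate in particular) to the model's WM
parameters. A synthetic-cohort generator supplies data with the full
latent structure so that every stage is testable end to end.

## The RL-WM model

Per block, both modules start at the uniform expectation
$Q_0 = W_0 = 1/n_A$. After choosing action $a$ for stimulus $s$ and
receiving $r \in \{0, 1\}$:

* RL: $\delta = r - Q(s,a)$; $Q(s,a) \mathrel{+}= \alpha^+ \delta$ if
  $\delta > 0$, else $\alpha^- \delta$.
* WM: a positive WM prediction error stores the outcome in one shot,
  $W(s,a) \leftarrow r$; a non-positive one moves $W$ toward $r$ by
  $\nu = \alpha^-/\alpha^+$ (the same relative neglect of negative feedback
  as in RL; $\nu$ may exceed 1 and $W$ is deliberately not clamped).
* Decay: every WM weight except the pair just observed relaxes toward
  baseline, $W \mathrel{+}= \phi\,(W_0 - W)$. At $\phi = 0.174$ an
  association retains $1-\phi = 82.6\%$ of its above-baseline strength per
  trial; at $\phi = 0.324$ it forgets roughly twice as fast.

Choice follows a lapse-mixed mixture of two softmax policies sharing the
learning-phase inverse temperature $\beta_L$:

$$P = (1-\epsilon)\left[\omega_{nS}\,\mathrm{softmax}(\beta_L W(s,\cdot))
 + (1-\omega_{nS})\,\mathrm{softmax}(\beta_L Q(s,\cdot))\right]
 + \epsilon/n_A.$$

The WM reliance $\omega_{nS}$ is set-size specific ($\omega_3$,
$\omega_6$). Test-phase choice uses only the Q-values frozen at the end of
each learning block, with its own temperature $\beta_T$ and the same lapse
rate; WM, $\phi$ and $\beta_L$ play no role there, which the test suite
verifies as a likelihood invariance.

**Order of operations.** The displayed update equations do not fix whether
decay precedes or follows the current trial's update. We decay first
(exempting the observed pair) and then apply both updates to the observed
pair: the exemption of "the association seen on the current trial" is only
meaningful if decay acts on the trial where that pair is observed.

**Missed trials.** Responses slower than the deadline are recorded as
missed: they contribute no likelihood and trigger no state update, matching
the exclusion of such trials from all analyses.

## Task generator

The default session has 10 independent blocks (6 of set size 3, 4 of set
size 6), a novel stimulus set per block, 9 presentations per stimulus, 3
response keys counterbalanced so each is correct for exactly one third of
the 42 stimuli, and a shuffled test sequence presenting every learned
stimulus 4 times (the number of test repetitions is not fixed by the
design; 4 is the package default, chosen for estimation stability).

Within a block the presentation order is pseudo-randomized so that the
delay between successive presentations of the same stimulus is approximately
uniform over its design support $1 \dots 2\,nS-3$ (mean $nS-1$, the value
forced by the counting identity; immediate repeats are excluded). The
generator builds the sequence from rounds — each round a permutation of all
stimuli — and flattens the pooled delay histogram by a seeded local search
over within-round swaps, capped at 4000 proposals with the best sequence so
far accepted. For set size 3 the search routinely reaches an exactly flat
histogram (8 delays each of 1, 2, 3); for set size 6 it reaches the integer
optimum (48 delays over 9 cells). A chi-square goodness-of-fit over 200
seeded blocks per set size is part of the test suite.

## Hierarchical Bayesian estimation

Three hierarchy variants are supported. `flat` places independent priors on
every participant's parameters (unit-interval parameters Beta(2,2),
$\beta_T \sim$ Gamma(2, 0.2)). `single_hierarchy` draws each unit-interval
parameter from a group-level Beta$(1+a, 1+b)$ with
$a, b \sim$ Gamma(2, 0.2) hyperpriors, and $\beta_T$ from a lognormal with
a normal hyperprior on its log-mean (centered on $\log 5$) and half-normal
on its log-sd. `two_group` duplicates those hierarchies per age group,
which is what licenses group contrasts such as
$\Delta\mu_\phi = \mu_\phi^{\mathrm{young}} - \mu_\phi^{\mathrm{older}}$
with equal-tailed 95% credible intervals. In every variant the
learning-phase temperature $\beta_L$ is a single value shared by all
participants of a group, with a Gamma(2, 0.04) prior (prior mean 50,
consistent with the common practice of fixing this parameter to a large
value); letting the data pick it is strictly more flexible than fixing it.
All hyperprior constants are package defaults, configurable through
`prior_spec()`.

**Sampler.** Estimation uses an adaptive Metropolis-within-Gibbs sampler
written in C++: single-site random-walk proposals on unconstrained scales
(logit for unit-interval parameters, log for temperatures), with proposal
scales adapted toward a 0.44 acceptance rate during warmup only, so the
post-warmup chain is a valid fixed-kernel MCMC. The group-shared $\beta_L$
and the hyperparameters are the slowest-mixing quantities; the sampler
therefore revisits $\beta_L$ three times and the (data-free, cheap)
hyperparameter conditionals five times per sweep. Thinning is available
(`n_thin`) and used by default in the heavier validation runs. Convergence
is summarized by split-$\hat R$ and an initial-positive-sequence effective
sample size for every parameter; the BFMI and divergence fields of the
diagnostics report exist for Hamiltonian backends and are reported NA/0 by
this sampler. For publication-grade inference one would run the default 4
chains of 500 warmup and 1500 kept sweeps with heavier thinning; the
package's own validation runs use 2 chains of 250/750 to keep the suite
fast, which is sufficient for the posterior means and group contrasts they
check.

**WAIC.** Because successive trials are dependent, the pointwise unit is
one participant-block: a block's learning trials plus its stimuli's test
trials pool into one unit (an alternative with separate test units was
considered and rejected to keep the quoted unit definition literal). WAIC
is $-2(\mathrm{lppd} - p_{\mathrm{WAIC}})$ with the standard
log-mean-exp/variance estimators over draws.

## Validation

`run_recovery()` simulates a cohort from stated hyperparameters, refits the
two-group model, and reports true-vs-recovered correlations and
hyperparameter coverage. On the default conditions (30 per group, decay
means 0.174 vs 0.324) the decay rate recovers at $r \approx 0.85$-$0.9$,
the learning rates at $r \approx 0.7$-$0.87$ across seeds, and the group
decay contrast excludes zero with the correct sign.

A known limitation: the WM reliance parameters recover at only
$r \approx 0.55$ under the default between-participant dispersion. This is
an information ceiling of the design, not an estimation artifact — a profile
maximum-likelihood estimate of $\omega_3$ with every other parameter fixed
at its true value achieves the same correlation on the same cohort. The
hierarchical posterior mean is thus essentially efficient here; studies
needing precise individual $\omega$ estimates would need more trials per
set size or wider true dispersion.

`posterior_predictive_curves()` simulates full sessions from posterior
draws (200 by default) and aggregates accuracy by stimulus iteration, group
and set size; `asymptotic_mean()` summarizes the last three iterations.
`counterfactual_swap()` replays one group with a named parameter replaced
by the other group's posterior group-level mean — the decay-swap experiment
showing how much of the group difference in learning curves decay alone
explains.

## Model-independent statistics

The trial-level GLM predicts accuracy from set size, delay since the last
rewarded presentation of the stimulus, cumulative reward history, trial and
block, fitted per participant as a logistic regression with predictors
z-scored within participant (so coefficients are comparable across
participants), followed by one-sample t-tests on the coefficients. We chose
per-participant fits plus group-level tests rather than a single
random-effects fit because the downstream age regression consumes the
individual coefficients; a mixed model would not supply them directly.
Trials with no prior rewarded presentation (undefined delay) are excluded
rather than imputed. The age regression drops participants any of whose
coefficients lie more than 2 SD above that coefficient's mean. The test
phase mirrors the analysis with its reduced predictor set (reward history
accrued in learning, set size).

## Brain-behavior linking

Candidate predictors are built by averaging each multi-region measure
(glutamate, GABA, NAA, gray matter, white matter) across MFG, IPS and
striatum and keeping cortical thickness (CMF, SF, RMF) region-specific —
eight z-scored candidates. `select_features_cv()` repeats 200 times: a
random 4/5 train / 1/5 validation split, an elastic-net path with equal L1
and L2 weighting on the training fold, and the configuration (nonzero
coefficient set, the intercept-only model included) minimizing held-out MSE
recorded. The final model is the configuration with the lowest mean
held-out MSE among those selected in at least 5% of splits (ties go to the
sparser model), refit by OLS for inference. A sparser one-standard-error
rule and a maximum-nonnull-penalty rule are available as options. Downstream
steps: `brain_predicted_performance()` (fitted values of the selected
model), `map_parameters()` (OLS of those predictions on all seven model
parameters, with VIFs), `anatomical_specificity()` (a parameter on the
three regional glutamate measures, plus a partial correlation controlling
MFG gray matter and creatine), and `mediation_acme()` (nonparametric
percentile-bootstrap product-of-coefficients mediation of the age-decay
path through glutamate; a bootstrap was chosen because it is simple,
assumption-light and fully seeded).

## The synthetic cohort

`cohort_spec()` encodes the emulated study: 36 young (ages
$\mathcal N(21, 4.4^2)$) and 42 older ($\mathcal N(68, 8.5^2)$)
participants; group decay means 0.174 / 0.324; WM reliance above 0.5 for
set size 3 and below for set size 6 in both groups; a positive learning-rate
asymmetry slightly larger in the older group; small lapse rates; shared
$\beta_L$ per group. Dispersions and temperatures were calibrated once so
that simulated mean learning accuracies land near 0.74 (young) and 0.60
(older); with those constants the generator also reproduces, emergently,
the larger set-size gap in older adults and the larger training-to-test
drop in set size 3. Brain measures follow
$\mathrm{glu}_r = b_{0r} - b_{\phi r}\,\phi - b_{a r}\,\mathrm{age} +
\varepsilon_r$ with the MFG coupling strongest and noise calibrated so the
sample Spearman correlation between age and MFG glutamate is about $-0.6$;
nuisance measures (GABA, NAA, glutamine, creatine, volumes, thickness)
decline mildly with age (correlations roughly 0.3-0.5) with modest
inter-metabolite correlation ($\rho \approx 0.3$) but carry no direct
coupling to decay. Per default, 6 young and 18 older participants lack
brain measures. Every latent quantity is recorded in the returned truth
object and serialized by `write_fixture()`.

What the generator does not emulate: response times, the selective neglect
of some stimuli in large set sizes that some older participants show (a
documented misfit of the model), episodic-memory contributions to the test
phase, and any within-participant session effects. Passing tests therefore
demonstrate the pipeline's internal consistency and its sensitivity under
the stated generative structure, not fidelity to any particular empirical
dataset.

## Problem sizes used by the test suite and acceptance script

Routine tests run on shortened sessions and small cohorts; the recovery and
model-selection checks use 30 participants per group with 2 chains of 250
warmup and 750 kept sweeps (thinning 2), and the brain-link checks use the
full 78-participant cohort with 200 cross-validation splits. These sizes
were chosen as the smallest at which the checked properties are stable
across seeds.
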
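---
title: "Methods: learning and evaluating dexmedetomidine dosing policies offline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning and evaluating dexmedetomidine dosing policies offline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dexrl)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open. Nothing here reports an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

# The decision problem

Each ICU admission is modelled as a finite-horizon Markov decision process
on a 6-hour grid — the cadence at which delirium is re-assessed on nursing
shifts, and a horizon short enough for a dose recommendation to still be
actionable.

* **State** `s_t`: a numeric feature vector. The default schema has 16
  features — heart rate, systolic pressure, respiratory rate, SpO2, body
  temperature, FiO2, pH, lactate, creatinine, bilirubin, platelets, WBC,
  hemoglobin, the summed Glasgow Coma Scale, the Richmond
  Agitation–Sedation Scale, and the dexmedetomidine rate administered over
  the previous window (`dex_prev`). Including the previous rate makes the
  titrating behavior policy approximately Markov in the state, which both
  the Q-function and the propensity model rely on. The schema is
  configurable up to the full 35-item inventory such registries carry.
* **Action** `a_t`: the infusion rate discretized into **16 actions**:
  action 0 is "no drug", action *k* covers `(0.1·(k−1), 0.1·k]` mcg/kg/h,
  *k* = 1..15. The clinical literature describes 15 uniform positive
  intervals; we add an explicit zero-dose action because clinicians can and
  do withhold the drug, and observed dosing distributions have mass at
  exactly zero. The inverse mapping returns a bin's upper edge, so
  `discretize_dose(dose_from_action(k)) == k` for all 16 actions.
* **Reward**: terminal only. `r = −1` on the transition into the delirium
  onset step, `+1` on the final transition of a delirium-free stay, `0`
  elsewhere; exactly one nonzero reward per trajectory. Onset is treated as
  **absorbing**: with a single terminal penalty the alternative (penalising
  every delirium-positive step) would break the one-terminal-reward
  structure, so the trajectory ends at onset. Delirium is identified from
  medication records (administration of haloperidol, quetiapine or
  clonidine to treat delirium; the drug set is configurable) — the one
  criterion that needs no chart review.
* **Discount** γ = 0.99, so returns lie in [−1, 1] and the value of
  prevention barely decays over a typical stay (~10–17 six-hour steps).

# Preprocessing

`preprocess_cohort()` turns raw timestamped records into a complete grid:

1. **Binning**: half-open windows `[6t, 6(t+1))` hours from the first
   dexmedetomidine administration; multiple measurements in a window are
   reduced to their median (even counts: mean of the two central values).
   GCS components recorded at one assessment time are summed first; when
   exactly one component is missing it is estimated from a conversion
   table. The shipped table (`extdata/gcs_conversion_synthetic.csv`) is a
   synthetic proportional-allocation stand-in for published tables, which
   are not redistributable.
2. **Outlier removal**: cells strictly outside closed plausibility bounds
   become absent; boundary values are kept. Bounds are part of the feature
   schema.
3. **Follow-up and inclusion**: trajectories run from first exposure to
   discharge, delirium onset, or the start of prolonged deep sedation
   (RASS −4/−5 for more than 24 h, i.e. ≥5 consecutive windows). Admissions
   are rejected — with reason codes, not errors — for age < 18, stays
   < 1 or > 30 days, ECMO, no exposure, or delirium before follow-up start.
4. **Imputation**: interior gaps by time-weighted interpolation (the two
   nearest observations of the same feature in the same admission, weighted
   by inverse time distance); leading/trailing gaps by a seeded
   chained-equations regression over the other features, 10 rounds,
   initialized at cohort medians and clipped to the plausibility bounds.
   Observed cells are never altered, and re-running the chain on a complete
   grid is the identity.

# Conservative Q-learning

The Q-function is a rectified-linear multilayer perceptron mapping the
z-scored state to 16 Q-values (the scaler is fitted on the training
transitions and travels with every checkpoint). The loss is

\[
L(\theta) = \alpha\,\mathbb{E}_{s\sim D}\Big[\log\textstyle\sum_a e^{Q_\theta(s,a)}
  - \mathbb{E}_{a\sim D} Q_\theta(s,a)\Big] + L_{\mathrm{DoubleDQN}}(\theta),
\]

with the Double-DQN term using action selection by the online network and
valuation by a target network synchronized every `target_sync` gradient
steps; terminal transitions regress onto the reward alone. The regularizer
is nonnegative by construction (log-sum-exp dominates any entry) and
vanishes only when the logged action dominates all alternatives; at
α = 0 the loss is exactly the Double-DQN loss. Both identities are tested.

Parameters, defaults, and why:

| parameter | default | note |
|---|---|---|
| hidden layout | 3 × 256 units | full-scale reference architecture; we read "three-layer MLP with 256 hidden dimensions" as three hidden layers — a 256-unit single hidden layer is the plausible alternative reading and is configurable via `qnet_spec()` |
| batch size / epochs / lr | 4096 / 2000 / 6.25e-5 | full-scale reference optimizer settings (Adam) |
| α (conservatism) | 1.0 | the reference work used a library default without stating it; 1.0 is that library's default |
| target sync | 100 steps | unstated in the reference; common practice |
| tie-break | lowest action index | ties resolve toward the lower dose — the conservative clinical choice |

At the desk scales used in tests and the acceptance script (hundreds to a
few thousand admissions, ~10⁴ transitions) those full-scale settings are
mismatched — 6.25e-5 with a handful of gradient steps per epoch barely
moves the network — so the examples use `hidden = c(64, 64)`,
`batch_size = 512`, `epochs = 50–120`, `lr = 1e-3`. These are problem-size
choices, stated here once; the constructors keep the full-scale defaults.

**Checkpoint selection** follows the conservative rule: every
`checkpoint_every` epochs a checkpoint is stored, each is scored on the
validation fold by the bootstrap 95% *lower* bound of its FQE estimate, and
the highest bound wins (ties to the earliest checkpoint; failed evaluations
exclude a checkpoint with a warning).

**Splits** are patient-level: the five 20% test folds tile the cohort (so
per-fold test results can be aggregated), and the remainder of each fold is
re-sampled into 70/10 train/validation. All admissions of a patient share a
partition.

# Off-policy evaluation

**FQE** fits an evaluation Q-network by iterated regression onto
`r + γ Σ_a π(a|s′) Q(s′, a)` (terminal targets = r), then averages
`Σ_a π(a|s₀) Q(s₀, a)` over trajectories. The CI is a percentile bootstrap
over those per-trajectory initial values — it reflects cohort sampling, not
fitting error. Estimates outside ±1/(1−γ) abort as divergence.

**WIS** weights each trajectory by `Π_t π_eval(a_t|s_t) / π_b(a_t|s_t)`
(computed in log space) and reports the weight-normalized mean discounted
return, its percentile-bootstrap CI, and the Kish effective sample size
`(Σw)²/Σw²` of the weights. Kish's formula is our choice: the reference
work cites external methods without printing one, and Kish is the standard
diagnostic with the right edge cases (equal weights → n, one-hot → 1).
Weights are per-trajectory, not per-decision, matching "one sample = one
admission".

**Behavior policy**: multinomial logistic regression of the logged action
on the z-scored state features *plus* the six confounders (age, sex, BMI,
renal replacement, ventilation, shock). Whether state features belong in
the propensity model alongside the confounders was ambiguous; we include
them because the behavior rule is state-responsive and omitting them would
misstate the propensities badly. Predicted probabilities are floored at
1e-4 and renormalized so ratios stay bounded; flooring is logged.
Deterministic evaluated policies are softened first (0.99 on the
recommendation, 0.01 spread uniformly over the 15 others).

**Comparison rule**: policy A is "superior" only if A's 95% lower bound
strictly exceeds B's 95% upper bound; everything else is "not separable".

A caution the synthetic oracle makes vivid: FQE is accurate (the acceptance
suite requires |FQE − truth| < 0.05 on 5000 trajectories) for evaluated
policies whose actions stay inside the behavior policy's support, such as
the softened clinician-mimicking policy. For policies that place even 10%
of their mass uniformly over all 16 actions, the simulator's true value
collapses (extreme doses are genuinely dangerous) while FQE — which has
never seen those state–action pairs — cannot know that, and overestimates.
This is precisely the distributional-shift problem CQL addresses on the
learning side; on the evaluation side the WIS effective sample size is the
honest warning light, and the acceptance suite checks WIS against truth in
bootstrap-SE units for such a broadly softened policy.

# The synthetic cohort

No generative model of the real registries exists, so every simulator
parameter is an artifact choice, fixed once and documented here.

A latent severity `sev_t` follows a stationary AR(1) (coefficient 0.9, unit
marginal variance, shifted upward for shock and renal-replacement
patients). Features are linear emissions `mu_f + load_f · sev_t + noise`
clipped to their plausibility bounds; RASS and GCS respond to the previous
dose (sedation deepens, consciousness falls); a severity *score* computed
from six marker features (heart rate, FiO2, lactate, WBC, platelets,
hemoglobin) makes the hazard and optimal dose functions of the observable
state rather than the latent variable, which keeps the MDP close to fully
observed — deliberately, so that OPE oracle comparisons are meaningful.

* **Optimal dose**: `d*(s) = clip(0.35 + 0.25 · sevscore, 0, 1.2)` mcg/kg/h
  — sicker patients need more.
* **Delirium hazard** per step:
  `plogis(−4.0 + 10 · (dose − d*)² + 0.6 · sevscore + 0.4 · 1[RASS ≤ −3])`.
  The quadratic deviation term encodes that both under-treatment and
  over-sedation raise risk; the intercept was set so that the clinician
  behavior rule yields roughly a one-third delirium incidence, the scale
  such registries report; the deep-sedation term adds the known harm of
  RASS −4/−5.
* **Clinician behavior**: a persistent per-admission bias (+0.2 ± 0.15
  mcg/kg/h above `d*`) plus per-step jitter, titrated toward the target in
  0.1 steps with probability-0.25 inertia — clinicians in this simulator
  are systematically a touch heavy-handed but state-responsive, giving the
  learner signal and the behavior model support near the optimum.
* **Discharge**: hazard 0.08/step, truncation at 20 steps (~5 days),
  matching typical stays of ~2–4 days.
* **Raw-record emission**: Poisson measurement counts per window (vitals
  ~2/window, labs ~every 4 windows), per-cell missingness, small
  observation noise, rare (0.2%) decimal-place gross errors to exercise
  outlier removal, and a 30% chance the verbal GCS component is
  unassessable (intubation) to exercise the conversion table.

`true_policy_value()` rolls this environment forward under any policy;
because each trajectory has one terminal reward, the return is
`γ^(T−2) · r_last`. `expected_incidence()` integrates the per-step hazards
along full-horizon paths with event sampling disabled — an oracle for the
event sampler that the test suite compares against empirical incidence.

**What the simulator does not capture**, hence what passing tests do and do
not show: real cohorts have non-Gaussian marginals, informative
measurement timing, feedback from treatment to labs, co-sedatives with
interactions, unobserved confounding, and delirium labels with chart-review
noise. Tests on this simulator validate the *machinery* — preprocessing
semantics, the CQL objective, estimator correctness against ground truth —
not clinical effectiveness. Cohort-level return values from the original
registries depend on private data and are out of reach by construction.

# Numerical and statistical conventions

* Argmax ties break to the lowest action index everywhere.
* Even-count medians are the mean of the two central values; quantiles use
  linear interpolation (R type 7), including the "first quantile" used to
  split policy-matched from policy-unmatched cases, which we read as the
  25th percentile (cases at or below it are "matched").
* Features are z-scored before PCA (variance-based component retention is
  scale-sensitive); the retained set is the smallest reaching 90%
  cumulative explained variance.
* Multiclass Shapley attributions (exact TreeSHAP on the gradient-boosted
  surrogate) are aggregated across the 16 action classes by mean absolute
  value — the reference work does not state its aggregation; mean absolute
  value is the common convention and preserves per-class additivity, which
  is tested to 1e-6.
* Fisher's exact test replaces the chi-squared test when any expected cell
  count is below 5 (the switch rule was unstated).
* Bootstrap intervals are percentile, 1000 replicates by default, with the
  admission as the resampling unit; a statistic failing on >10% of
  replicates aborts.
* One RNG stream per pipeline module, derived from the master seed, so
  module-level reruns reproduce independently.

# Problem sizes

Module tests run on cohorts of 10–500 admissions in seconds. The
acceptance-style checks use the scales at which their claims are sharp:
5000 trajectories (~37k transitions) for estimator-vs-oracle comparisons,
1200 admissions for policy-improvement training, 10000 rollouts for
Monte-Carlo truth, 400 repetitions for bootstrap coverage. The acceptance
script simulates 1000 patients end to end. These sizes are the package's
choices for a single-CPU workflow.

# Known limitations

* FQE's bootstrap CI omits fitting variability; two evaluator seeds give
  estimates that agree within CI overlap on moderate data, but the interval
  is not a full account of estimator uncertainty.
* The chained-equations imputer is deterministic (no posterior draws), so
  imputation uncertainty is not propagated.
* WIS at p_top = 0.99 for a policy far from the clinicians' collapses to a
  handful of effective admissions — reported honestly via ESS rather than
  fixed, because that degeneracy is a property of the estimand.
* The multinomial behavior model is correctly specified only approximately;
  its misfit propagates into WIS weights (visible in the self-evaluation
  identity tests, which hold exactly only because the same model is used on
  both sides of the ratio).
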
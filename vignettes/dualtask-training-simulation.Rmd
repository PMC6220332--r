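---
title: "Simulating dynamic dual-task training: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating dynamic dual-task training: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dualtasksim)
```

This vignette documents the generative model behind `dualtasksim`, the
parameters that matter and why they default to what they do, the numerical
choices, and what the package's validation studies do and do not show.

## The experiment being simulated

A two-arm training study on a combined continuous visuomotor-tracking and
shape-discrimination task. Each simulated participant is thresholded on
both component tasks to ~80% accuracy, tested (five 3-minute trials per
condition: single tracking, single discrimination, dual), trained for six
sessions of twelve 3-minute trials — all dual trials for the multitask
group, six of each single task for the active-control group — tested
again, and run through a six-task transfer battery before and after
training. The key outcome is the overall dual-task cost,

$$\text{cost} = (\text{single} - \text{dual})_{\text{tracking}} +
  (\text{single} - \text{dual})_{\text{discrimination}},$$

in accuracy percentage points, with positive values meaning impairment
under load. Accuracy costs are single minus dual so that the printed costs
of such studies come out positive; the RT cost is dual minus single for
the same reason. These sign conventions, and the identity
`overall = tracking + discrimination`, are enforced by `compute_costs()`
and re-asserted after every aggregation.

## The observer model

### Psychometric functions

Expected single-task accuracy is a lapse-bounded logistic in the
difficulty parameter $x$ (target speed in dps for tracking, response
window in ms for discrimination):

$$\mathbb{E}[\text{acc}] = A \,\sigma\!\big(b + s\,(m - x)\big), \qquad
A = 100(1-\lambda), \quad b = \sigma^{-1}(80 / A),$$

with the sign of $s\,(m-x)$ arranged so accuracy falls with speed and
rises with window length. The anchoring through $b$ makes $m$ exactly the
80% point — the quantity the staircase is built to find — so
`psychometric_accuracy(obs, task, m)` is 80 by construction. Slopes
default to 130 per dps and 0.013 per ms: about two accuracy points per
fine ladder step near the start level, which is what makes a ±1.75%/level
proportional staircase move in sensible increments.

### Trial noise

Tracking accuracy over a trial is a binomial over one-second on/off-target
indicators around the psychometric expectation; the outcome of interest is
percent time on target and nothing downstream consumes cursor paths, so
the closed-loop pursuit is not simulated (the bouncing-target trajectory
generator `generate_trajectory()` is still part of the engine, with
specular reflection at the arena edges and at the two invisible discs plus
the central 1 cm protective zone — positions provably never enter any
disc, and speed is conserved exactly). Discrimination trials run through
the full stimulus engine: a schedule with onsets every 2/2.5/3 s, 50%
targets, per-stimulus hit and false-alarm draws whose rates are chosen so
the expected overall accuracy (targets answered in the window plus
distractors correctly withheld) equals the psychometric value, and scoring
by `score_discrimination()` over the response times. Response times are a
shifted log-normal (default 100 ms shift, median ~220 ms) truncated at the
response window, giving in-window means around 320–340 ms with right skew.

### Interference and learning

Dual-condition performance subtracts an interference parameter, in
accuracy points, at the observer's operating level (defaults: ~15.6 points
on discrimination, 0 on tracking — in this paradigm the tracking cost sits
near zero and discrimination carries nearly the whole cost). Subtracting
points at the operating level is equivalent to a midpoint shift calibrated
there; we deliberately did not use a *fixed* midpoint shift, because as
single-task learning pushes the operating point up the flattening logistic
a fixed shift would shrink the rendered cost in *both* groups, and the
single-task group's cost is empirically stable across training.

Learning is linear per completed session and split by mechanism:

* single-task skill moves the midpoints (defaults 0.00055 dps and 4.2 ms
  per session, both groups — chosen so single-task accuracies rise ~5–6
  points over six sessions, the scale seen in this paradigm);
* dual-task coordination reduces the interference parameter (default 1.2
  points per *dual-trained* session), and only dual training provides it.
  Over six sessions that is a ~7-point cost reduction in the multitask
  group and none in the control group — the training-specific effect the
  design is powered for.

Training-trial outcomes do not feed back into learning (no
accuracy-contingent plasticity is modelled), which is why the replicate
studies may run the protocol with `include_training = FALSE`: skipping the
causally inert training trials is exact, not an approximation. Bonus
points are recorded but inert; rest days are inert (no forgetting).

### Population and randomization

`sample_population()` draws every observer parameter independently from a
truncated normal with configurable mean and between-subject SD (midpoint
SDs of 0.008 dps / 40 ms disperse the 80% points by roughly ±8 ladder
levels), draws a personal transfer profile per observer, and assigns
groups by randomization, so group membership is independent of every
generative parameter. Defaults use 19 multitask and 20 single observers.

## The staircase

Nine trials per task, starting at level 29 of a 49-level ladder. Inside
the 77.5–82.5% deadband the level is unchanged; outside it moves by
`round((accuracy − 80) / 1.75)` levels, rounding half away from zero so
too-easy and too-hard overshoots are treated symmetrically, and clamping
at the ladder ends so ceiling/floor observers terminate. The test level is
then read from an OLS regression *of level on accuracy* evaluated at 80 —
that orientation is the only one that yields a level from a target
accuracy. We evaluate the regression at the criterion (80) rather than at
the median observed accuracy; with a converged staircase the two nearly
coincide, and the criterion is the quantity the procedure is defined to
find. If all nine accuracies are identical the regressor has zero variance
and the most recent level is returned with a warning (a pure edge-case
fallback). The implementation computes the normal equations directly; the
test suite checks it against `stats::lm()` to 1e-9.

`staircase_recovery_study()` validates the whole loop: across observers
with dispersed true 80% points, the mean accuracy actually achieved at the
chosen level sits near 80% (within about one point in our runs, with a
slight easy-side bias from regression attenuation over the nine noisy
points — visible, but well inside the ±3-point design band).

## Inference layer

`mixed_anova_2x2()` is an exact cell-means decomposition for the
two-between × two-within design, allowing unequal group sizes: the group
effect is tested on subject means, session and interaction on difference
scores with unweighted (Type III-style) contrasts. For this design the
interaction F is *identically* the squared pooled two-sample t on the
change scores — the suite verifies this to 1e-9 over a thousand random
datasets, alongside exact SS conservation and agreement with
`stats::aov()` on balanced designs. With a degenerate (all-zero) error
stratum the F is defined as 0 when the effect SS is also zero. p-values
use the F distribution at the design's integer dfs; with two levels per
factor no sphericity correction exists to apply. Pooled-variance t tests
are the default (df = 37 at 19 + 20), matching classical reporting.

Bayes factors use the BIC approximation
$\mathrm{BF} \approx \exp((\mathrm{BIC}_1 - \mathrm{BIC}_2)/2)$ over three
nested random-intercept models fitted by ML with `lme4` (null, main
effects, main effects + interaction), composed by transitivity
(`bf12 = bf10 / bf20`, exact by construction). These are directionally
comparable to, but not numerically the same as, default-prior Bayesian
ANOVA factors; no claim of numerical equivalence with any particular
default-prior software is made or tested.

## Transfer battery

Transfer tables are generated at the trial-statistic level (RT and
accuracy draws per trial), not at stimulus-rendering level, because every
downstream statistic consumes trial tables only. Geometry: PRP 4 × 40
trials at SOAs 200/1000 ms; single response selection, Stroop, go/no-go
(25% no-go) and flanker 4 × 36; attentional blink 4 × 24 with lags
2/3/5/7 and T2 scored only on T1-correct trials. Default effect sizes are
standard healthy-adult magnitudes (PRP ~213 ms, AB ~22 points, Stroop
~122 ms, flanker ~92 ms, ~20% commissions, go RT ~318 ms, RS RT ~631 ms)
with between-subject SDs of the same order as published samples. Each
personal effect is drawn once per observer and held across sessions, so
pre/post are subject-correlated as in real data. The post-training
practice shift is applied *identically in both groups* — the null-transfer
structure: every transfer statistic's session-by-group interaction is zero
in expectation, and `simulate_transfer_null_study()` confirms the
interaction tests reject at about the nominal rate. Stroop/flanker neutral
trials are generated and retained in the tables but excluded from the
congruency contrast; RT statistics use correct trials only (field
convention).

The a-priori exclusion rule (`apply_exclusions()`) removes participants
more than 3 SD above the cohort RT mean or below the accuracy mean on any
of the six tasks at pre-training, with the SDs computed over the full
enrolled cohort in a single pass — no iterative re-computation after
removals, matching a rule fixed before seeing data. Cohorts smaller than
three are refused (the SD is unstable).

## Numerical and design choices

* **Ladders.** Generated from the stated step structure: speeds 0.0100 to
  0.0820 dps in 0.0040 steps (levels 1–19), then 0.0010 steps to 0.1120
  (level 49); windows 1000 to 550 ms in 25 ms steps, then 10 ms steps to
  250 ms. Endpoints are asserted exactly in the tests.
* **Rounding.** Half away from zero for level deltas and threshold
  selection (symmetric treatment of the two directions).
* **Seeding.** A single master seed; every participant/phase draws from a
  named sub-stream via `derive_seed()`, so one participant's trial count
  cannot perturb another's stream and runs are byte-identical for a fixed
  seed (the manifest test checks this).
* **Trajectory geometry.** The two invisible bounce discs sit at (⅓, ½)
  and (⅔, ½) of the 1024 × 768 arena with 1 cm radius; the obstacle
  positions and start heading are not otherwise constrained by the design,
  so they are fixed, documented constants. Pixel↔cm conversion assumes
  57 cm viewing distance at 30 px/cm; the kinematic tick is 10 ms (100 Hz
  display).
* **Thresholding durations.** 60 s tracking and 120 s discrimination
  trials, nine of each; both are config values.
* **Problem sizes in validation.** The training-effect study uses 500
  replicate cohorts (and 200 for the null-calibration variant), the
  transfer-null study 120 replicates, and staircase recovery 200
  observers — sizes chosen to put Monte-Carlo error comfortably inside
  each property's acceptance band. The rejection-rate bounds in the tests
  are nominal-α plus 3.5 binomial standard errors at the replicate count
  used, fixed from sampling theory rather than from observed runs.

## Limitations

* The observer model is deliberately minimal: independent parameter
  dispersions (no individual-differences covariance), linear learning, no
  motivation/bonus feedback, no forgetting, no fatigue. Passing tests show
  the pipeline's logic and calibration are right, not that real
  participants behave this way.
* Cursor dynamics are not modelled; tracking accuracy is generated from
  the psychometric function, so questions about pursuit kinematics are out
  of scope.
* BIC Bayes factors approximate default-prior Bayesian ANOVA only up to
  its unit-information prior; magnitudes will differ even when directions
  agree.
* Trial-level RT distributions for the transfer tasks are modelling
  choices (Gaussian around personal means at the trial level); only their
  means and between-subject spreads are calibrated.
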
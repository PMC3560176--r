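---
title: "Objective ADHD phenotyping: models, generators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective ADHD phenotyping: models, generators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitstill)
```

`sitstill` asks a single scientific question of its data: when adult
ADHD cases and controls perform sustained-attention tasks, is the
capacity to *sit still* — measured by infrared motion capture — a more
discriminative marker than the attention performance itself?  This
vignette documents the models behind each stage, the parameters that
matter, what the synthetic data do and do not emulate, and the design
decisions taken where the underlying methods left genuine freedom.

## 1. Movement measures

A marker trajectory is a 50 Hz sequence of 2-D positions quantized to
0.04 mm, with a validity flag per frame (occlusions and reflections lose
frames; the study-scale average loss is 18%).  Preprocessing linearly
interpolates invalid frames and records the loss fraction.

Six measures summarize a trajectory:

* **Microevents** — an event fires whenever the marker has moved at
  least 1 mm (Euclidean) from an anchor; the anchor then resets to the
  current position.  The anchored definition is deliberately robust to
  sub-resolution jitter, which oscillates without escaping the anchor
  neighbourhood.  The same event stream underlies the immobility and
  temporal-scaling measures, so one threshold governs the whole
  activity/stillness dichotomy.
* **Immobility duration** — mean gap between consecutive microevents
  (whole session when no event occurs).
* **Displacement** — summed inter-frame Euclidean distance (m).
* **Area** — convex hull of visited positions (cm²).  An occupancy-grid
  area would be a defensible alternative; the hull is the simplest
  well-defined reading of "area in which movements occurred" and is the
  one implemented.
* **Spatial complexity** — the divider (compass) dimension.  Apparent
  length `L(r)` is measured by a true compass walk (stepping exactly
  `r` along the polyline, interpolating within segments) over a
  geometric ruler ladder; the exponent is `1 − slope` of
  `log L(r) ~ log r`, clamped to `[1, 2]`.  The ladder anchors at twice
  the mean inter-vertex step (floored at 0.5 mm) and caps at a quarter
  of the bounding-box diagonal — anchoring at the path's own inner scale
  is what makes the estimate invariant under uniform rescaling of the
  coordinates.
* **Temporal scaling** — box-count exponent of the microevent times:
  occupied windows `N(w)` over `w = 0.5 s … 64 s`, exponent
  `−slope` of `log N ~ log w` clamped to `[0, 1]`, with saturated
  widths (every event its own box) excluded from the fit.  No events
  maps to 0 by convention.

Extensive measures (microevents, displacement) are rescaled by
`1/(1 − loss)`; intensive ones (exponents, area, mean immobility) are
not.  Loss above 50% triggers a data-quality warning.

Numerical behaviour worth knowing: on exactly self-similar,
non-self-crossing curves the divider estimate and an independent grid
box-count agree closely (a depth-5 triadic Koch curve gives ≈1.22 under
both, against the analytic 1.2619), and smooth paths give 1.0 within
0.02.  On *self-crossing* Brownian-like paths the two estimators
diverge systematically — the compass walk measures the parametrized
curve including revisits (→ ≈1.9), box-counting counts each cell once
(→ ≈1.7 at finite length).  That divergence is a property of the
estimators, not an error; the oracle-equivalence tests therefore pin
exact agreement on non-revisiting curves and only the qualitative
"rough path" behaviour on walks.

## 2. Attention tasks

The **cognitive control task** presents star stimuli for 240 ms at a
variable ISI with mean 2500 ms; 90% are targets.  The ISI law is not
published beyond its mean; the generator uses a shifted exponential
(minimum 1000 ms, mean 2500 ms) — a one-parameter family consistent
with "variable ISI".  A 20-minute session then yields ≈438 trials
(1200 s / 2.74 s mean cycle).  Scoring: accuracy over all trials,
errors of omission (missed targets), errors of commission (responses to
non-targets), and latency mean/SD/COV over correct target responses.

Sessions divide into 30-second epochs; each epoch's feature vector is
(hit rate, false-alarm rate, mean RT, RT SD, response count) — a
minimal set sufficient to separate the five described attention states.
A multiclass Fisher linear discriminant (pooled within-class
covariance, uniform priors) assigns each epoch a state; exact posterior
ties break by the fixed priority attentive > distracted > impulsive >
random > minimal.  "Attention shifts" is operationalized as
adjacent-epoch label changes — the simplest fluctuation count
consistent with the description.  Percent-time measures are labeled
epoch shares.

The **letter CPT** uses 6 blocks × 3 ISI sub-blocks (1000/2000/4000 ms,
randomized within block), 250 ms letters; trial count and non-target
rate are not published for this context, so the generator adopts the
conventional 360-trial / 20-per-sub-block / 10% 'X' geometry
(configurable).  Signal detection uses the log-linear guard: rates are
clipped to `[1/(2N), 1 − 1/(2N)]` before `d' = z(hit) − z(fa)` and
`beta = exp[(z(fa)² − z(hit)²)/2]`.  The four slope measures are
least-squares slopes of sub-block mean correct RT (and RT SE) on block
index 1–6 and ISI *level index* 1–3 — level index, not raw
milliseconds, because the published slope magnitudes (~0.05) are only
consistent with per-level units.

## 3. Composite instruments

The commercial composites' coefficients are proprietary, so all four
instruments are re-fit on synthetic calibration cohorts and persisted
(JSON, with reference statistics and a config hash):

* activity severity — 12 movement measures, standardized against
  control reference statistics, ridge-penalized logistic weights;
* distraction severity — same construction over the 12
  cognitive-control measures;
* discriminative index — both blocks jointly (24 measures), lighter
  penalty (it is the one instrument described as explicitly optimized
  for discrimination);
* confidence index — linear discriminant on (percent omissions, sex,
  age, beta, RT-by-ISI slope), reported as the ADHD posterior × 100.

The ridge penalty (fixed λ = 0.25; 0.1 for the combined index) is a
deliberate modeling stance: these instruments are stable,
population-level scoring rules, and an unpenalized fit on a wide block
of strongly correlated measures chases calibration-sample contrasts
(and separates outright for the 24-measure block).  In the pipeline the
instruments are always fit on a calibration cohort *separate* from the
analysis cohort, so reported composite AUCs are out-of-sample.

## 4. Inferential layer

Per measure: ANCOVA (`value ~ group + age + sex`) with the covariate
gate — age or sex enters only when it influences the measure on its own
at unadjusted p < 0.05; the group F is the marginal (type II) F; the
gate decision is recorded per measure rather than assumed.  Adjusted
values subtract centred covariate contributions only.  Q-values are
Benjamini–Hochberg within each measurement panel.  Effect sizes are
Cohen's d with pooled SD and a 1,000-resample percentile bootstrap CI
(percentile, not BCa — nothing more specific is warranted by the
method's description).  ROC areas are trapezoidal (midrank ties) with
DeLong CIs; paired curve comparisons use DeLong's placement-value test,
two-sided throughout.  Scores are oriented by the *hypothesized*
ADHD-high direction before the ROC, so anti-predictive measures report
areas below 0.5 rather than being flipped post hoc.
`binormal_auc(d) = Φ(d/√2)` provides the closed-form cross-check
linking the effect-size and ROC columns.

Variable importance: a 10,000-tree random forest with 4 variables per
split, reporting both permutation-accuracy and Gini-decrease criteria
with ranks.  The predictive-modeling harness draws stratified 75/25
splits once per seed — identical partitions for every family and
feature set, enabling paired split-level tests (paired t, Wilcoxon
fallback under clear non-normality) — and evaluates six families:
linear discriminant, OLS scoring of the 0/1 outcome ("general linear"),
binomial logistic, a single-hidden-layer neural network (size 5, decay
0.1), a radial SVM (cost 1), and a random forest (300 trees per split).
The network/SVM hyperparameters are unpublished; the values are typical
of the harness ecosystem the original analysis used and are fixed in
the configuration.  Sensitivity treats ADHD as the positive class at a
0.5 posterior threshold.

## 5. The synthetic cohort: what it emulates and what it does not

Subject-level data were never deposited; the generator's calibration
inputs are the printed per-measure group means and 95% CIs (36
measures), the demographic composition (40 ADHD, 23M/17F, 35 ± 10 y; 60
controls, 28M/32F, 29 ± 9 y; ages 18–57; 17 predominantly inattentive),
and the published block-level discriminability.  Group SDs come from
`sd = (CI width / 2) / 1.96 × √n` (the normal multiplier; at n ≥ 40 a t
quantile changes nothing material).  Marginals are normal, or
moment-matched lognormal for the strictly positive, visibly skewed
count/extent measures (microevents, displacement, area, commissions).

Within-subject dependence is a hierarchical factor model: a general
severity factor plus one factor per instrument block (motion system,
each attention task), with every measure's block loading *proportional
to its printed effect size* and the block-factor separations capped at
d = 1.7 (motion), 1.0 and 0.95 (attention tasks) — the ranges implied
by the published cross-validated AUC/accuracy of models built on each
block.  Proportional loadings are the internally consistent
common-cause solution: they make each printed group difference fully
mediated by its block factor.  The alternative — free loadings with
margin-only calibration — was implemented first and rejected, because
it manufactures within-block "contrast" directions whose combined
discriminability exceeds anything the published models achieved,
inverting the study's central activity-versus-attention ordering on
some sampled cohorts.  Cross-block coupling is deliberately modest
(γ = 0.2): the published rating-correlation table would suggest a
stronger activity–attention coupling, but the published dominance of
the combined index over the activity composite requires a largely
independent attention signal; the generator resolves this internal
tension of the source results in favour of the ordering, so the
synthetic attention-composite rating correlations come out weaker than
printed.  Executive-function ratings are generated against the activity
composite at the printed correlation targets and inherit all other
correlations structurally.

One further tension is worth stating plainly: the printed per-measure
movement AUCs reach 0.88, so *no* generative model calibrated to those
margins can yield an optimal activity composite at the printed 0.83 —
a composite at least as good as its best single measure is a
mathematical floor.  The synthetic activity composite therefore sits
near 0.90, and the pipeline's reproduction targets for composites are
orderings, not levels.  The floor has a second consequence: it
compresses the combined-index advantage over the activity composite
from the published ~0.13 AUC to ~0.014, so on 100-subject cohorts the
combined > activity ordering holds in roughly nine of ten replicates
rather than always — the one reproduction target that sits at, not
comfortably above, its acceptance margin (the importance ordering and
the per-family activity-model superiority hold in ten of ten).

The signal-level generators (bout/immobility trajectories with
heavy-tailed still periods and roughness-controlled correlated-walk
bouts; hidden five-state Markov response models at 30-s epoch
granularity) exist to exercise the extractors end-to-end and to test
parameter recovery (microevents and temporal scaling increase in bout
rate, spatial complexity in roughness).  They are *not* calibrated to
reproduce the printed feature tables — the feature-level generator is —
and the `run_study()` pipeline accordingly samples its analysis cohort
at the feature level while pushing exemplar subjects through the full
signal path.  Frame loss is injected in geometric runs (mean 10 frames)
because occlusions are temporally contiguous, at the study-scale 18%
share.

What passing tests therefore show: the extractors, statistics and
harness are correct against independent oracles, and the study's
qualitative conclusions are reproduced on cohorts that match the
published summary statistics and block discriminabilities.  What they
cannot show: behaviour under real marker noise, real RT distributions,
or correlation structure beyond the hierarchical factor model.

## 6. Reproduction scales and determinism

Every generator and every analysis stage is deterministic given a seed;
`run_study()` fans a single master seed out to per-stage child seeds
(`seed × 1009 + stage`, mod 2³¹ − 1), so a configuration reproduces its
report bit-for-bit.  The pipeline defaults mirror the published design
where it is stated — 40/60 cohort, 1,000 bootstrap resamples, 10,000
importance trees with mtry 4, 200 cross-validation splits — and uses
desk-scale substitutes where the published figure is a compute budget
rather than a method: 500 splits (not 5,000) for the random-forest
family by default, 300 trees per split inside the harness, and
10-replicate screens for the ordering checks.  Exemplar signal sessions
default to 5 minutes rather than 20 for the same reason; all of these
are configuration fields, not constants.

## 7. Known limitations

* Scaling-exponent estimators follow this package's concrete
  definitions (compass dimension; temporal box count).  The printed
  exponent ranges are representable under these definitions, but exact
  numeric equivalence with the original proprietary implementation is
  not claimed.
* The ANCOVA covariate gate is applied per measure and logged; which
  covariates passed the gate in the original analysis is not published,
  so adjusted values can differ measure-by-measure from the originals.
* Composite weights are synthetic re-fits; only their construction, not
  their coefficients, matches the commercial instruments.
* The generator matches first and second moments and a
  three-factor dependence structure — not higher moments, learning or
  fatigue effects within sessions, or subtype-specific profiles beyond
  the subtype labels themselves.
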
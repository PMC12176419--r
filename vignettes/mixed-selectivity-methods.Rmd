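---
title: "Detecting nonlinear mixed selectivity in multivoxel patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nonlinear mixed selectivity in multivoxel patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A neuron (or a voxel-level population) shows *nonlinear mixed selectivity*
(NMS) when its response to two experimental variables — here, the category
of a viewed object and the task performed on it — contains an interaction:
the response to a combination is not the sum of the responses to each
variable alone. At the population level this corresponds to a multivariate
*difference in differences*: the pattern difference between two categories
changes depending on the task context. Interactive coding of this kind is
what lets a fixed population support context-dependent readouts, and this
package implements a complete analysis stack for detecting it
noninvasively in block-wise multivoxel activity estimates ("beta"
patterns), together with the cross-decoding and representational-geometry
analyses needed to interpret it.

The intended design is factorial: 8 stimulus categories crossed with 2
tasks (an Oddball detection task and a Oneback repetition task), 13
participants, 20 runs each (10 per task; the task alternates run by run
except for a repeat at the session midpoint, so neither task is
systematically earlier), and one analyzed block per category per run.
All analyses generalize to other even run counts and category numbers.

## The analysis stack

**Normalization.** Every block's voxel vector is z-scored across voxels
(mean 0, sample SD 1, divisor *n* − 1), removing per-block amplitude and
offset differences. The divisor choice is immaterial: z-scoring is an
affine per-block map and cannot change any classifier decision.

**Decoding.** All classification uses a linear soft-margin SVM with
regularization constant c = 1 on all voxels (no voxel selection).
Cross-validation folds are runs: leave-one-run-out for single-task
analyses; leave-one-adjacent-run-pair-out when both tasks must appear in
training (each adjacent pair (2i−1, 2i) contains one run of each task
under the alternating order — this is why the package requires an even
number of runs per task). Category decoding averages all 28 pairwise
accuracies per task; task decoding averages the 8 per-category accuracies.

**Cross-decoding.** A classifier trained to separate a category pair in
one task is tested on the same pair in the other task (both directions
averaged), and analogously for task across categories. Training rotates
over all-but-one run of the training context so the training-set size
matches within-context decoding; otherwise the generalization ratio would
be confounded with data quantity. (The alternative — train on all runs of
the training context — is available as `cross_train_all_runs = TRUE` in
`decoding_spec()`.) The *cross-decoding ratio*
(between − .5)/(within − .5) puts regions with different baseline decoding
on a common scale; 1 means perfect generalization. A probit-scale variant
qnorm(between)/qnorm(within) is provided because accuracy can relate
nonlinearly to underlying pattern separation; on the probit scale chance
maps to 0, so no baseline subtraction is needed. Participants whose
within-context accuracy does not exceed chance have no defined ratio and
are returned as NA with a warning — never silently dropped.

**Pattern difference decoding** is the direct interaction test. Within
each run, difference vectors between same-task category pairs are formed
(fixed lexicographic subtraction order — any consistent order works, and
consistency is all the classifier needs); a classifier then tries to
decode *which task* a difference vector came from, per category pair,
under fold-respecting cross-validation. The complementary direction
(decode *category pair* from between-task difference vectors formed
within adjacent run pairs) tests the same interaction, and the two
directions are averaged. Chance is .5; above-chance accuracy means the
category code is not a fixed pattern offset across tasks. Difference
vectors pair blocks within the same run (or the same adjacent run pair)
so that run-level additive artifacts cancel.

Cross-decoding and the interaction test can dissociate, and the package's
`scenario_fixtures()` build the four canonical planar geometries showing
how: an additive code with an orthogonal task shift (cross-decoding works,
no interaction), an *oblique* additive code whose task shift runs along a
category axis (cross-decoding fails with no interaction present), an
interaction that preserves the sign of the difference vector
(cross-decoding survives an interaction), and a sign-reversing interaction
(cross-decoding below chance, interaction maximal).

**Inference.** Per region, the standard family is 12 tests (category
decoding per task, their comparison, overall category decoding, task
decoding, category-vs-task, both cross-decoding analyses with their drop
tests, the ratio against 1, and the interaction test against chance),
corrected with Benjamini–Hochberg FDR at q = .05 within the family; tails
follow interpretability (one-tailed against chance and for drops,
two-tailed for comparisons). Per participant, a permutation test shuffles
the training labels of the difference vectors immediately before
classifier training (1000 iterations in the reference analysis) and takes
the proportion of permuted accuracies strictly above the observed one; a
(1+b)/(1+N) variant bounded away from zero is available. At the group
level, `posterior_odds()` fits a hierarchical model — per-participant
correct counts as Binomial(n_j, pi_j) with logit(pi_j) ~ Normal(mu,
sigma²), mu ~ Normal(0, 10²), sigma ~ half-Normal(0, 2) — and reports
p(mu > 0)/p(mu < 0), the posterior odds that the population decoding
accuracy exceeds chance. The posterior is computed deterministically:
Gauss–Hermite integration over the random effect and a two-scale
trapezoid grid over (mu, sigma), with convergence diagnosed by grid
refinement (the default tolerance of 0.05 on the log odds reflects the
scheme's accuracy target; the suite validates the result against a long
MCMC run of the same model). Sector summaries always average *final*
per-region statistics (e.g. ratios of accuracies, never ratios of
averaged accuracies), so each region contributes equally.

**Geometry.** Pairwise accuracies among all 16 category-by-task
conditions form a representational dissimilarity matrix; for embedding,
chance is subtracted and negative values clipped to zero, and classical
(Torgerson) multidimensional scaling is applied — chosen over iterative
stress minimization for determinism, with a fixed sign convention per
axis. The rotation/reshaping question is settled by a
reliability-corrected comparison: each participant's 28-entry category
similarity vector (no clipping here) is correlated with the average
vector of the *remaining* participants within task and across tasks; the
group-mean within-task correlation is the noise ceiling, and each
participant's between-task correlation divided by that ceiling, squared,
estimates the proportion of reliable geometry shared across tasks.
A value of 1 means the task rotates or shifts the category geometry
without changing its content; values below 1 mean genuine reshaping.
Negative correlations are not clipped before squaring — squaring discards
the sign anyway and the one-tailed test direction is unaffected; the sign
is retained in the per-participant output. For correlating geometry
change with interaction strength within participants,
`between_task_rdm_correlation()` uses each participant's own two vectors,
so both quantities are within-participant.

## The synthetic cohort

No public beta patterns ship with the package; a seeded generator stands
in, with ground truth exposed for every dataset. Its construction is the
result of deliberate choices, each of which matters for what the tests
can and cannot show:

- **Hierarchical category geometry.** Shared category templates are built
  from latent factors giving sibling-pair correlations ≈ .9, within-
  cluster ≈ .5, across-cluster ≈ 0 — the canonical clustered structure of
  object-category RDMs. A flat i.i.d. geometry would give the cohort
  almost no shared distance profile, hence a near-zero noise ceiling and
  an unstable reliability-corrected ratio.
- **Exactly equal condition norms.** All category templates are
  normalized to identical norms (gain × √(V−1)); task templates are
  orthogonalized against every category template and norm-equalized; the
  additive task shift therefore carries no category information, and — the
  crucial point — the z-scored noise scale is identical for every
  condition. With unequal norms, weak conditions end up noisier after
  z-scoring, and the interaction test can read out that noise-scale
  difference with no mean interaction present. Equal norms are what make
  the additive null hold in the analyzed space.
- **Unit-variance calibration.** In the default `znormed` domain the
  i.i.d. voxel noise variance is set so each block has unit variance in
  expectation; `noise_sd` is ignored and the gains are interpretable as
  template standard deviations relative to total block variation
  (defaults: category 0.33, task 0.12, giving mean pairwise category
  decoding ≈ .85–.90 and task decoding ≈ .62). A `raw` domain with
  explicit `noise_sd` is available.
- **Participant structure.** Participants share the group templates with
  jitter (0.15 of the gain, re-norm-equalized), giving across-participant
  RDM reliabilities around .75–.85 — comparable to well-measured visual
  ROIs, and required for the noise-ceiling logic. Task templates are
  fully participant-specific: voxel-level task axes have no reason to
  align across brains, and a shared task axis couples with the
  normalization geometry to fake a task-specific profile component.
- **Interaction regimes.** `rotation` applies planar rotations (angle =
  `interaction_gain`, radians) within the span of the category templates:
  exactly distance-preserving, so it creates an interaction without
  changing representational content. `reshape` scales category k's
  template by 1 + gain·l_k (l_k a fixed grid on [−1, 1]) in task 2,
  altering the distance profile itself. `oblique` shifts task 2 along the
  axis of the best-separated category pair by 1.5× that pair's half
  separation, realizing the cross-decoding failure without interaction.
  Gain 0 reduces every mode to additive. For dissociation demonstrations
  the package's tests use rotation 0.6 and reshape 0.8 — effect sizes a
  13-participant design detects decisively.

**What passing tests do and do not show.** The generator emulates the
block-design statistics of beta patterns, not their physiology: no
hemodynamics, no spatial voxel correlations, no run-level drifts (the
within-run pairing of difference vectors makes those cancel anyway), no
attention or arousal confounds. Null calibration on this cohort shows the
*analysis stack* is unbiased under additive coding; it cannot rule out
physiological sources of apparent interaction in real data (e.g.
vascular nonlinearity), which the method itself cannot distinguish.

## Numerical behavior worth knowing

- Cross-validated accuracy under the null is not exactly .5: the strict
  fold structure makes it slightly pessimistic (≈ −0.02 on this design),
  and per-block z-scoring couples templates and noise at second order
  (≈ +0.03 with task templates of the default size). On the full study
  design these nearly cancel: measured null interaction decoding is
  0.507–0.510 across seeds, well inside the ±0.03 calibration band; the
  per-participant permutation test is the principled answer to this,
  since the permutation null inherits the same biases.
- The squared reliability-corrected ratio has a small upward Jensen bias
  (≈ +0.03 at ceiling ≈ .8, n = 13) — intrinsic to a ratio-of-noisy-
  quantities estimator, shared with the original measure.
- Classifier decision values of exactly zero are broken by a seeded coin
  flip (reported via a message); with continuous data this essentially
  never occurs.
- Degenerate inputs error early and loudly: zero-variance blocks, empty
  selections, missing condition pairs, sub-chance denominators, and
  ledger inputs are all validated with messages naming the offender.

## Problem sizes

The test suite and the acceptance script run the full 13 × 10 × 8 × 100
design for cohort-level checks (a few minutes each) and deliberately
smaller designs — fewer categories, runs, and voxels — for property-style
checks such as permutation-null uniformity, where hundreds of full
analyses are re-run. At those small sizes the template-realization
variance of null accuracies is large (±0.05 per participant); bands in
the small-scale tests are set accordingly, and cohort-level calibration
claims are only made at the full design size.

## Worked example

```r
library(mixsel)

cfg <- sim_config(geometry_mode = "reshape", interaction_gain = 0.8,
                  seed = 42)
cohort <- simulate_cohort(cfg)
dat <- znormalize_blocks(cohort$data)

pdd <- pattern_difference_decoding(dat)     # interaction test
sv  <- category_similarity_vectors(category_pair_accuracies(dat))
ve  <- geometry_variance_explained(sv)      # rotation vs reshaping

one_sample_t(pdd$accuracy, 0.5, "greater") # interaction above chance?
one_sample_t(ve$variance_explained, 1, "less")  # geometry reshaped?
```

Or as one orchestrated run with ledger, permutation test, Bayesian odds,
and geometry analyses:

```r
res <- run_pipeline(pipeline_config(simulation = cfg, n_perm = 200))
summarize_results(res)
autoplot(res$rsa$mds$simulated)
```

## Known limitations

Two-class analyses only (pairwise decoding everywhere, as in the target
design); exactly two tasks; no searchlight or voxel-selection variants;
the Bayesian model assumes exchangeable participants and a logit-normal
accuracy distribution; and the generator's Gaussian tuning is a stand-in,
not a receptive-field model.
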
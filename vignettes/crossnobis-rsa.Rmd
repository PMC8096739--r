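---
title: "Cross-validated Mahalanobis RSA for imagery and perception: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated Mahalanobis RSA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnobis)
```

## What this package models

Representational similarity analysis (RSA) characterizes a neural code by
the matrix of pairwise dissimilarities between the multi-voxel activity
patterns that different stimuli evoke. This package implements the complete
analysis chain for a family of imagery/perception fMRI studies in which
participants perceived or imagined campus buildings, cities on the map of
Italy, hours on a clock face, and famous faces, with the spatial quadrant
of each item (NE/SE/SW/NW) as the unit of the spatial analyses:

1. **Design** — continuous carry-over (serially balanced) trial sequences
   and per-scan timelines for three experiments (24, 16 and 24 conditions;
   120, 96 and 120 experimental trials per scan, plus null and question
   trials).
2. **Data** — a synthetic generator for ground-truth representational
   geometries, beta-level run patterns, and full BOLD time series with
   spatially and temporally correlated noise and simulated head motion.
3. **Pattern estimation** — a per-run ordinary-least-squares GLM with one
   HRF-convolved regressor per condition, a pooled question-trial
   regressor, a framewise-displacement (FD) nuisance, and an intercept.
4. **Distances** — cross-validated Mahalanobis (crossnobis)
   representational dissimilarity matrices (RDMs) with multivariate noise
   normalization from shrinkage-estimated residual covariances.
5. **Averaging** — factor-predicate selection of RDM cells (same/different
   category, domain, quadrant), a two-standard-deviation exclusion rule
   pooled across subjects and stimulus pairs, within-subject averaging, and
   merging of subjects who took part in two experiments.
6. **Inference** — a two-stage, region-gated testing framework: one-tailed
   one-sample t tests against zero with seed-level Bonferroni correction,
   then paired/two-sample t tests or one-way ANOVA on the surviving
   regions.

Real data for these studies are not publicly archived, so the package's
first-class input is its own generator; user-supplied beta maps (NIfTI plus
ROI mask plus a condition-label table) enter through `read_beta_nifti()`.

## The crossnobis estimator

For per-run, prewhitened condition patterns $u_i^m$ (condition $i$,
partition $m$ of $M$), the distance between conditions $i$ and $j$ is

$$
d_{i,j} \;=\; \sum_{l,m;\; l \ne m}^{M}
\frac{\left(u_i^m - u_j^m\right)^{\mathsf T}\left(u_i^l - u_j^l\right)}
     {M\,(M-1)} .
$$

Because the two difference vectors in each product come from independent
partitions, run-specific noise does not inflate the estimate: $d_{i,j}$ is
unbiased for the true squared Mahalanobis distance. That gives the measure
a *meaningful zero* — if two stimuli evoke identical patterns the expected
distance is zero, and inconsistent patterns can produce negative estimates
— which is what licenses one-sample t tests of averaged distances against
zero, and direct paired/two-sample comparisons between conditions. The
superscript $\mathsf T$ in the formula is the vector transpose (the inner
product runs over voxels); we note that reading it as "number of time
points" would make the expression dimensionally incoherent, and the
transpose reading is the one the estimator's derivation requires.

Two conventions deserve explicit mention:

* **No voxel normalization by default.** The plain estimator sums over
  voxels without dividing by the voxel count; `normalize_voxels = TRUE`
  enables the distance-per-voxel convention for comparisons across regions
  of different size.
* **Ordered-pair summation.** Summing over ordered run pairs and dividing
  by $M(M-1)$ equals summing over unordered pairs, doubling, and dividing
  by the same factor; the implementation is checked against a naive
  double-loop oracle to $10^{-10}$.

### Multivariate noise normalization

Voxel noise is spatially correlated, so Euclidean geometry on raw patterns
mixes signal with noise structure. Patterns are therefore transformed by
$\Sigma^{-1/2}$, the symmetric inverse square root of the voxel noise
covariance estimated from GLM residuals. The covariance is shrunk toward
its diagonal with a Ledoit–Wolf/Schäfer–Strimmer weight estimated from the
data (`estimate_noise_cov()`), which guarantees positive definiteness even
when voxels outnumber timepoints. Per-run residual covariances can be used
run by run (`noise = "per_run"`, matching a strictly per-run normalization)
or averaged into a pooled covariance (`noise = "pooled"`); the pooled mode
is the default because a single run's residual degrees of freedom (a few
hundred timepoints against up to hundreds of voxels) make per-run inverses
noisy, and pooling demonstrably stabilizes the whitening without changing
its expectation. The inverse square root uses a symmetric
eigendecomposition with an eigenvalue floor of $10^{-10}$ times the largest
eigenvalue.

## Carry-over designs

In a continuous carry-over design every stimulus precedes and follows every
other stimulus in a balanced way, so that event-related estimates are not
confounded by first-order carry-over effects. `carryover_sequence()`
constructs such sequences as Eulerian circuits. A fully balanced sequence
over $n$ items requires $n^2$ transitions ($n^2 + 1$ trials); a scan of the
simulated experiments is shorter (e.g. 120 trials over 24 conditions), and
a plain truncation of one long circuit would leave conditions unequally
presented within a scan. Each run's sequence is therefore an Eulerian
circuit on an $m$-regular *circulant* sub-digraph of the complete directed
graph with self-loops, where $m$ is the per-scan presentation count (5 or
6): every condition then appears exactly $m$ times per scan, every ordered
successor pair (self-successions included) occurs at most once per scan,
and the circulant offsets are partitioned across the experiment's scans so
the full session approaches complete pair coverage. Null and question
trials are inserted at seeded random positions after the experimental
sequence is built, keeping the experimental-item balance exact; question
probes are drawn at random and are analysis-irrelevant. Experimental and
null trials occupy 2 s followed by a 2 s fixation gap; question trials
occupy 4 s.

Imagery and perception trials (Experiments 2 and 3) are interleaved within
a single carry-over sequence over all conditions — the domain is part of
the condition identity — which maximizes design balance across the
domain boundary.

## The GLM

Each exemplar of each category, within each domain, gets its own regressor:
a boxcar of the trial durations built on a 0.1 s microtime grid, convolved
with a canonical double-gamma HRF (response gamma shape 6, undershoot shape
16, undershoot ratio 1/6, 32 s window — the common "canonical" convention;
all parameters are exposed), and sampled at volume midtimes. Question
trials are pooled into a single nuisance regressor; null trials stay
unmodeled as the implicit baseline. The framewise displacement nuisance is
the sum of absolute temporal derivatives of the six rigid-body parameters,
with rotations converted to arc length on a 50 mm sphere (the radius is an
argument; an all-zero FD column, e.g. under constant motion, is dropped).
The fit is ordinary least squares; no temporal prewhitening is applied in
the GLM, since the noise correlation that matters for the distance measure
is spatial and is handled by the crossnobis prewhitening. Residual degrees
of freedom are timepoints minus design rank.

## Cell averaging and the exclusion rule

`cell_selection()` expresses each question's averaging rule as a predicate
over unordered condition pairs — same/different/ignored on each of
category, domain and quadrant, with optional restrictions (e.g. only
perception-domain buildings). Before within-subject averaging, distances
are pooled across subjects and stimulus pairs within a selection (per
region) and values strictly beyond two standard deviations from the pooled
mean are excluded; values exactly at the boundary are retained. Pooling is
per region because RDMs are region-specific and the regions are independent
analysis units; this scoping (and whether hemispheres should pool) is not
uniquely determined by the verbal description of the rule, and the per-
region choice is the most conservative reading consistent with it.
Exclusion happens *before* averaging — the order matters, and masking first
makes the subject mean a mean of accepted cells rather than a contaminated
mean later discarded. Subjects who took part in two experiments contribute
one row per analysis, the arithmetic mean of their per-experiment values
(`merge_repeat_subjects()`); paired comparisons drop subjects listwise and
record the count.

## Two-stage gated inference

Each question is a declarative `question_spec` (the packaged
`questions.yaml` encodes the seven analyses Q1a–Q3c verbatim). Stage 1
gates every (region, selection) cell with a one-tailed one-sample t test
against zero at $\alpha = 0.05 / n_{\text{regions}}$, the seed-level
Bonferroni correction over hemisphere-resolved regions — 8 regions
(OPA, PPA, RSC, hippocampus, both hemispheres) for the Experiment 1/2
analyses, hence 0.00625, and 12 (adding FFA and OFA) for Experiment 3,
hence 0.00416. Stage 2 runs each follow-up comparison only on regions whose
required gates were all significant, at $0.05/\text{divisor}$; the packaged
specs expose the divisors explicitly (9, 4, 6, 2, 3, 1 — reproducing the
published second-level thresholds 0.0056, 0.0125, 0.0083, 0.025, 0.016 and
0.05). One of those divisors (9, for the first question's follow-up) does
not equal the count of regions the corresponding results text lists as
eligible (8); because the threshold is stated explicitly we follow the
printed value and expose the divisor in the config rather than inferring
it. All "higher than zero" and directional tests are one-tailed; the
printed $(t, p)$ pairs (e.g. $t_{18} = 2.49 \to p = 1.12 \times 10^{-2}$,
$t_{18} = 1.94 \to p = 3.41\times10^{-2}$) are consistent only with the
one-tailed convention, which fixes it for the gates as well. Two-sample
tests use pooled variance with $n_a + n_b - 2$ degrees of freedom, computed
from the data, never taken from a label. Where a comparison's group count
is data-dependent (two vs three eligible categories), `auto_group` selects
a two-sample t or a one-way between-groups ANOVA; a repeated-measures ANOVA
would be defensible for equal-n within-subject categories, but the
between-groups form is the one the verbal description names, and the
category groups can have unequal subject counts once experiments are
merged. Significance is strict inequality $p < \alpha$. A follow-up for a
region that failed eligibility can never be produced — this gate discipline
is asserted on every run.

## The synthetic generator and its calibration

`make_geometry()` composes each condition's true pattern from seeded random
unit-norm component vectors — one per level of category, domain, quadrant
and item — scaled by the corresponding effect sizes (in units of the
per-voxel noise SD). The factorial structure of the questions therefore
maps directly onto the block structure of the true RDM, and the true
squared Mahalanobis distance between any two conditions is available in
closed form (`true_rdm()`), which is what makes parameter-recovery testing
possible. An optional `perception_gain` multiplies the non-domain
components of perception conditions, emulating the sharper neural
representations of perceived relative to imagined stimuli that the
domain-comparison questions probe; the presets use 1.5.

Defaults, chosen once as plausible for the data the generator emulates:

* **Spatial noise**: exchangeable correlation $\rho = 0.3$, unit variances
  — strong enough that prewhitening demonstrably matters, weak enough to
  stay well-conditioned at realistic voxel counts.
* **Temporal noise**: AR(1) with $\phi = 0.4$ at TR = 2 s, a typical BOLD
  autocorrelation magnitude.
* **Motion**: a Gaussian random walk (step SD 0.02 mm/radians by default)
  over the six rigid-body parameters; motion feeds the FD regressor but
  does not corrupt the signal, so the FD path is exercised without
  conflating motion artifacts with noise structure.
* **Between-subject variability**: a seeded Gaussian perturbation of the
  true patterns per subject (`subject_sd`), giving group t tests realistic
  between-subject variance.
* **Effect sizes**: the published studies report no SNR or pattern-scale
  figures (plotted distance ranges are figure-derived), so effect sizes are
  free parameters. The `moderate` preset and the calibration effect used in
  the test suite (mean true pairwise squared Mahalanobis distance rescaled
  to exactly 3 noise-SD² units, at 8 conditions, 40 voxels, 5 runs, 19
  subjects) were set a priori by a design power analysis targeting
  one-sample gate power above 95% at the corrected $\alpha = 0.0125$ — the
  regime the published effects evidently occupy, given their gate p-values.
  The rescaling matters: the separation implied by random unit component
  vectors varies across seeds, and a calibrated power claim needs the true
  distance pinned exactly.

What the generator does *not* emulate: physiological noise and scanner
drift, susceptibility artifacts, anatomically realistic ROI geometry or
retinotopy, task-correlated motion, and hemodynamic variability across
regions or subjects. Passing tests on synthetic data therefore certify the
estimator chain and the inference logic, not the neuroscience of any
particular real dataset.

## Numerical choices and problem sizes

* All randomness flows from one integer seed through a documented splitting
  scheme (`child_seed()`, a Lehmer-style hash), so any run, subject or
  region is reproducible in isolation; derived seeds stay below $2^{31}$.
* Eigenvalue floor $10^{-10} \times \lambda_{\max}$ in the inverse square
  root; shrinkage weights clipped to $[0, 1]$; an exchangeable $\rho$ must
  exceed $-1/(P-1)$ for positive definiteness and is validated.
* Zero-variance gates (all subject distances identical) warn and return a
  degenerate p of 0 or 1 rather than failing.
* The test suite verifies estimator unbiasedness with 1000 beta-level
  replicates (2 conditions, 100 voxels, 5 runs), full-pipeline recovery
  with 200 replicates of 4 runs of ~330 volumes at 12 voxels — sized so
  that the precision-estimation bias of the noise normalization
  (inverse-Wishart inflation of order $(P+1)/T_{\text{pooled}} \approx
  1\%$) stays well inside three Monte-Carlo standard errors — and gate
  calibration with 600 replicates of a four-region study (one injected
  signal, three null regions). These sizes are the package's choices for a
  desk-scale demonstration; all of them scale up by changing arguments.

## Known limitations

* The estimated-covariance prewhitening makes recovered distances exact
  only in expectation under the true covariance; with short runs and many
  voxels the inverse-Wishart inflation of the estimated precision biases
  distances upward by roughly $(P+1)/T$, which pooling across runs and
  shrinkage mitigate but do not remove.
* The null distribution of a *single-pair* crossnobis distance is
  right-skewed (it is a difference of scaled chi-square forms), and the
  skew decays only like $1/\sqrt{P}$; a one-tailed t gate on single-pair
  distances at $n \approx 19$ is therefore mildly conservative at
  seed-level alphas (empirically ~0.008 true rate at a nominal 0.0125 for
  10–200 voxels). Averaging distances over the dozens of cells a question
  selects — which is what the actual analyses gate — symmetrizes the
  subject-level quantity and restores nominal calibration; the calibration
  suite gates pair-averaged distances for exactly this reason. Gates on
  near-singleton selections should be read as conservative, never
  anticonservative.
* The exclusion rule's pooling scope across hemispheres/regions and the
  handling of subjects asymmetrically excluded from one side of a paired
  comparison are under-determined by the verbal rule; the package masks per
  region and drops subjects listwise, and logs both.
* Question-trial content and behavioral responses are not modeled; the
  question regressor exists purely as a nuisance.
* Only the crossnobis dissimilarity is implemented; correlation distances,
  decoding accuracies and model-based RDM regression are out of scope.
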
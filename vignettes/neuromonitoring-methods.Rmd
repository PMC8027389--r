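---
title: "Methods: connectivity-based neuromonitoring of psychosis-likeness change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based neuromonitoring of psychosis-likeness change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Resting-state functional connectivity (rsFC) — the matrix of pairwise
temporal Pearson correlations between regional BOLD signals — carries a
reproducible multivariate signature of psychotic illness. The idea
implemented here is to turn that signature into a longitudinal monitoring
instrument: train a binary classifier separating healthy controls (HC)
from recent-onset psychosis patients (ROP) on baseline rsFC, freeze it,
and then score an independent intervention sample at baseline (T0) and
follow-up (FU). Because a linear support vector machine produces a signed
decision score $s(x) = w^\top x + b$ whose sign encodes the predicted
class (here: positive = ROP), the within-subject difference

$$\Delta = s(x_{FU}) - s(x_{T0})$$

is interpretable as movement across the diagnostic hyperplane: $\Delta <
0$ is a shift toward the healthy-like side, $\Delta > 0$ toward the
psychosis-like side. We call $\Delta$ the *psychosis-likeness change*. The
package implements the whole chain — synthetic cohort generation,
connectivity preprocessing, classifier training, out-of-sample
monitoring, and the statistical battery relating $\Delta$ to
sensory-processing subgroups and cognitive gains.

### Connectivity features

Each scan is a $T \times R$ ROI time-series table (default $R = 160$, the
size of a standard functional atlas, giving $R(R-1)/2 = 12720$ edges).
Preprocessing per scan:

1. optional median-filter spike attenuation (`despike_median`, off by
   default) — a simple robust smoother occupying the despiking slot of
   the chain;
2. zero-phase band-pass, 0.01–0.08 Hz (4th-order Butterworth applied
   forward–backward; columns are demeaned first because at these low
   cutoffs filter startup transients would otherwise leak large offsets);
3. nuisance regression of the Friston-24 motion expansion (parameters,
   squares, one-frame lags, squared lags) plus WM/CSF traces, with the
   regressors band-passed identically to the data. Regressing *after*
   filtering with identically filtered regressors avoids reintroducing
   attenuated frequencies into the residuals;
4. Pearson correlation and row-major upper-triangle vectorization.

Motion QC uses Power-style framewise displacement (sum of absolute
backward differences, rotations converted at a 50 mm head radius); scans
with mean FD below 0.5 mm (configurable) are flagged as included.
Zero-variance ROIs are flagged and carried as missing edges rather than
silent NaN; the classifier's variance pruning removes them.

### The classifier

Training uses repeated nested double cross-validation: a $k$-fold outer
cycle (CV2) estimates generalizability while, inside every outer training
partition, a $k$-fold inner cycle (CV1) generates models; both cycles are
re-permuted, so the full ensemble holds
$k_{outer} p_{outer} k_{inner} p_{inner}$ fold models (default
$10 \times 10 \times 10 \times 10$). Every fold model fits, on its CV1
training rows only:

* zero-variance pruning;
* per-edge ordinary-least-squares residualization of sex and premorbid IQ
  (the deconfounding step; betas are stored and reapplied to any subject
  the model later scores);
* PCA retaining the leading components explaining 80% of training
  variance — the rank rule is this package's choice, made because
  dimensionality must be reduced below the fold sample size and a
  variance-share rule is scale-free and reproducible;
* 0–1 scaling of component scores by training min/max. Scores of new
  subjects can fall outside the training range; they are clamped to
  $[-0.5, 1.5]$ in scaled units to bound extrapolation of the linear
  score;
* a soft-margin linear SVM (libsvm) at fixed $C = 1$ with class weights
  $n_{total} / (2 n_{class})$, so the minority class is not swamped.
  No inner hyperparameter search is performed: $C$ is fixed, and CV1
  exists to generate the model ensemble.

Held-out (CV2) predictions use only models whose outer branch excluded
the subject; the vote is the majority of model-wise score signs, ties
fall to the sign of the mean score, and an exactly zero mean is called HC
(the negative class). Performance is summarized as balanced accuracy
(BAC), the mean of sensitivity (recall on ROP) and specificity (recall on
HC). Significance comes from a label-permutation test in which the whole
nested CV is re-run per permutation and the p-value uses the add-one
estimator $(1 + \#\{BAC_{perm} \ge BAC_{obs}\})/(1 + n_{perm})$.

Feature reliability is the *CV ratio*: each model's hyperplane weights
are back-projected to edge space (un-scaled through the stored 0–1
scaling slope, then through the PCA basis, zeros on pruned edges), and an
edge's reliability is its mean weight divided by the standard error
across all models. The back-projection order (un-scale, then basis) is a
declared convention. Edges with zero weight SE get a flagged, non-finite
ratio and are excluded from percentile ranking. The percentile of the
20th-ranked edge among 12720 is ≈ 99.84; the package therefore ranks by
|CV ratio| and takes a top-$k$ (default 20) rather than applying a fixed
percentile cut.

### Monitoring and calibration

Out-of-sample scoring (`score_oocv`) applies *all* fold models,
unmodified, and averages: with no principled way to prefer a subset of
branches for external subjects, the full-ensemble mean is the
deterministic, leakage-free choice. Probabilities come from Platt
scaling, $p(\text{ROP} \mid s) = 1/(1 + e^{As + B})$, fitted by Newton
iterations on the diagnostic sample's decision scores with Platt's
smoothed targets $(N_+ + 1)/(N_+ + 2)$ and $1/(N_- + 2)$, which keep the
fit finite even for perfectly separated scores. Calibration is strictly
monotone, so probability ranks always equal score ranks. An exactly zero
$\Delta$ maps to direction "none" and is excluded (with a log message)
from the shift-direction contingency test; continuous scores make this a
measure-zero event.

### The statistical battery

Group comparisons are Student's pooled-variance t-tests (the printed
statistics of the source tables reproduce under pooled variance, not
Welch) and Pearson chi-square without continuity correction (likewise
verified against the printed values). The cognition-by-time analysis is a
mixed-design ANOVA with two timepoints; with exactly two sessions the
design decomposes exactly into between-subject tests on the session mean
and within-subject tests on the session difference, computed with Type
III sums of squares. The ANCOVA for follow-up scores controlling baseline
is the standard nested-model residual-sum-of-squares comparison. Paired
contrasts report Cohen's $d$ as mean change over SD of change (the
within-subject variant; the source does not name one). Multiplicity is
controlled with Benjamini–Hochberg FDR (`stats::p.adjust`). Outliers are
masked per domain at |z| > 2 against the study sample; the median split
of learning scores assigns at-median ties to the maintainer group (with a
warning), which keeps the split deterministic.

## The synthetic cohort generator

No scan data accompany the analysis, so the generator stands in for the
study and defines the conditions every test runs under.

* **Spatial structure.** Two $R \times R$ covariance matrices share a
  base (identity by default) and differ by a signed offset `delta` on a
  random set of "affected" edges — mostly positive offsets, emulating the
  predominantly stronger coupling reported in patients. Perturbation can
  break positive definiteness when affected edges share nodes; matrices
  are repaired by eigenvalue clipping at $10^{-6}$ with
  re-symmetrization, the simplest reproducible projection, and the
  repair is reported in the returned spec.
* **Scans.** $T \times R$ draws from the group's Gaussian process
  (default $T = 190$, TR = 2 s, matching a ~6 min sequence; the source
  states no acquisition parameters, so these are declared defaults), plus
  unit-variance WM/CSF-like nuisance signals with random ROI loadings,
  continuous low-amplitude motion drift, and Bernoulli motion steps with
  motion-locked global intensity spikes so the FD/QC paths are exercised.
* **Cohorts.** The diagnostic sample defaults to 56 HC / 35 ROP with the
  published sex proportions and per-group premorbid-IQ and age moments,
  so the IQ–diagnosis confound the deconfounding step must handle is
  present by default; `confound_strength` adds more. The intervention
  sample defaults to 14 maintainers / 12 improvers.
* **Longitudinal shifts.** A follow-up covariance interpolates
  $\Sigma_{FU} = \Sigma_{ROP} + \delta_i(\Sigma_{HC} - \Sigma_{ROP})$
  with per-subject shift $\delta_i \in [-1, 1]$. Improver shifts are
  drawn N(0.25, 0.6) and maintainer shifts N(0, 0.45): these reproduce
  the published shift-direction proportions (about one third of improvers
  and one half of maintainers moving psychosis-ward) and the small
  within-group standardized changes, while keeping all subgroup-by-
  direction cells populated.
* **Behavior.** Attention gain follows
  $a \cdot 1[\text{maintainer}] + b \cdot \delta_i \cdot 1[\text{improver}] + \varepsilon$,
  other domains are pure noise, and learning scores separate the
  subgroups by a configurable gap. The defaults ($a = 0.4$, $b = 2$,
  noise SD 0.4, gap 3 SD) are a deliberately strong-effect regime fixed
  by an upfront power analysis (interaction power at $n = 26$ well above
  90%), so recovery checks are informative rather than borderline. This
  linear gain model is the package's own minimal structure matching a
  subgroup-by-direction interaction; it is synthetic, not a claim about
  real training data.

What the generator does *not* emulate: hemodynamic convolution,
scanner-site effects, spatially structured atlas geometry, non-Gaussian
BOLD artifacts, or any real relationship between symptoms and
connectivity. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that its operating characteristics (chance-level
behaviour under the null, detection and recovery under planted effects)
hold under the stated generative assumptions — they say nothing about
classification accuracy attainable on real patients.

## Problem sizes used by the test suite

The simulation checks run on a scaled-down connectome so the full battery
stays inside ordinary development budgets: 40 ROIs (780 edges) for the
null-BAC check, 24 ROIs for the strong-effect and recovery checks, 16
ROIs for permutation-uniformity, always with the study's sample sizes
(91 diagnostic, 26 intervention subjects) and a reduced 5-fold outer ×
3-fold inner scheme (one permutation each; 15 fold models). Permutation
tests in these checks use 100 permutations, and p-value calibration is
checked by a Kolmogorov–Smirnov test against uniformity over 50 null
seeds. The linear pipeline is dimension-agnostic, so none of these scale
choices touch the logic being verified; the `analysis/` drivers run the
same chain at 40 ROIs with a 5×5 double-permuted scheme (100 fold
models).

## Numerical choices and degenerate inputs

* PD repair: eigenvalue clipping at $10^{-6}$, re-symmetrization, repair
  flag returned; a matrix still non-PD afterwards is an error.
* Degenerate 0–1 scaling (a constant PC score in training) sets the slope
  to 1 and flags the component, making it inert rather than undefined.
* Rank-deficient nuisance designs are handled by pivoted QR with a
  warning (collinear columns dropped).
* The libsvm decision sign depends on class order of appearance; the
  stored hyperplane is re-oriented from the decision-value column name so
  positive always means ROP.
* Zero pooled variance in the t-test: $t = 0$ for equal means, an error
  (infinite statistic) otherwise. Zero change SD in the paired test:
  $d = 0$ when all changes are zero, an error otherwise.
* All generators are seed-deterministic: identical (config, seed) yields
  bit-identical cohorts, scans and fold assignments.

## Known limitations

* The despiking slot is a stub; no wavelet despiking is implemented.
* The identity base covariance makes null edges independent, which is
  cleaner than real connectomes; a user can supply any PD base.
* Only two sessions are supported; there is no trajectory model.
* The mixed ANOVA handles one or two two-level between factors with
  complete cases, not general designs; cells need at least 2 subjects.
* The extrapolation clamp on scaled component scores bounds decision
  scores of subjects beyond the training range. A side effect is an
  asymmetry in the monitoring statistic: follow-up patterns that worsen
  beyond the patient training distribution extrapolate into the clamp and
  their psychosis-ward score changes are compressed, while healthy-ward
  changes interpolate within the training range and are fully expressed.
  Simulated subgroup-by-direction cell counts inherit this asymmetry.
* Platt calibration is fitted on cross-validated mean scores of the
  diagnostic sample, which are mildly shrunken relative to single-model
  scores; ranks (the quantity the monitoring statistic uses) are
  unaffected.
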
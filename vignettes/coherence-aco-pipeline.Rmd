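---
title: "Coherence features, ant-colony feature selection, and nested cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence features, ant-colony feature selection, and nested cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohaco)
```

## The model

`cohaco` classifies two patient groups (by default labelled BD and MDD)
from resting-state EEG using band-averaged magnitude-squared coherence
(MSC) as the feature family, a metaheuristic wrapper search to pick a
subset of those features, a soft-margin SVM as the classifier, and nested
cross-validation as the estimate of generalization. This vignette explains
each stage's assumptions, the tunable parameters, and the design decisions
taken where the method left genuine freedom.

## Coherence features

For channels $x$ and $y$, the MSC at frequency $f$ is

$$H_{xy}(f) = \frac{|P_{xy}(f)|^2}{P_{xx}(f)\,P_{yy}(f)} \in [0, 1],$$

estimated by Welch averaging: the band-passed signal is cut into 650 ms
windows with 50 % overlap, each window is mean-detrended, tapered with a
Hanning window and Fourier transformed, and the auto-/cross-periodograms
are averaged across windows. Band coherence is the arithmetic mean of the
MSC over the bins inside a band, and features are Fisher-Z transformed,
$z = \operatorname{atanh}\sqrt{H}$.

Numerical and convention choices:

* **Window length.** 650 ms at 250 Hz is 162.5 samples; we use
  $\lfloor 0.65\,f_s \rfloor = 162$ samples (hop 81). The half-sample is
  immaterial to the estimate; the floor convention is configurable through
  `feature_config(win_ms = )`.
* **Band edges.** Delta 0.5–4 Hz, theta 4–8 Hz, alpha 8–13 Hz — the
  conventional clinical bands, configurable per analysis. With 162-sample
  windows the frequency resolution is about 1.54 Hz, leaving 2–3 bins per
  band.
* **Detrending.** Each window is mean-removed before tapering because the
  band-pass lower edge (0.15 Hz) lies below the resolution of a 650 ms
  window; without it, DC leakage contaminates the delta band.
* **Single-segment estimates are degenerate** (MSC $\equiv 1$ regardless
  of the signals); the estimator requires at least two windows and errors
  otherwise.
* **Fisher-Z convention.** For *squared* coherence the variance-stabilizing
  transform acts on the coherency magnitude, $\operatorname{atanh}\sqrt{H}$;
  the plain $\operatorname{atanh}(H)$ convention is available via
  `fisher_z(convention = "direct")`. The transform is applied to the
  band-averaged value (averaging first is the smoother choice; the
  alternative order is not implemented).
* **Band-pass.** Zero-phase Butterworth cascade: order-2 high-pass at
  0.15 Hz plus order-4 low-pass at 30 Hz, each applied forward and
  backward. A single order-4 band-pass section at a normalized edge of
  0.0012 is numerically fragile; the cascade is well-conditioned and meets
  the response targets (DC < 1 %, 10 Hz within 5 % of unity, 50 Hz
  < 10 %).

The default grid is 16 electrode pairs (left and right intrahemispheric
triangles F/C/P/T5,T6 and the interhemispheric pairs F3–F4, C3–C4, P3–P4,
T7–T8) times 3 bands = 48 features. Published descriptions of this montage
are internally inconsistent about the total (47 and 49 both appear
elsewhere); the pair list itself yields 48 and that is what the package
produces. The interhemispheric temporal pair is kept as T7–T8 verbatim,
so recordings must contain those labels alongside T5/T6.

## The synthetic cohort generator

No public dataset exists for the original clinical cohort, so the package
generates cohorts whose coherence structure is *known*. The generative
model is a shared-source model: for each planted effect (pair, band,
per-class target $h$), both electrodes receive one common band-limited
unit-variance source plus independent band-limited noise of variance
$\sigma_n^2$, all other channel content being independent band noise. Two
channels sharing one source with gains $g_x, g_y$ and noises
$\sigma_{n_x}^2, \sigma_{n_y}^2$ have exactly

$$H = \frac{(g_x g_y \sigma_s^2)^2}
  {(g_x^2\sigma_s^2 + \sigma_{n_x}^2)(g_y^2\sigma_s^2 + \sigma_{n_y}^2)}$$

at every frequency where the spectra are non-zero — the validation oracle
`analytic_pair_coherence()`. With unit gains and equal noise,
$\sigma_n^2 = 1/\sqrt{h} - 1$ hits a target $h$.

Implementation notes:

* Band-limiting is done in the frequency domain: each series is white
  Gaussian spectrum times a Butterworth-magnitude mask, inverse
  transformed. This is the same law as time-domain filtering of white
  noise (a Gaussian process is fully specified by its spectrum) and two
  orders of magnitude faster. The mask order is 16 — near-brick-wall — so
  that skirt leakage from neighbouring bands stays below the Welch
  estimator's resolution; with gentler masks, high coherence targets were
  visibly diluted by cross-band noise.
* A channel may carry at most one shared source per band; the spec of a
  cohort rejects electrode-overlapping effects in the same band because
  the closed form above assumes a single source.
* Residual estimator-side leakage (the Hann main lobe spans about two
  bins) still mixes a few percent of neighbouring-band noise into edge
  bins, so empirical band MSC sits slightly below very high targets when
  other-band noise is present. In the noiseless limit (`noise_sd` near 0)
  the estimate reaches the target essentially exactly. Tests therefore
  check mid-range targets under default noise and the 1-limit without it.
* The default cohort is 46 + 55 subjects (the two-class split of the
  motivating study; its own recruitment section says 48 + 58 elsewhere —
  the results-section split is used), 180 s at 250 Hz, with five planted
  effects on electrode-disjoint pairs per band
  (`planted_effect_map()`: two alpha, two theta, one delta) at coherence
  0.6 vs 0.2. These targets give a strong, realistic group difference
  (Fisher-Z gap of roughly 0.5 against between-subject estimation noise of
  a few hundredths at 180 s).
* What the generator does **not** emulate: ocular/muscle artifacts, 1/f
  background spectra, volume-conduction correlations, inter-subject
  variability of the *target* coherence (all subjects in a class share the
  same expected coherence). Passing tests therefore demonstrate that the
  pipeline recovers known structure through the full estimator chain — not
  that it would attain any particular accuracy on clinical data.

## Wrapper search

All searches maximize the subset fitness
$f(A) = m\,J(A) + n/|A|$ with $m = 0.92$, $n = 0.78$, where $J(A)$ is the
validation accuracy of an SVM trained on the candidate subset. The
parsimony term makes smaller subsets win ties, and with these weights a
single excellent feature can outscore a large mediocre subset — intended
behaviour for a biomarker search.

**Ant colony.** Each of `n_ants` ants draws a target size $k$ uniformly
from `subset_size_range` (default 10–35, bracketing the subset sizes the
motivating study reports) and picks $k$ distinct features by sequential
roulette with weights $\tau_j^{\sigma} \eta_j^{v}$. The heuristic
$\eta_j$ is the per-feature Fisher discriminant ratio rescaled to $(0,1]$
— the feature-selection analogue of the inverse-distance heuristic in the
travelling-salesman formulation, which has no direct counterpart here.
Pheromone evaporates at rate $\rho$ and every ant deposits
$\delta f(A)$ on the features it used (fitness-proportional deposits
replace the inverse-tour-length rule of the TSP setting, since here larger
fitness is better). Pheromone is clamped to $[\tau_{\min}, \tau_{\max}] =
[0.1, 5]$, max–min style, so stagnated trails remain recoverable.

**Improved ACO.** The reference description says only that heuristic
parameters were varied during optimization to counter stagnation and slow
convergence; the mechanism is unspecified. Our reading: $\sigma$ ramps
linearly 1 → 2 and $v$ ramps 2 → 0.5 over the iteration budget (trust the
filter heuristic early, trust learned pheromone late), and while the best
fitness has stagnated for 5 iterations the evaporation rate is doubled
(capped at 1). This is one defensible interpretation, marked as such.

**Stopping.** The stated halting criterion ("standard error as low as
possible") is not operational; searches stop at `n_iter` or after 10
iterations without improvement.

**Baselines.** The GA uses binary chromosomes, tournament selection (size
2), two-point crossover with probability 0.8, per-chromosome mutation of a
single uniformly chosen bit with probability 0.2 (a per-bit rate of 0.2
would randomize 20 % of the genome every generation and prevent
convergence), elitism of one, and repair of all-zero chromosomes. The
binary PSO uses sigmoid-transfer velocities with inertia 0.9 → 0.4,
$c_1 = c_2 = 2$ and velocity clamp ±4 — textbook defaults, since the
reference names PSO without parameters. Both can optimize either the
fitness above (default, for comparability) or raw accuracy
(`objective = "accuracy"`, matching the GA's original description).

## SVM

The dual problem is solved by a second-order working-set SMO written for
this package (the wrapper search trains tens of thousands of small SVMs
per experiment, so the solver lives in C++ with a combined
train-and-score path). Tests cross-check its decision values against an
independent implementation (e1071/libsvm) to $10^{-4}$ and verify dual
feasibility and margin conditions directly. Kernels: linear, polynomial,
RBF. The reference sets the RBF "width" hyperparameter to 0.2 while
denoting both the slack variable and the kernel width by the same symbol;
we read it as $\gamma = 1/(2\sigma^2) = 0.2$, configurable. $C = 10$.
Features are standardized with training-fold means and SDs before every
fit — coherence Z-values have heterogeneous scales and the RBF kernel is
scale-sensitive; standardization parameters never see validation or test
rows.

The positive class defaults to the first factor level (BD in the default
cohort) for sensitivity; configurable via `cv_config(positive = )`.

## Nested cross-validation

Six outer folds, stratified within one subject of the global class
proportions. Per outer cycle, five inner splits each run the wrapper
search with the evaluator "train on the other four inner folds, score on
the verification fold"; the five winners are ranked by verification
fitness (so subset size breaks accuracy ties), the top subset's SVM is
refit on all inner data, and that single model is scored once on the
outer test fold, which nothing upstream has seen. The description of fold
rotation in the reference is ambiguous; this is standard nested CV with
rotation, which matches its stated intent of keeping test folds "totally
unfamiliar". Reported metrics are per-fold accuracy, sensitivity and AUC
(Mann–Whitney with ties counted ½) and their arithmetic means — no score
pooling — plus the "global best" fold model for inspection; the honest
summary is the mean.

## Problem sizes used in validation

The test suite validates the full pipeline at the default study
conditions — a 46/55 cohort of 180 s recordings with the five planted
effects — using a colony of 20 ants × 30 iterations, 20 seeded
nested-CV runs for recovery, 10 label-permuted runs for the chance-level
null, and 10 paired seeds for the IACO-vs-ACO convergence comparison.
Unit tests use smaller synthetic matrices and shorter recordings where the
property under test does not depend on scale.

## Known limitations

* Delta-band coherence is estimated from only two frequency bins at the
  default window length; its targets are met less tightly than alpha's.
* The IACO schedule is an interpretation of an underspecified mechanism.
* The generator's within-class homogeneity makes planted effects easier
  to find than clinical group differences would be; accuracy on synthetic
  cohorts says nothing quantitative about clinical accuracy.
* EDF input is not implemented; recordings enter as delimited matrices
  with a manifest.
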
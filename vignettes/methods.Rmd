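---
title: "Decoding and representational analysis for backward-masking designs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and representational analysis for backward-masking designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskmvpa)
```

# The analysis problem

Backward masking curtails recurrent processing in the visual system while
largely sparing the initial feedforward sweep: a mask arriving ~17 ms after
a target truncates recurrence (the *early mask* condition), while a mask at
~600 ms leaves it intact (the *late mask* condition). Contrasting
multivariate object representations between these two conditions therefore
isolates the contribution of recurrent activity. `maskmvpa` implements the
complete analysis machinery for such a design — pairwise decoding of EEG
channel patterns over time, temporal generalization, time-frequency (power
and phase) decoding, ROI and searchlight decoding of fMRI response
patterns, representational similarity analysis (RSA) against layered model
RDMs with noise ceilings and commonality partitioning, and non-parametric
group statistics — together with a synthetic-data generator that emulates
the design, so every stage can be verified end to end without real
recordings.

# The synthetic generator

The generator is the package's specification of what the analyses are
supposed to detect. Each trial of subject-level EEG is

$$x(c, t) = a_{f}\, P^{f}_{c,o}\, g_f(t) \;+\; a_{r} m\, P^{r}_{c,o}\, g_r(t)
\;+\; a_{o}\, T_c \cos(2\pi f t + \phi_o)\, g_o(t) \;+\; \varepsilon(c, t),$$

with channel $c$, object $o$, and three signal components:

* **Feedforward**: a Gaussian transient $g_f$ (default peak 120 ms, FWHM
  100 ms) carrying object-specific channel patterns $P^f$. Present in both
  masking conditions.
* **Recurrent**: a sustained plateau $g_r$ (logistic onset at 150 ms,
  plateau ~450 ms) with its own patterns $P^r$, scaled by a mask-dependent
  multiplier $m$ (defaults: early 0.2, late 1.0). This is the component the
  early mask suppresses; it produces the off-diagonal spread in temporal
  generalization matrices.
* **Oscillatory**: a stimulus-locked oscillation (default 10 Hz) with a
  fixed channel topography $T$ whose *phase* $\phi_o$ codes object
  identity. Training a classifier at one time and testing half a cycle
  later meets anti-correlated patterns, reproducing below-chance
  off-diagonal decoding by construction.

Noise $\varepsilon$ is temporally white and spatially correlated
(AR(1) channel covariance, $\rho = 0.3$, unit scale). Real EEG noise is
neither white nor stationary; white-plus-spatial noise is sufficient for
the property tests this generator serves, and a pink-noise option was
deliberately left out of scope. Setting all three amplitudes to zero yields
data with no condition information, which must drive every decoding
statistic to 50% — the package's primary null check.

Population-level patterns are drawn once per ground truth; each subject
receives the population patterns plus Gaussian jitter (`subject_jitter_sd`,
default 0.2), so group statistics and noise ceilings are meaningful. A
`pattern_overlap` parameter interpolates between one geometry shared by
both masking conditions (1, the default) and fully mask-specific
geometries (0); the latter makes cross-condition decoding fall to chance
while within-condition decoding stays high, the signature the
within-vs-cross contrast is designed to detect.

The default design mirrors the reference experiment: 24 objects × 2
masking conditions × 53 EEG trials per cell (2,544 trials per subject), 64
channels, epochs −200..800 ms at 10-ms steps, and 12 fMRI runs with 2
presentations per condition per run (96 betas per run).

For fMRI, model-layer geometry is planted directly: `make_model_rdms()`
builds layer feature matrices as rotations between two random bases (so
adjacent layers correlate more than distant ones, emulating a deep
network's gradient of feature complexity), and each ROI's voxel patterns
are projections of a weighted mixture of layer features. The default
geometry gives the entry-level ROI ("EVC") weight on a shallow layer under
both masks, and the object-selective ROI ("LOC") weight on a middle layer
under the early mask and the deepest layer under the late mask — the
representational-shift scenario the RSA peak-shift test targets. A small
volume with an informative corner cube serves as the searchlight fixture.

# Preprocessing

Baseline correction subtracts the per-trial, per-channel mean of the 200 ms
pre-stimulus window. Multivariate noise normalization estimates the error
covariance from within-condition residuals around each object × mask cell's
mean time course, pooled over conditions and time points, applies analytic
(Ledoit–Wolf) shrinkage toward the scaled identity, and multiplies the data
by the inverse matrix square root. Two open choices were resolved as
follows: the covariance is estimated per time point and *pooled* (rather
than whitening each time point separately), and one whitening matrix is
computed per subject on all trials with both masking conditions pooled, so
within- and cross-condition decoding share a single transform. Shrinkage
guarantees invertibility even with duplicated channels.

# Decoding

The classifier is a linear maximum-margin SVM (LIBSVM via `e1071`) with
regularization constant 1 and no per-fold feature scaling — data reaching
the classifier are already noise-normalized, and these hyperparameters are
the conventional defaults for this analysis family. Trials of each
condition are averaged into 4 pseudo-trials (random binning; the surplus,
e.g. 53 mod 4 = 1, is dropped uniformly at random) and accuracy comes from
leave-one-pseudo-trial-out cross-validation, repeated (100 times in the
reference configuration; tests and examples use fewer) with fresh random
binnings. Accuracies are stored as percent with chance at 50, in K × K
symmetric matrices with an undefined diagonal; those matrices double as
neural RDMs for RSA.

Cross-condition decoding trains on one masking condition and tests on the
other, averaged over both directions; pseudo-trial binning is re-drawn
independently per direction and repetition (whether the reference analysis
re-binned jointly is unknowable from its description; independent
re-binning is the weaker assumption and is amortized by the repetitions).
Temporal generalization trains at each time point and tests at all others;
because train/test direction is meaningless the TGM is symmetrized by
averaging both directions. For efficiency the hyperplane $(w, b)$ is
extracted once per training fold and applied to all test time points by a
matrix product.

Time-frequency decoding uses per-channel power (64 features) or the
concatenated unit-normalized cosine/sine phase pair (128 features for 64
channels) at each time × frequency cell. ROI decoding groups the 12 runs
into 4 pseudo-runs of 3 (random grouping) and cross-validates
leave-one-pseudo-run-out. Searchlight decoding repeats this in spheres of
Euclidean radius 4 voxel units (center included, truncated at mask edges) —
the sphere-membership convention is geometric and includes the center,
matching `sphere_offsets(1)` = 7 voxels.

# Time-frequency decomposition

The wavelet bank spans 4–100 Hz in 50 logarithmically spaced frequencies.
The temporal FWHM of the Gaussian envelope is scheduled log-linearly from
500 ms at 4 Hz to 20 ms at 100 Hz. Two reading decisions are documented
here because the printed description underdetermines them: "power" is taken
as the magnitude of the complex coefficient (a literal square root of a
complex coefficient is not a power measure), and the spectral FWHM is
measured on the *power* spectrum — only under that convention does the
20–500 ms temporal schedule imply the printed 1–31 Hz spectral range, via
the Fourier-uncertainty relation
$\mathrm{FWHM}_f = 4\ln 2 / (\pi\,\mathrm{FWHM}_t\,\sqrt{2})$
(≈ 31.2 Hz at 20 ms, ≈ 1.25 Hz at 500 ms). Kernels are sampled at 500 Hz
(2-ms steps) on ±3.5 SD supports with unit-integral envelopes; epochs are
generated long (−600..1200 ms), transformed, downsampled to 20-ms steps,
and cropped — reflection padding exists but is off by default, mirroring
the generate-long-and-crop workflow.

# GLM with voxel-wise HRF selection

Condition responses are estimated per run by GLMs whose regressors are
event trains convolved with each member of an HRF family; per voxel, the
member with the lowest mean squared residual over the whole series is
selected (ties to the lowest index) and its betas kept. The reference
workflow drew 20 empirical HRFs from an external library; since that
library is an external dataset, the package substitutes a parametric
double-gamma family with peak latencies 3–9 s in 20 steps, which preserves
the selection logic and makes parameter recovery testable. Nuisance
regressors are shared across the 20 candidate GLMs.

# RSA, noise ceilings, and commonality

Model RDMs use 1 − Pearson over feature rows; brain RDMs are the decoding
accuracy matrices. RDMs are compared by Spearman correlation of their
lower-triangle vectors, computed per subject with group statistics across
subjects. Noise ceilings: the lower bound correlates each subject's RDM
with the mean of the others, the upper bound with the mean including the
subject, both averaged over subjects.

Commonality analysis partitions the target RDM's explained variance into
components shared and unique to two predictor RDMs. The exact formula is
not printed in the reference description, so the package adopts the
standard two-predictor variance-partitioning identity

$$C = R^2(t \sim a) + R^2(t \sim b) - R^2(t \sim a + b),$$

computed on rank-transformed lower-triangle vectors for consistency with
the Spearman-based RSA step. $C$ can be legitimately negative
(suppression), is bounded above by each pairwise $R^2$, and satisfies
$C + U_a + U_b = R^2_{full}$ exactly; the test suite asserts the identity
to $10^{-10}$ against `lm()`-based partitioning.

# Resampling statistics

All group inference is sign-permutation based: participant effects (e.g.,
accuracy − 50) are randomly multiplied by ±1; the observed sample is
included in the null so p ≥ 1/n_perm, a standard validity guarantee that
the reference description leaves implicit. Cluster-based correction
thresholds per-point permutation p-values at 0.005, forms clusters under
orthogonal adjacency (2/4/6 neighbors in 1/2/3 dimensions — the
conservative conventional choice), scores them by *size* (the statistic
the reference names), and compares against the permutation null of the
maximum cluster size at a 0.05 cluster threshold. BH-FDR handles small
sets of unrelated comparisons. Peak latencies get bootstrap CIs (resample
subjects, argmax of the group mean, 2.5/97.5 percentiles); argmax ties
break to the earliest point, which matters because bootstrap distributions
do hit ties. The peak-shift test permutes condition labels within subjects
and reports a two-tailed p with Hedges' g
($g = \bar d/s_d \cdot (1 - 3/(4(n-1)-1))$).

# Genetic subset selection

The stimulus-selection task — choose k of K items minimizing the absolute
Spearman correlation between two reference RDMs restricted to the subset —
is solved by a genetic algorithm. The reference description names only the
method, so all hyperparameters are package choices: population 200,
500 generations, binary tournament selection, uniform crossover on
membership vectors with repair to size k, per-gene swap mutation at 0.02,
and single-individual elitism (making the best objective non-increasing).
The suite verifies exact agreement with exhaustive search on C(8,4)
instances and superiority over a random-subset baseline.

# Numerical and scale choices

Tests and the acceptance script run at deliberately reduced problem sizes —
typically 4–8 objects, 8–12 trials per cell, 16–64 channels, coarse time
grids, 3–10 repetitions, and 300–10,000 permutations — chosen so the whole
suite completes in a few minutes while every property remains detectable;
the full-scale reference configuration (24 objects, 53 trials, 100
repetitions, 10,000 permutations) is exposed as the defaults of
`design_spec()` and `read_run_config()`. Determinism is end-to-end: every
user-facing function takes a seed, and `run_pipeline()` derives named
per-stage substreams from one config seed.

# What passing tests do and do not show

The generator produces Gaussian, stationary, white-in-time noise, linearly
separable patterns, and phase-coding implanted exactly where the analyses
look for it. Passing tests therefore demonstrate that the machinery is
correct — chance level is unbiased, planted effects are recovered, error
rates are controlled, oracles agree — not that real EEG/fMRI data would
yield any particular result. Peak latencies, cluster extents, peak
frequencies and effect sizes reported from real recordings depend on the
recordings themselves and are outside what synthetic verification can
reproduce. Known limitations: no forward head modeling or realistic source
projection, no BOLD physiology, no 1/f noise, no nonlinear classifiers,
and no separation of oscillatory from evoked-transient contributions in
the time-frequency analyses.
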
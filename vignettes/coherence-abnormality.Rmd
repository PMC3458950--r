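---
title: "Spectral-coherence abnormality analysis: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-coherence abnormality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectanom)
```

## The problem

Resting-state fMRI connectivity between two brain regions — here the
posterior cingulate cortex (PCC), a core default-mode node, and the dorsal
anterior cingulate cortex (dACC) — is usually summarised by a single
correlation coefficient. That collapses the frequency structure of the
coupling. This package instead represents each subject by a *spectral
coherence profile*: the squared frequency-domain correlation between the
two region signals at 125 frequencies, and then asks a normative question:
**how atypical is each subject's profile relative to the pooled cohort?**
A one-class support vector machine (OC-SVM) turns the profile into a scalar
abnormality index, rank tests compare the index between groups, and a
leave-one-frequency-out analysis attributes the group difference to
frequencies.

## The model, stage by stage

### Region signals

Signals are either loaded from two-column TSV tables or extracted from 4D
NIfTI volumes as the mean over a spherical ROI (radius 7.5 mm; PCC at MNI
(-5, -49, 40), dACC at (8, 7, 38)). Voxel membership is decided by
voxel-centre distance through the image affine; no partial-volume
weighting. Every signal is normalised to mean zero and variance one using
the population (1/T) variance, so "unit variance" is a property of the data
at hand rather than an estimator convention. Inputs are assumed already
preprocessed (motion correction, normalisation, filtering are out of
scope).

### Parametric coherence via a bivariate VAR

The signal pair is modelled as a vector autoregression
\(z_t = \sum_{k=1}^{p} B_k z_{t-k} + e_t\), \(e_t \sim N(0, \Sigma)\).
Coefficients are estimated by solving the multivariate Yule-Walker system
built from biased (1/T) sample autocovariances; the biased divisor keeps
the block-Toeplitz system positive semi-definite. The implementation is
checked to machine precision against base R's `ar(method = "yule-walker")`
at every order. The lag order is chosen per subject by AIC over orders
1-10, in the ranking-equivalent form \(T \log\det\hat\Sigma_p + 2pd^2\)
(d = 2); ties go to the smaller order. Per-subject selection reflects
expected inter-subject variability.

The spectral density matrix is
\(S(f) = A(f)^{-1} \Sigma A(f)^{-H}\) with
\(A(f) = I - \sum_k B_k e^{-i 2\pi f \,\mathrm{dt}\, k}\); the \(1/2\pi\)
density constant is omitted because it cancels in coherence. Coherence is
the magnitude-squared form
\(C(f) = |S_{xy}|^2 / (S_{xx} S_{yy}) \in [0, 1]\); the unsquared magnitude
variant is available behind a config switch, but the squared form is the
default because the downstream analysis implicitly assumes a [0, 1]
feature scale.

Coherence is sampled at \(f_j = j \cdot f_{\mathrm{Nyq}} / 125\),
\(j = 1..125\): the grid excludes 0 Hz and includes the Nyquist frequency
(0.25 Hz at TR = 2 s). The DC point is excluded deliberately — after
z-normalisation and the high-pass filtering typical of resting-state
preprocessing it is uninformative, and "spanning 0 to 0.25 Hz" is read as
the covered band rather than grid membership.

### Abnormality index

The 42 coherence profiles of a two-group contrast are pooled and treated as
one population — neither group is privileged as the normative reference,
which is the protocol's bias control. A \(\nu\)-parameterised one-class SVM
with RBF kernel is trained on the pooled matrix:
minimise \(\tfrac12 \alpha^\top K \alpha\) subject to
\(0 \le \alpha_i \le 1/(\nu n)\), \(\sum_i \alpha_i = 1\). Defaults are
\(\nu = 0.5\) (with two equal groups, half the pooled sample may fall
outside the learned region) and \(\gamma = 1/d\) — the standard
dimension-reciprocal heuristic, giving 1/125 on the default grid. \(\gamma\)
is deliberately not tuned, to avoid overfitting; when the relevance
analysis drops a column the heuristic is re-applied (1/124), with a config
switch to freeze 1/125 instead.

The solver is a deterministic pairwise coordinate-descent (SMO-type) method
with KKT tolerance 1e-6 and a deterministic feasible start, so no seed is
involved in training; it is verified against an exhaustive active-set
enumeration on tiny instances and against `e1071::svm` (whose dual
coefficients are scaled by \(\nu n\) relative to the sum-to-one
convention). The offset \(\rho\) is the median of the fitted scores over
margin support vectors, a numerically robust version of the usual
single-support-vector rule; any standard convention moves indices by at
most the solver tolerance. The abnormality index of subject \(v\) is the
negated decision score \(\rho - \sum_i \alpha_i k(x_i, v)\): higher means
less typical, positive means outside the learned normative region.

### Group comparison and confound checks

Groups are compared by a one-tailed Mann-Whitney test with the case group
hypothesised to have the **greater** median index (cases are expected to be
more abnormal). The implementation wraps `wilcox.test`: exact when the
pooled sample is at most 12 and tie-free, otherwise the tie-corrected
normal approximation with continuity correction. Confound checks are a
two-tailed Mann-Whitney on sex and the overall F-test of a quadratic
least-squares regression of index on age.

### Frequency relevance

For each frequency \(j\), both groups' features are reduced by dropping
column \(j\) and the whole mixed-group analysis is retrained. With
\(\Delta = m_1 - m_2\) the difference of group median indices, the
relevance of frequency \(j\) is the **drop** its exclusion causes:
\(r_j = \Delta_{\mathrm{full}} - \Delta_{(-j)}\). The raw
\(\Delta_{(-j)}\) values are also reported and can be selected as the
curve instead; the drop convention is the default because it directly
measures each frequency's contribution to discrimination. Because one-class
training never sees group labels, a label-permutation null for the curve's
peak height costs nothing beyond re-computing medians on the stored index
matrix — no retraining.

## The synthetic cohort generator

The generator exists so every stage is testable without imaging data. It
emulates the study conditions: two groups of n = 21, T = 197 volumes at
TR = 2 s, cross-coupling confined to the low-frequency band. Each subject
pair shares a band-limited Gaussian latent with weight \(\lambda\):
\(x = \sqrt{\lambda} z + \sqrt{1-\lambda}\, w_x\) (likewise \(y\)), so true
coherence rises monotonically with \(\lambda\) inside the band and is
nearly zero outside.

The default group profiles encode a *reduced and heterogeneous* case group:
both groups draw \(\lambda \sim N(0.7, 0.03)\) (clipped to [0.5, 0.9]) over
0.012-0.048 Hz, controls are coupled over the full band, and each case
subject only over a random sub-band of half-width 0.005-0.008 Hz. Two
empirical findings from the design phase motivated this geometry:

* A pooled one-class model is *insensitive to a pure location shift*
  between two equally tight clusters — by symmetry both medians sit at the
  boundary and the test has no power. What separates groups is
  **heterogeneity**: case subjects must each be atypical in their own way.
  Clinically this matches the greater inter-subject variability reported in
  patient populations.
* Group differences must be kept strictly inside the perturbed band.
  Designs in which the groups differed in coupling-band *edges* or in
  overall spectral complexity leaked discriminative signal into the VAR
  lag-order distribution and thence into high-frequency coherence texture —
  an artifactual confound (the real study explicitly verified lag orders
  did not differ between groups). Sharing the band support distribution-wise
  and the coupling-weight distribution between groups removes it.

Ages are drawn from per-group normal models (case 36.5 +/- 7.1; control
35.5 +/- 9.9) and sexes from per-group Bernoulli models (16/21 and 10/21
male), so confound checks run on realistic inputs. Master seed to
per-subject seed derivation uses a fixed prime stride modulo 2^31 - 1;
cohorts are byte-reproducible.

What the generator does *not* emulate: hemodynamic forward modelling,
physiological noise, scanner drift and artifacts, spatial structure. A
passing synthetic suite therefore demonstrates the *statistical machinery*
— not that real resting-state data carry the effect.

## Numerical choices and degenerate inputs

* Autocovariance divisor 1/T; block-Toeplitz solve via `solve`; innovation
  covariance symmetrised after the subtraction.
* Unstable fitted models (companion spectral radius >= 1) warn rather than
  fail; a numerically singular transfer matrix at some frequency is an
  error naming the frequency.
* Coherence values are clamped to [0, 1] against roundoff at the
  boundaries.
* AIC with a non-positive-definite innovation estimate scores +Inf, so such
  orders are never selected; ties prefer the smaller order.
* Constant series cannot be z-normalised (error); masks that miss the field
  of view name the offending ROI.
* The OC-SVM solver caps iterations and reports the duality gap on
  non-convergence; identical training rows produce equal scores by
  symmetry.

## Problem sizes used by the test suite

Oracle-equivalence and parameter-recovery checks simulate long series
(T = 200,000 for the Welch comparison, T = 100,000 for coefficient
recovery, 20 replicates of T = 5,000 for order selection); the end-to-end
cohort checks use the full study geometry (42 subjects, 125 features, 126
one-class trainings). The null-calibration check uses 2,000 Mann-Whitney
replicates at n = 21 + 21. These sizes were chosen so that Monte-Carlo
error is comfortably below each asserted tolerance.

## Known limitations

* With T = 197 samples the VAR coherence estimate blurs spectral structure
  by roughly one estimator resolution step (~0.01 Hz). Leave-one-frequency-
  out relevance inherits this: in repeated synthetic cohorts the curve's
  argmax occasionally lands one or two grid bins outside the true perturbed
  band, most often just below its lower edge (the fitted spectrum
  extrapolates band structure toward DC). Band-edge conclusions from the
  relevance curve should be read with that resolution in mind.
* The relevance score measures *marginal* contribution under exclusion of
  one frequency at a time; heavily redundant neighbouring frequencies share
  credit, so a flat-topped relevance region does not mean individual
  frequencies are unimportant.
* The approach is restricted to a two-region analysis by construction;
  extending to more regions would square the feature count and erode the
  one-class model's power at these sample sizes.
* In-sample indices are used deliberately (the protocol's symmetry is the
  bias control), so indices must not be interpreted as out-of-sample
  abnormality estimates for new subjects without retraining conventions.
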
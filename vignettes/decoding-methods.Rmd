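---
title: "Decoding on-going pain states from ASL perfusion images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding on-going pain states from ASL perfusion images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslgpc)
```

# The problem

Arterial spin labeling (ASL) MRI yields quantitative maps of regional
cerebral blood flow (rCBF) and is sensitive to *tonic* brain states over
minutes — exactly the regime of on-going clinical pain, which cannot be
chopped into the blocks that conventional task fMRI requires. In a
repeated-measures postsurgical (third-molar-extraction) design, every
subject is scanned before surgery, after each of two extractions (left and
right, order pseudorandomized), and at a pain-free follow-up, with six ASL
scans per session. The question for the analyst: can a multivariate pattern
classifier, reading the whole-brain rCBF image, tell the postsurgical
(in-pain) state from a pain-free state in a *new* subject — and with how few
scans?

`aslgpc` implements that analysis end to end: a synthetic cohort generator
(the original MRI data are not publicly deposited), the preprocessing tail,
a Gaussian process classifier (GPC) with expectation propagation (EP)
inference, subject-level leave-one-out cross-validation (LOOCV),
repeated-measures permutation significance testing with Holm step-down
correction, a scan-number reduction analysis, and discriminative pattern
("g-map") extraction.

# The classifier

## Model

For feature vectors $x_i \in \mathbb{R}^d$ (the in-mask voxels of one rCBF
image) and labels $y_i \in \{+1, -1\}$ (postsurgery vs comparison state),
the latent function $f$ gets a zero-mean GP prior with a *linear* covariance

$$k(x, x') = s \, \frac{\langle x - \bar{x}, x' - \bar{x}\rangle}{d} + b,
\qquad s = e^{\theta_1},\; b = e^{\theta_2},$$

where $\bar{x}$ is the training-fold feature mean. Labels enter through a
probit likelihood $p(y_i \mid f_i) = \Phi(y_i f_i)$. The class-$(+1)$
predictive probability for a test point is
$\Phi\!\left(\mu_* / \sqrt{1 + \sigma_*^2}\right)$ with $(\mu_*, \sigma_*^2)$
the predictive latent moments.

Three choices here are this package's own, where the underlying approach
leaves them open:

* **$1/d$ normalization** of the dot product, so that hyperparameter scales
  are comparable across feature dimensions (mask sizes). Purely a
  conditioning device; it can be disabled (`d_normalize = FALSE`).
* **Training-mean centering** before the dot product. A linear-kernel GPC is
  translation-sensitive; centering makes the bias hyperparameter $b$ absorb
  the class offset cleanly. Centering always uses the *training fold's*
  mean, so no test information leaks into training.
* **Bias as a kernel offset** rather than an explicit mean function: the
  scale-plus-offset kernel above is recorded as this package's definition of
  the "scaling and bias" hyperparameters.

## Inference

The probit likelihood makes the posterior non-Gaussian; EP approximates it
with Gaussian site factors $\tilde{t}_i(f_i)$, visited in ascending index
order. Numerical policies (all tested):

* convergence when the largest site-parameter change in a sweep is below
  `1e-4` (default), hard cap 60 sweeps with a warning;
* no damping by default; an update that would drive a site precision
  negative is damped by 0.5 and, failing that, clipped at zero;
* jitter of $10^{-8}\times$ the mean kernel diagonal before factorization;
* posterior moments recomputed in the numerically stable
  $B = I + S^{1/2} K S^{1/2}$ form at the end of every sweep.

EP's moments, evidence and predictive probabilities are validated against
Gauss–Hermite quadrature of the exact 1-D and 2-D integrals (to $10^{-3}$)
in the test suite.

All heavy computation uses the $n \times n$ kernel (dual) form — the natural
representation when voxels vastly outnumber samples. Fold-wise centering is
done directly on a precomputed Gram matrix, which the tests verify against
an explicit primal (feature-space) computation.

## Hyperparameters

$(\theta_1, \theta_2)$ are set by type-II maximum likelihood: box-bounded
(L-BFGS-B, $[-10, 10]^2$) ascent of the EP log evidence from the fixed start
$(0, 0)$. The optimizer is deterministic and is re-run inside every LOOCV
training fold. Whether the original analysis re-optimized inside every
*permutation* replicate is not stated; this package re-optimizes by default
and offers `reoptimize_permutations = FALSE`, which optimizes once on the
unpermuted data and freezes the values for the observed *and* all null
cross-validations — keeping the two comparable while cutting the cost by two
orders of magnitude.

# Evaluation

* **LOOCV at the subject level**: one fold per subject; all of the held-out
  subject's samples are predicted by a model that never saw any of them.
* **Sensitivity / specificity** at the 0.5 probability threshold; a sample
  *exactly* at the threshold counts as misclassified for either class (the
  conservative reading of a strict-inequality decision rule). Balanced
  accuracy is their mean — an exact identity the tests assert against
  published per-class rates.
* **Permutation test**: each permutation independently flips, with
  probability 1/2, *all* condition labels of each subject together,
  respecting the repeated-measures design in which every subject contributes
  both classes. The plus-one estimator
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$ keeps
  $p > 0$; with 1,000 permutations its floor is $\approx 0.001$. The
  literal "proportion achieving higher" reading would allow $p = 0$, which
  is statistically improper for a sampled null.
* **Holm step-down** across the family of all tests produced by one
  scan-reduction run (both sides together when both are requested).
* **Scan reduction**: for $n = 1\ldots6$ the last scans are dropped in
  reverse acquisition order, the kept scans averaged into one image per
  subject-session, and the full LOOCV (and permutation test) repeated.

The sample construction for the all-sessions pre-vs-post comparison is
ambiguous in the source material (accuracy in nineteenths suggests one
prediction per subject per class). The default here averages each subject's
presurgical sessions into one sample and postsurgical sessions into another
(`samples = "averaged"`); `samples = "per_scan"` enters each image
separately. Neither is asserted as *the* original construction.

# The g-map

The discriminative pattern is the posterior mean in input (voxel) space: no
explicit formula is printed in the source description, so this package
defines it as

$$g = X_c^\top K^{-1} \mu,$$

with $X_c$ the centered training features, $K$ the (jittered) training
kernel and $\mu$ the EP posterior latent mean — the projection of the
training data onto the direction of maximal class difference. The default
sign convention (`negative_favors_positive`) matches the published display:
negative coefficients favor the postsurgical class. Maps are defined only on
in-mask voxels (background is explicit `NaN`, never silent zeros) and are
never thresholded. By default the map is fitted on all data; per-fold maps
are available by fitting on fold subsets.

# The synthetic cohort generator

No accession exists for the original ASL data, so the generator emulates the
design as a *stated world*, not a tuning dial:

* 20 subjects × 5 imaging sessions (presurgery, postsurgery ×2 each,
  follow-up) × 6 scans per session; surgery side order balanced and
  pseudorandomized from the seed.
* Per scan: `baseline_cbf * g_s + 1[postsurgery] * effect_scale * template +
  noise`, with `g_s ~ lognormal(0, 0.15)` fixed per subject — the
  multiplicative inter-subject global perfusion spread that motivates
  median-1000 scaling — and i.i.d. Gaussian voxel noise per scan. Noise is
  spatially white *before* smoothing; spatial correlation is induced by the
  8 mm kernel rather than simulated directly (the simplest model consistent
  with the pipeline).
* The spatial template is a sum of Gaussian blobs standing in for the
  published pattern: bilateral thalamus-, insula- and anterior-cingulate-like
  foci with positive amplitude, occipito-parietal foci with negative
  amplitude. These are schematic positions in grid fractions, not anatomy.
* Default grid 24×32×24 at 3 mm isotropic — a desk-scale stand-in for the
  48×64×60, 1×1×3 mm acquisition — keeping a full LOOCV plus permutation
  run in minutes on one CPU.
* The brain mask defaults to a centred ellipsoid covering ~60% of the grid:
  arbitrary but deterministic.
* VAS pain scores are Gaussian around `presurgery_mean` (+ the side-specific
  postsurgical delta), clipped to [0, 100]. The deltas default to the
  published group differences, 52.41 (left) and 50.779 (right). The
  presurgical mean (15) and sd (8) are this package's choices: mild
  presurgical discomfort at a spread small enough that clipping at 0 cannot
  bias the realized deltas away from the printed values (with a mean of 15
  and sd 8, the clipping bias is < 0.1 VAS points). Alertness has no
  condition effect, matching the reported null.
* Numeric levels without a stated value (`baseline_cbf = 50` scaled CBF
  units, `scan_noise_sd = 8`) were fixed once at values a perfusion analyst
  would call plausible for smoothed rCBF maps; their absolute scale is
  largely irrelevant because median-1000 scaling renormalizes every image.

**Effect size.** No quantitative postsurgical rCBF effect size is published,
so `effect_scale` is explicitly a tuned quantity: `tune_effect_scale()` sets
it so that the contrast-to-noise ratio of the session-averaged, smoothed
image — peak absolute smoothed template amplitude over the analytically
propagated post-smoothing, post-averaging noise sd — hits a target (1.5 for
the accuracy-band checks). CNR is linear in `effect_scale`, so tuning is a
single ratio, computed analytically before any classifier ever runs.

## What a green test does and does not establish

The generator reproduces the *statistical structure* the decoding analysis
assumes: repeated measures, subject-level global scale variability,
spatially distributed condition effects, independent scan noise, seeded
reproducibility. It does not attempt MRI physics, motion, realistic
neuroanatomy, subject-specific effect topographies, or the image artifact
that excluded one subject's session in the original cohort. Green tests
therefore establish that the *pipeline* behaves as specified on data with
the assumed structure — not that the published real-data accuracies are
reproduced; those depend on undeposited MRI data and are out of reach at
desk scale.

# Degenerate inputs and numerical edges

* Median scaling refuses non-positive medians (empty or degenerate images);
  the median is taken over in-mask voxels by default, since background zeros
  would dominate a whole-volume median (a config switch restores the
  whole-volume variant, as the original choice is unstated).
* Smoothing uses reflection boundaries, the choice that preserves constant
  images exactly; `fwhm = 0` is the identity.
* LOOCV refuses training partitions missing a class, naming the offending
  subject; ROC and confusion statistics refuse one-class test pools.
* EP warns (not errors) on non-convergence; an indefinite kernel after
  jitter is a hard error.
* Predictive probabilities are clamped to the open interval (0, 1) at
  machine precision.

# Reproducibility

Every random draw traces to an explicit seed: the cohort seed for
simulation, the permutation seed for significance testing, and the single
top-level seed of `run_config()` from which stage seeds are derived. The
generator and permutation code save and restore the caller's RNG state.
Identical configurations reproduce byte-identical reports (timestamps are
never written into hashed artifacts).

# Known limitations

* The laterality comparison (left vs right postsurgery) is null *by
  construction* here — the synthetic effect template is side-agnostic — so
  only its chance-level behaviour is meaningful, mirroring the near-chance
  published result.
* EP fixed points are reached to a tolerance; order-invariance holds to that
  tolerance (tests tighten it where exact invariance is asserted).
* The NIfTI-1 codec is deliberately minimal (single-file, little-endian,
  3-D; float32 output with a diagonal RAS affine). It is cross-validated
  against nibabel but is not a general-purpose reader.
* With 12-subject cohorts the LOOCV balanced accuracy under the null is
  slightly pessimistic (folds are correlated and anti-learning is possible);
  its mean over replicate cohorts stays within a few points of chance, which
  is what the calibration checks assert.
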
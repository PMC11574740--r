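---
title: "Imaging markers of post-traumatic epilepsy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging markers of post-traumatic epilepsy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Post-traumatic epilepsy (PTE) is recurrent unprovoked seizing that emerges
more than a week after a traumatic brain injury (TBI). Predicting which TBI
patients will develop PTE from early MR imaging would let treatment and
trials start before the first seizure. `ptemarkers` implements a complete
marker-discovery pipeline for this problem on a balanced PTE / non-PTE TBI
cohort:

1. **Unsupervised lesion scoring.** A slice-wise variational autoencoder
   (VAE) is trained on (mostly lesion-free) FLAIR-like anatomy. Because the
   VAE learns to encode only normal anatomy, decoding a lesioned scan
   yields a lesion-free version, and the per-voxel residual
   `|original - decoded|` is a lesion score. A 7x7 median filter removes
   isolated residual pixels; a voxel-wise one-class SVM across subjects
   turns scores into binary lesion masks; counting mask voxels per region
   gives 15 ROI lesion volumes.
2. **Functional features.** From resting-state series: the amplitude of
   low-frequency fluctuations (ALFF), i.e. band power in 0.01-0.1 Hz, per
   voxel and averaged per ROI; and ROI-to-ROI functional connectivity, the
   15 x 15 Pearson matrix of ROI-mean series whose strict upper triangle
   (105 values, Fisher z-transformed) is the feature vector.
3. **Group statistics.** TBI lesions strike different places in different
   people, so group differences appear as *variance* differences rather
   than mean shifts. The central test is a one-sided variance-ratio F
   statistic (PTE variance over non-PTE variance) whose null distribution
   is obtained by permuting group labels (1000 permutations by default),
   with Benjamini-Hochberg FDR control across voxels or ROIs. Lobe-wise
   lesion volumes are compared with a one-sided rank-sum test.
4. **Classification.** The 15 + 105 + 15 = 135 features feed
   PCA-plus-classifier models (RBF-kernel SVM, linear SVM, random forest,
   and a 32/16/16 multilayer perceptron), evaluated by nested
   leave-one-pair-out stratified cross-validation: each outer test fold
   holds exactly one PTE and one non-PTE subject, and standardization, PCA
   and hyperparameter selection happen strictly inside each outer training
   set. Significance of the AUC comes from a permutation null (labels
   shuffled, one full CV pass per draw, rank-sum comparison), and the
   effect of sample size from a learning curve with quadratic
   extrapolation.

Real cohorts of this kind live behind restricted-access repositories, so
the package ships a seeded synthetic cohort generator that reproduces the
*statistical structure* the analysis assumes, making every downstream stage
testable end to end.

## The synthetic cohort generator

`cohort_config()` fixes the study conditions. The defaults mirror the
design the pipeline targets: 36 subjects per group; 153 resting-state
volumes at a repetition interval of 2 s (so the Nyquist frequency is 0.25
Hz and the 0.01-0.1 Hz ALFF band is comfortably inside it); a 15-region
lobe-level parcellation (bilateral frontal, parietal, temporal, occipital,
insula, cingulate, plus brainstem, cerebellum and corpus callosum) obtained
by deterministic Voronoi tiling of an ellipsoidal brain mask around fixed
anatomically-placed seeds.

Group differences are planted the way the statistics expect to find them:

* **Lesions** are spherical hyperintense blobs (radius 3 voxels, additive
  contrast 0.15 on a [0,1] intensity scale, i.e. 3x the 0.05 anatomical
  noise sd) planted per ROI with a group-dependent *prevalence*. The
  default preset elevates PTE prevalence in the bilateral temporal lobes,
  cerebellum and right occipital lobe (0.35-0.45 vs a 0.10 base rate),
  echoing where post-traumatic epileptogenesis is typically reported. A
  prevalence gap produces an across-subject variance difference, which is
  exactly what the one-sided F-test detects; group means barely move.
* **ALFF** differences are planted as variance ratios of a per-subject,
  per-ROI band-power scale (non-PTE coefficient of variation 0.2; PTE
  larger by the square root of the configured ratio), not as mean shifts.
* **Connectivity** differences subtract a fixed amount from the target
  correlation of selected ROI pairs in the PTE group; the perturbed matrix
  is projected back to a valid correlation matrix by eigenvalue clipping at
  1e-6 followed by diagonal renormalization — simple and reproducible.

Three presets bundle these choices: `"default"` (moderate, paper-like
effects), `"null"` (no group difference anywhere — used for calibration
studies), and `"strong"`. The strong preset exists for power and recovery
checks and deliberately plants a strong effect in *every* feature channel
(lesion prevalence 0.9 vs 0.05 in four ROIs, ALFF variance ratio 8 in six
ROIs, and -0.35 correlation shifts on all temporal-to-frontal/parietal/
insula/cerebellum pairs): an early draft that only strengthened the lesion
arm made the combined-features classifier look worse than the best single
block simply because 120 uninformative columns diluted the PCA, which
defeats the preset's purpose of testing multi-feature recovery.

Per-subject seeds are derived deterministically from the cohort seed via a
small linear-congruential hash, so identical configurations reproduce the
cohort bitwise and any single subject can be regenerated alone. Demographic
covariates (age, sex) are not emulated: the analysis never consumes them.

What the generator does *not* emulate: MR physics, motion or physiological
artifacts, registration error, partial-volume effects, site effects, or
spatially correlated noise. Passing tests therefore demonstrate the
*statistical correctness* of the pipeline under its own assumptions, not
performance on clinical data.

## The VAE and its training

The architecture follows the classic small convolutional VAE: three
encoder blocks (3x3 convolution with stride 2, batch normalization, ReLU)
with channel widths (32, 64, 128) by default; two fully connected
bottleneck heads producing the latent mean and log-variance (latent
dimension 32); a decoder with one fully connected layer, three transposed
convolution blocks (4x4, stride 2, batch norm, ReLU) and a final same-size
deconvolution to one channel with a sigmoid output. Slices are resized to
the network input (128 x 128 by default) by bilinear interpolation and
scores mapped back the same way. The loss is the standard evidence bound:
per-pixel Gaussian reconstruction error plus `kl_weight` times the KL
divergence of the latent posterior from the unit Gaussian; `kl_weight = 0`
recovers a plain autoencoder. Robustness to the occasional lesioned
training slice is an empirical property of training on mixed data, not a
special loss.

The network engine is written in plain R matrix algebra (im2col
convolutions, scatter-add col2im, explicit batch-norm backward, Adam), and
every analytic gradient is verified against central finite differences in
the test suite at tolerance 1e-4. Inference decodes from the latent *mean*
(no sampling), so score maps are deterministic given a trained model, and
training is deterministic given its seed. Batch-norm running statistics
are an exponential moving average (momentum 0.9) initialized from the
first batch.

Numerical and scale choices made where the design was open:

* Score = absolute residual. Lesions are hyperintense in FLAIR, but the
  absolute value also captures decoder overshoot; `signed_positive = TRUE`
  restricts to positive residuals.
* The one-class SVM runs per voxel on the across-subject scalar score
  sample, with an RBF kernel, `nu = 0.1`, and bandwidth from the median
  heuristic on pairwise distances. Flagged subjects must also score above
  the sample median, so only *abnormally large* errors count as lesions;
  a voxel where all subjects score identically flags no one.
* Test and example problems use desk-scale settings chosen once: a
  32 x 32 x 10 grid, 32 subjects per group, channels (8, 16, 32), latent
  dimension 16, five epochs at learning rate 5e-3, batch 16. Under these
  conditions the voxel-level score-versus-truth ROC area exceeds 0.90,
  which the acceptance suite asserts.

## Statistical conventions

* Permutation p-values use the add-one convention
  `p = (1 + #{F_perm >= F_obs}) / (nperm + 1)`, which is valid (never
  exactly zero) for any `nperm`. When the number of distinct labelings
  `choose(nA + nB, nA)` is at most `nperm`, the test switches automatically
  to exhaustive enumeration and returns the exact `p = #{F_all >= F_obs} /
  n_labelings`; on the 2-versus-2 worked example this gives exactly 1/6.
  One permutation is applied to all voxels jointly, preserving spatial
  correlation. The PTE group is always the numerator; zero denominator
  variances produce an `Inf` sentinel that ties with permuted infinities.
* ALFF is band *power* (not its square root), normalized so that the
  periodogram sums to the series variance (Parseval convention); an
  amplitude-A in-band sinusoid thus scores approximately A^2/2. Only
  relative comparisons matter downstream, so the convention is free but
  fixed and documented.
* Fisher z features clip |r| at 1 - 1e-7 to stay finite; the 105-vector is
  ordered row-major over the strict upper triangle, (1,2), (1,3), ...,
  (14,15), and this order is fixed everywhere.
* BH-FDR is the textbook step-up; the implementation delegates to
  `p.adjust(method = "BH")` and is tested against the hand-computed
  thresholds. Voxel-wise correction runs across in-brain voxels only.
* The rank-sum test is `wilcox.test`: exact enumeration for small
  tie-free samples, normal approximation with tie correction otherwise.

## Cross-validation design

"1000 iterations" of leave-one-pair-out CV is interpreted as 1000 complete
CV passes, each with a freshly randomized PTE-to-non-PTE pairing; the
repeat count is configurable and the package's test profile uses 3-25.
AUC is computed from the out-of-fold decision scores pooled over all pairs
of one pass (per-pair AUC would be degenerate at 0/0.5/1), and the
reported sd is across repeats. Standardization and PCA are fit inside each
outer training set — the leakage-free placement — and hyperparameters (PCA
components; SVM cost; RBF bandwidth as a multiple of the 1/p heuristic)
are selected by inner stratified 5-fold AUC on the outer training set
only. Within the inner loop the PCA basis of the outer training set is
reused rather than refit per inner fold; the quantity protected from
leakage is the held-out pair, which never touches any fitting step, and
the no-leakage property is asserted by recomputation in the tests. Feature
importance back-projects the linear-SVM hyperplane normal through the PCA
rotation, keeps the positive part, and sums into ROIs with connectivity
features split half-and-half between their two endpoints.

The learning curve subsamples balanced cohorts at each size and the
extrapolation is an ordinary least-squares quadratic in n through the last
k points (k = 6 by default, matching the optimistic variant; larger k is
more conservative), clipped to [0, 1] with a warning.

## Known limitations

* The generator's simplicity means absolute performance numbers (AUCs,
  p-values) characterize the synthetic conditions, not clinical data; the
  headline clinical numbers of this problem domain are data-bound and not
  reproducible without the restricted cohorts.
* The volumetric ALFF stand-in skips any surface mapping step real
  pipelines may use; all analysis is on the shared voxel grid, and
  real-data users must register their inputs to a common grid first
  (volumes are written with an identity affine).
* Variance-coded effects (the ALFF channel) are intrinsically hard for
  margin classifiers; the RBF kernel picks them up only partially. This is
  a property of the method, visible in the block-wise AUCs.
* The per-voxel one-class SVM treats voxels independently; no spatial
  regularization beyond the median filter is applied.
* VAE anomaly scoring lives on a capacity trade-off: an under-trained
  model leaves structured background residual everywhere, while an
  over-trained or over-parameterized one starts reconstructing the
  lesions themselves, which *lowers* detection performance. The shipped
  training settings sit deliberately on the small side of that ridge, and
  the mean-score contrast between lesion and background is strongest for
  high-contrast lesions (the strong preset), even when the rank-based ROC
  area is already high under default contrast.
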
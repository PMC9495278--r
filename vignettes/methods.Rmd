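---
title: "Multi-view attention-guided classification of spinal lesions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view attention-guided classification of spinal lesions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two malignancies commonly involve the spine — multiple myeloma and
metastases (here, those originating from lung cancer) — and they are hard
to tell apart on conventional MRI: both present as single or multiple
lesions with overlapping imaging patterns, while their treatment pathways
differ fundamentally. `mvlesion` implements a complete, testable pipeline
for this differential-diagnosis problem: cross-view annotation transfer in
the DICOM patient coordinate system, a multi-view convolutional classifier
whose spatial attention is supervised by the lesion annotation, a
handcrafted radiomics baseline, and a stratified cross-validation harness.
Because clinical cohorts of this kind are private, the package ships a
synthetic tri-view phantom generator that reproduces the statistical
structure the method assumes, so every stage runs and is verified end to
end without patient data.

## Geometry: one annotation, three views

Radiologists delineate lesions on the sagittal series only. Each series
records, DICOM-style, where its voxel grid sits in the patient coordinate
system: the position of the first voxel (`ImagePositionPatient`), the unit
direction cosines of its rows and columns (`ImageOrientationPatient`), the
in-plane `PixelSpacing` and the `SpacingBetweenSlices`. A voxel index
$(i, j, k)$ maps to patient-space millimetres through the affine

$$x = o + i\,s_r\,\mathbf{r} + j\,s_c\,\mathbf{c} + k\,s_s\,\mathbf{s},$$

and the inverse map takes any patient point back into a grid. The sagittal
annotation is transferred to the axial and coronal grids *pull-wise*:
every destination voxel center is mapped into the source grid, the binary
mask is sampled there by trilinear interpolation (this is the linear
interpolation that keeps the transferred annotation continuous across the
2 mm slice gaps), and the interpolated value is binarized.

Numerical choices, made here and recorded as package decisions because no
convention is universal:

* voxel-center convention with 0-based continuous indices; the origin is
  the center of voxel $(0,0,0)$, matching DICOM semantics;
* binarization of the interpolated $[0,1]$ field at 0.5 — a deterministic
  rule that keeps the transferred volume approximately conserved (tested:
  within 10% under grid refinement);
* pull-based sampling (iterate destination voxels) rather than push-based
  scattering, which would leave holes under anisotropic spacings.

Transferred boundaries are rough — an inherent property of resampling a
binary field between anisotropic grids — but the transfer conserves the
lesion's patient-space centroid to within one voxel spacing, which is what
attention supervision needs.

## The multi-view attention-guided classifier

Each of the three views contributes one lesion-centered 2-D slice (the
slice with maximal lesion area; ties break to the smallest index). A
per-view convolutional backbone produces a $C$-channel feature map, which
is pooled spatially by log-sum-exp (LSE) pooling

$$f_c = \frac{1}{r}\log\Big(\frac{1}{hw}\sum_{p} e^{\,r A_c(p)}\Big),$$

a smooth interpolation between mean pooling ($r \to 0$) and max pooling
($r \to \infty$); the implementation subtracts the per-channel maximum
before exponentiation for stability. The three pooled vectors are
concatenated in fixed order (sagittal, axial, coronal) and a single fully
connected layer with a sigmoid emits the positive-class probability. The
sharpness parameter is not prescribed anywhere; the package default is
$r = 10$, intermediate between the two limits and standard in weakly
supervised localization work, exposed in the configuration.

The training objective combines two losses. Classification is penalized by
binary cross-entropy over the batch,

$$L_C = -\frac{1}{N}\sum_i y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i).$$

Attention is supervised per view: the class-activation map (CAM) — the
head-weight-weighted sum of feature channels, rectified, bilinearly
upsampled to crop resolution and min–max normalized — is compared to the
binary lesion mask by mean squared error $L_S$, and the three per-view
terms are summed into $L_{S\_all}$. The total objective is

$$L = L_C + \lambda\, L_{S\_all}, \qquad \lambda = 0.5$$

by default, with $\lambda$ exposed so that $\lambda = 0$ recovers plain
classification training exactly (the attention machinery is bit-inert in
that case, which the test suite asserts). Two presentation details of the
segmentation loss are implementation decisions: it is computed as a
positive quantity (a mean squared error is non-negative by definition),
and it is normalized per pixel as well as per batch, which only rescales
the effective $\lambda$.

Optimization follows the protocol this model family is trained with:
Adam, initial learning rate
$10^{-3}$ reduced by 10% every 5 epochs (multiplicative $\times 0.9$ per
5-epoch block — the standard step-decay reading), batch size 16, He-uniform
initialization. The epoch budget is not prescribed; the package default is
50 and the desk-scale experiments in the tests use 10–30.

### Attention maps: CAM at training time, Grad-CAM for visualization

The training-time attention uses the CAM form (head-weight channel
weighting) because it is an ordinary first-order function of the feature
maps: the mask supervision backpropagates through it without second-order
gradients. Grad-CAM — channel weights as spatially averaged gradients of
the logit — is provided as a separate mode for visualization. For this
architecture the two coincide: the head is linear in the LSE-pooled
features, so the averaged logit gradient per channel is proportional to
that channel's head weight, and min–max normalization absorbs the constant.
The test suite asserts this equivalence rather than assuming it. Masks are
compared at crop resolution (attention upsampled) rather than at feature
resolution, because the annotation exists at image resolution and
downsampling it would discard exactly the boundary detail the supervision
is meant to inject.

### No autodiff dependency

No automatic-differentiation tensor library is used: the backbone is a
compact stack of 3×3 convolutions (compiled kernels; four blocks with
channels 4/8/16/32 by default, downsampling by stride 2 in all but the
last block so the feature map keeps a usable spatial resolution for
attention), and the
full backward pass — through the LSE pooling softmax, the CAM weighting,
rectification, bilinear upsampling and min–max normalization — is written
out analytically. The analytic gradients are verified against central
finite differences to better than $10^{-3}$ relative error in the test
suite, for both the plain and the attention-supervised objective. The
`resnet50` backbone name is reserved but deliberately not constructible:
pretrained weights cannot be bundled, and every property the package
verifies is architecture-independent; the compact backbone is the
supported configuration.

## The radiomics baseline

The comparison arm extracts a fixed, documented 78-feature vector per view
from the raw lesion-centered crop: 4 shape features, 14 first-order
statistics, 4 gray-level co-occurrence (GLCM) features on 32 gray levels
averaged over the four standard unit offsets, and the first-order set
recomputed on the four sub-bands of a one-level orthonormal Haar
transform (56 features). The feature count is extractor-specific by
nature; what matters — and what the tests pin down — is that the set is
fixed, ordered, NA-free, and that every formula matches an independent
brute-force implementation to $10^{-8}$. GLCM bin count (32) and the Haar
wavelet are package choices, recorded here because the standard leaves
them open.

Selection and classification follow the two-stage design: a seeded random
forest ranks features by mean decrease in Gini impurity, the top 30 are
retained, and the *first half* (top 15) feeds a gradient-boosting
classifier. Whether selection is refit per cross-validation fold or once
globally is ambiguous in most descriptions of this design; the package
refits per training fold, which is the only leakage-free reading, and the
per-fold ranked lists are returned so users can inspect their stability.
The multi-view variant pools the view-tagged feature columns before
selection, inside the *same* fold assignment as the network experiments.

## Evaluation

Cross-validation is stratified at patient level (all lesions of a patient
are merged into one annotation, so the patient is the sampling unit):
within each class, shuffled patients are dealt round-robin over a rotated
fold order, guaranteeing per-fold class counts within one patient of exact
proportionality — e.g. a 79/138 cohort gives per-fold positive counts in
{15, 16}. AUC is computed by mean ranks, which equals the
pairwise-concordance definition with ties counted one half exactly (tested
against the $O(n^2)$ oracle); ACC and F1 use a fixed 0.5 threshold, a
recorded decision since none is prescribed. Per-fold ROC curves are
averaged vertically on a common false-positive-rate grid. A hard assertion
in the harness aborts on any train/test patient overlap.

## The phantom generator

The generator emulates the statistical structure the method assumes, not
MRI physics:

* **Cohort**: `round(n_patients * prevalence)` positive patients, default
  prevalence 0.30 (mirroring a 79/217 class balance); 1–3 ellipsoidal
  lesions per patient with base radius 3–6 mm, *identically distributed
  across classes* — lesion size and location carry no class signal, since
  size is explicitly non-discriminative in this clinical problem.
  Secondary lesions fall within 8 mm of the first, as lesions in
  neighbouring vertebrae do, which keeps the merged annotation coverable
  by one lesion-centered crop.
* **Scene**: a resolution-free analytic patient-space scene — a smooth
  vertebral-column profile with 14 mm periodicity along the cranio-caudal
  axis (so lesions are a small part of a structured background), plus
  smooth-edged lesions that add contrast enhancement (+80 intensity
  units in both classes).
* **Class signal**: inside positive patients' lesions only, a
  non-negative texture field of amplitude `texture_effect` is added,
  composed of a steady enhancement component (60%) and a band-limited
  ripple (40%; six random cosine components, wavelengths 3–8 mm). The
  split makes the per-lesion texture dose stable across patients — a pure
  random-phase ripple would make the delivered signal itself a lottery —
  while keeping visible spatial heterogeneity. The two classes thus
  differ in lesion *texture* (both character and mean enhancement), and
  `texture_effect = 0` renders them exactly exchangeable, the null that
  the calibration tests rely on.
* **Views**: three grids render the same scene with distinct axis
  permutations, spacings (1 mm in-plane/2 mm slices; coronal at 0.8 mm
  with one flipped direction cosine) and jittered origins, so annotation
  transfer can never pass by identity. Per-view Gaussian noise
  (`noise_sd`, default 10) is independent across views; because each view
  also samples a different plane through the lesion, the three views
  carry partially independent evidence, which is what makes multi-view
  fusion beneficial on this phantom.

What the phantom does *not* model — bias fields, scanner-specific
artifacts, multi-sequence contrast, anatomy beyond the periodic column —
bounds what passing tests can show: they verify the pipeline's mechanics
and its statistical behaviour under the assumed structure, not clinical
performance. A clinical tumor-size distribution is likewise not claimed;
clinical tumor-diameter statistics live on a different measurement scale
from this scaled-down field of view.

## Preprocessing and the intensity-normalization choice

Per view, the maximal-lesion-area slice is selected, z-score normalized,
and cropped to a square window centered on the merged lesion's bounding
box (zero-padded at image borders; 256 px is the API default, with 32 px
used at phantom scale). Normalization is deliberately computed on the
*full slice* rather than on the crop: in a lesion-centered crop the lesion
occupies a large fraction of the pixels, so per-crop standardization
cancels much of the lesion's own intensity contrast — measured on the
phantom, the class separation of the in-lesion mean drops from 0.86 AUC
(raw) to 0.56 (per-crop z-scoring), while slice-level normalization
preserves it. Slice-level standardization removes the scanner gain and
offset it is meant to remove precisely because the lesion is a small part
of the whole image. Raw crops are retained alongside for the radiomics
arm, whose first-order features are intensity statistics by design.

Slice selection itself is the central choice this pipeline had to make
that the underlying design leaves unstated (a 2-D backbone needs one
image per view): one slice per view, maximal lesion area, deterministic
tie-break. Alternatives (several slices, a 2.5-D stack, per-lesion crops
for multi-lesion patients) are compatible with the module boundaries and
would slot into `preprocess_cohort()`.

## Problem sizes and determinism

All experiments in the test suite and the acceptance script run on one
CPU at phantom scale: 64 mm field of view, 32 px crops, the compact
backbone, cohorts of 40–100 patients, and 10–30 training epochs. These
sizes were chosen once as the smallest at which the statistical claims
under test (attention improves lesion-attention overlap; fusion is at
least as good as the best single view; null cohorts calibrate to chance)
are stable, and they are stated here so users know what the shipped
evidence covers. Every stochastic stage — cohort generation, fold
assignment, initialization, batch shuffling, forest and booster fits —
draws from an explicit seed, and all seeded runs are bit-reproducible on a
given platform; RNG state is always restored, so library calls never
perturb a caller's stream.

## Known limitations

* The phantom's class signal is intensity-and-texture only; a method that
  exploited lesion shape would not be exercised.
* The two arms are not on equal footing on the phantom: radiomics features
  are computed inside the annotated mask (oracle localization at test
  time), while the network must localize implicitly from the image. On
  synthetic cohorts the radiomics arm therefore typically scores higher;
  relative orderings between arms on the phantom say nothing about their
  clinical ordering.
* The compact backbone trained from scratch on desk-scale cohorts reaches
  nowhere near the representational power of a pretrained deep backbone;
  absolute AUC values on the phantom are therefore not comparable to
  clinical figures and are not meant to be.
* Attention supervision uses the transferred (rough-boundary) masks as-is;
  no boundary refinement is attempted.
* The CLI's `train`/`crossval` commands exchange preprocessed samples as
  RDS files for convenience; the on-disk cohort interchange format (NIfTI
  + JSON sidecars + CSV manifest) is the stable contract.
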
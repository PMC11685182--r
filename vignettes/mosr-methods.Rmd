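---
title: "Multi-orientation super-resolution of ultra-low-field brain MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-orientation super-resolution of ultra-low-field brain MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ultra-low-field (≈64 mT) scanners acquire T2-weighted infant brain volumes
at 1.5 × 1.5 × 5 mm, one anisotropic stack per orthogonal orientation. Each
stack is sharp in its imaging plane and heavily blurred through-plane, and
all three suffer low SNR and a field-strength-dependent contrast shift
relative to 3 T scans. `mosr` reconstructs a single 1 mm isotropic volume
from the three stacks with a convolutional encoder–decoder whose three
input channels are the co-registered, isotropically resampled acquisitions.

This vignette explains the model, the training objective, the synthetic
phantom that stands in for clinical data, the evaluation battery, and the
numerical and design choices a maintainer should know about.

## The multi-orientation U-Net

The network is a 3D U-Net. Each encoding level applies two
(conv 3×3×3 → group-norm → ReLU) sub-blocks followed by 2×2×2 max-pooling;
feature widths start at `base_features` (64 at full scale) and double per
level over three levels. The decoder mirrors this: trilinear 2× upsampling
followed by a 3×3×3 convolution halving the width, concatenation with the
matching encoder skip, then two conv sub-blocks. A 1×1×1 convolution with
identity (linear) activation produces the output channel, so raw
predictions are unbounded; they are clipped to [0, 1] only on export.

Choices the architecture description leaves open, fixed here:

* **Two conv sub-blocks per level** (exposed as `n_convs_per_block`),
  following the standard 3D U-Net lineage.
* **Upsampling** by trilinear interpolation plus a convolution rather than
  transposed convolution, avoiding checkerboard artifacts.
* **Group normalization with 8 groups** (divisibility of the width is
  enforced); at desk scale (width 8) this degenerates gracefully to
  per-channel normalization.
* **Channel order is fixed as (axial, coronal, sagittal)**; the
  reduced-input clone rule depends on it.
* **Initialization** is Kaiming fan-in for convolutions and unit-scale /
  zero-shift for the norms, with one exception: the output head uses a
  near-zero initialization (gain 0.1). With a full-scale random head the
  initial output magnitude varies strongly across weight seeds, and a
  short optimization budget can be consumed merely undoing an unlucky
  initial scale; a near-zero head makes the starting prediction (and hence
  the initial voxel-wise loss) essentially seed-independent. This is
  standard conditioning practice for image-regression heads.

There is no weight sharing across input channels: each orientation
contributes its own filters in the first convolution, which is why channel
order matters and why cloning a scan into an empty slot is meaningful.

The forward and backward passes are written layer by layer in R, with the
convolutions lowered to im2col + BLAS matrix products in C++
(RcppArmadillo). The backward pass is verified against central finite
differences in the test suite (relative error ≤ 1e-4 for network
parameters, ≤ 1e-3 through the full composite loss).

## The training objective

Training minimizes

```
L_total = LPIPS(Ŷ, Y) + λ · L2(Ŷ, Y),       λ = 100
```

* **L2 term** — the *mean* squared voxel-wise difference. The reduction is
  deliberately a mean rather than a sum so that λ = 100 transfers across
  cube sizes (a summed norm couples the weighting to the voxel count).
* **Perceptual term** — the extractor is a frozen 2D convolutional
  backbone; because it consumes 2D natural-image-like inputs, S = 6 paired
  slices are drawn per evaluation — 2 per anatomical axis under the
  default `balanced` policy ("uniform" draws the axis per slice) — from
  the central 80% of each axis (background-only slices carry no
  perceptual signal), without replacement within an axis, identically for
  prediction and target. For each extractor stage, features are
  unit-normalized across channels at every spatial position, scaled by
  per-channel weights, squared-differenced, summed over channels, averaged
  spatially, and summed over stages. The slice scores are averaged (a
  single 1/S) to give the LPIPS term.
* **Extractor** — the published pretrained classifier with fitted channel
  weights cannot be redistributed here, so the package ships a seeded
  random-weight extractor (strided 3×3 conv + ReLU stages, uniform channel
  weights). Every structural property of the distance — zero at identity,
  symmetry, positivity, monotone sensitivity to perturbation — holds for
  the random extractor, and all tests use it. A pretrained backbone can be
  plugged in through the `loss.extractor` config key.

Gradients of the full objective (including back-propagation through the
channel normalization and the frozen extractor) are analytic and tested
against finite differences.

## Training protocol

Adam with learning rate 1e-4, batch size 1, on-the-fly paired
augmentation: with probability 0.5 a random affine transform (rotation,
translation, isotropic scale) and, independently with probability 0.5, a
random elastic deformation (coarse displacement grid, trilinearly
upsampled) are sampled *once* per step and applied identically to all
three inputs and the target (nearest-neighbour for label maps). The
ambiguous reading "one of the two with p = 0.5" is available via
`aug_mode = "either"`. Augmentation happens after resampling and padding,
i.e. on the canonical cube, so transforms never introduce relative motion
within a pair. Validation loss is monitored every `val_every` epochs; the
best-validation weights are retained, but training never stops early.

Two conditioning details matter for short runs. First, preprocessing
places every channel on one canonical cube grid through the affines
(world coordinates), never by count-centred padding of each channel
separately: an anisotropic scan resampled to 1 mm does not fill the cube
exactly along its slab axis, and per-channel centring would shift each
orientation by its own slab-axis remainder — a one-voxel relative
misregistration that silently degrades the learned fusion. Second, the
training loop warm-starts the head intercept: before the first step the
output bias is shifted so the initial prediction matches the cohort-mean
target intensity. A scalar bias otherwise has to travel to the target
mean at roughly the learning rate per step under Adam, and an unlucky
head draw can spend hundreds of steps on a constant-output plateau.

**Desk scale.** CPU runs use 32³ cubes, 8 base features and a
few-hundred-step budget. `desk_train_config()` raises the learning rate to
1e-3 — appropriate for a short budget on a small model — and keeps gentle
augmentation amplitudes. The packaged study conditions are a 12-subject
phantom cohort split 7 train / 5 test, trained for 20 epochs
(140 optimizer steps); the end-to-end smoke pipeline uses the same cohort
with fewer epochs. Epoch budgets are configuration, not convergence
criteria: full-scale convergence protocols (thousands of epochs on a GPU)
are outside what a test suite should attempt, which is also why the
full-scale 160³/64-feature configuration is validated through its
contracts (shapes, parameter counts) rather than end-to-end training.

## Data splitting

`make_folds()` partitions the cohort into k disjoint hold-out groups of
size val + test; fold *i* takes group *i* as validation + test and trains
on the rest, so validation and test sets never overlap across folds
(56 subjects at 42/7/7 × 4 folds exactly partition the cohort). Subjects
are dealt into groups sorted by (age-group × sex) stratum in randomized
order, which bounds each stratum's deviation in every split to one
subject.

## The synthetic phantom

The generator emulates exactly the structure the method consumes: an
isotropic ground-truth volume with a label map, plus three orthogonal
degraded acquisitions.

**Anatomy.** Nested ellipsoids: bright CSF shell and two ventricles,
cortical grey-matter ribbon, white-matter interior, and up to eight deep
grey structures (accumbens, amygdala, pallidum, hippocampus, caudate,
putamen, thalamus, ventral diencephalon) at template positions scaled to
the cube. A per-subject smooth random displacement field warps all
boundaries; mild smooth texture is added within the brain. Labels and
intensities are computed from the same deformed geometry, so the label map
is exactly consistent with the image, and analytic ellipsoid volumes
provide a ground-truth check on voxel-counted volumes (within 5% for radii
of at least 4 voxels). The structure templates are placed pairwise
disjoint and fully inside the white-matter shell so that check is
meaningful, and the default deformation amplitude (0.75 voxels at a
smoothing scale of an eighth of the cube) is chosen so the volume change
it induces stays inside the same voxelization-error budget while still
giving every subject a visibly distinct geometry.

**Contrast.** T2-weighted infant contrast: CSF brightest (0.92); white
matter brighter than grey by `0.25 · gm_wm_contrast`, with grey at 0.52.
The dial defaults to 0.8 at 3 months (unmyelinated white matter), 0.3 at
6 months and 0 in "isointense" mode, reflecting the developmental collapse
of grey/white separation around 6 months.

**Degradation.** (1) boxcar average over `slice_mm` along the slice axis
(the simplest physically plausible slice-excitation profile); (2)
downsampling to the (1.5, 1.5, 5) mm grid with world extent preserved;
(3) gamma contrast remap (default exponent 0.7) standing in for the
field-strength contrast shift; (4) multiplication by a smooth random bias
field (default amplitude 0.2); (5) Rician magnitude noise (default scale
0.05 of the intensity range) — the correct noise model for magnitude MRI
at low SNR. The gamma + bias surrogate captures that ULF contrast and
shading differ from high field without claiming to model the scanner
physics; noise, bias and contrast parameters were fixed once at values
that make the degraded inputs visibly noisy, shaded and contrast-shifted
(single-input NMSE ≈ 0.25 against the ground truth) and are not tuned.

**What passing tests show — and what they do not.** The phantom exercises
the geometry (anisotropy in three orientations, complementary information
across them, co-registration) and the degradations' statistics. It does
not contain real anatomy, motion, partial-volume effects at genuine
cortical geometry, scanner-specific contrast, or segmentation ambiguity;
desk-scale results demonstrate that the implementation learns and that
more distinct inputs help, not that clinical image quality is attained.

## Inference

Inputs are preprocessed exactly as in training (normalize → resample to
1 mm → pad to the cube). Missing orientations are filled by cloning the
highest-priority available scan in the order axial > sagittal > coronal,
preserving the fixed channel slots — one axial scan is presented as
(axial, axial, axial), axial + sagittal as (axial, axial, sagittal). The
prediction is cropped back to the reference input's world extent (the
cube padding is an implementation detail, not part of the result) and
clipped to [0, 1] on export. `naive_fuse()` provides the non-learned
reference: the voxel-wise average of the isotropically resampled inputs.

## Evaluation battery

* **Dice** per region, with the empty-mask conventions (1 if both masks
  empty, 0 if exactly one).
* **Segmentation of evaluated images**: the reference label map supplies
  the anatomy; each image is segmented by nearest-centroid intensity
  classification within the brain hull (global tissues) and, for each deep
  grey structure, by intensity proximity within a small dilation of the
  reference mask. Dice therefore measures how faithfully an image's
  intensities reproduce the reference geometry. An external
  contrast-agnostic segmenter can be substituted through the `segmenter`
  argument of `evaluate_cohort()`.
* **Volumes** in cm³ (voxel count × voxel volume), compared across
  subjects by Pearson r, Lin's CCC with population (1/n) moments (the
  original estimator; a sample-moment variant is exposed), the mean
  difference, and Bland–Altman limits.
* **Grey/white differentiation**: |median(GM) − median(WM)| under
  reference masks, and its percentage change against the fused raw-input
  baseline, (X − ULF)/ULF × 100.
* **NMSE** normalized by reference energy Σref² (variance normalization is
  the other convention; energy normalization is used and stated), **PSNR**
  = 10·log10(range²/MSE) with +∞ for identical images, and **SSIM**
  computed volumetrically with a Gaussian window (σ = 1.5 voxels, standard
  constants), giving one unambiguous scalar per subject.
* **Wilcoxon signed-rank** between methods on paired per-region Dice:
  zeros dropped, mid-ranks for ties, exact two-sided p by full 2ⁿ
  enumeration of sign assignments for n ≤ 12 (the enumeration runs on the
  observed tie-ranks, so ties are handled exactly), tie-corrected normal
  approximation with continuity correction otherwise; effect size is the
  rank-biserial correlation (R⁺ − R⁻)/(R⁺ + R⁻). The family-wise
  threshold is Bonferroni: α/m (0.05/8 = 0.00625 for four tissue classes
  × two model contrasts).
* **Raw-scan rows** ("ulf" method) average each metric over the three
  resampled orientations.

## Numerical choices and degenerate inputs

* Resampled extents use floor(world extent / new spacing): the output grid
  never samples outside the input's support (160 mm at 1.5 mm → 106
  voxels). Resampling to the identical spacing is an exact identity.
* Min–max normalization runs over nonzero (brain) voxels only; the
  skull-stripped zero background would otherwise pin the minimum.
  All-zero and constant-intensity volumes are rejected.
* Pad/crop is centered with the affine shifted so retained voxels keep
  world coordinates; it is idempotent at the target size.
* Slice sampling without replacement within an axis makes the loss equal
  the plain all-slice mean when S covers an axis band — the identity the
  oracle test uses.
* The channel-normalization epsilon (1e-10) guards all-zero feature
  vectors; PSNR of identical images is reported as the +∞ sentinel rather
  than an arbitrary cap; zero-variance volume series flag r and CCC as NA
  with a warning.
* All randomness (phantom geometry, acquisition noise, weight
  initialization, shuffling, augmentation, slice sampling) derives from
  explicit seeds fanned out from one master seed; repeated runs are
  bit-identical, and report tables are written with fixed formatting so
  whole pipelines reproduce byte-for-byte.

## Known limitations

* The phantom's ellipsoidal anatomy cannot probe cortical folding,
  partial-volume mixtures or real ULF contrast; conclusions at desk scale
  are about implementation correctness and the value of multi-orientation
  fusion, not clinical performance.
* The random-weight perceptual extractor preserves the distance's
  structure but not the perceptual alignment of a pretrained backbone;
  with it, the perceptual term acts as a structured multi-scale feature
  loss.
* Training at the full 160³/64-feature scale is supported by the code but
  far outside CPU test budgets; the packaged protocols are desk-scale.
* Intensity-based evaluation segmentation is deliberately simple; plugging
  in a learned contrast-agnostic segmenter changes Dice absolute levels
  (the plug-in point is exposed).
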
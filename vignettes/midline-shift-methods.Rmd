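---
title: "Measuring midline shift on head CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring midline shift on head CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlshift)
```

## The measurement

Midline shift (MLS) is the lateral displacement of midline brain structures,
a clinical surrogate of mass effect after intracranial hemorrhage. On an
axial CT slice the ideal midline is the line between the anterior and
posterior attachments of the falx cerebri; the displaced structure is the
septum pellucidum. `mlshift` measures MLS from four named landmarks per
slice — `falx_anterior`, `falx_posterior`, `septum_anterior`,
`septum_posterior` — as the distance in mm between

* the midpoint of the falx line, and
* the midpoint of the septum segment,

with each pixel axis scaled by its own spacing before the Euclidean norm, so
anisotropic reconstructions are handled correctly. The per-scan MLS is the
maximum over slices, with ties broken to the lowest slice index. MLS is
reported unsigned; laterality is not encoded.

Two readings of the landmark construction are defensible: the point-to-point
distance between the two midpoints, and the perpendicular distance from the
septum midpoint to the falx line. The package defaults to the
point-to-point form (`mls_mode = "midpoint_distance"`), which is the more
literal reading of the construction; `"perpendicular_to_falx"` is available
as a config switch. The two agree whenever the septum midpoint sits level
with the falx midpoint (the usual anatomy) and differ when the septum
midpoint slides along the midline direction.

All MLS values are computed in the scan's **native** pixel space and spacing;
the 512x512 model resize never touches reported millimetres.

## Preprocessing

Each slice is turned into a 3-channel model input:

1. the three spatially adjacent slices (i−1, i, i+1) are stacked as channels,
   replicating the edge slice at the volume boundaries (the least surprising
   total convention);
2. each channel is resized bilinearly to 512x512, with the effective spacing
   rescaled so the physical field of view is preserved exactly;
3. channel k receives Hounsfield window k — (level 80, width 200)
   subdural-type, (40, 380) soft tissue, (600, 2800) bone — mapped linearly
   onto [0, 1] and clipped.

We interpret "three windows applied to three adjacent-slice channels" as
window k on channel k: a per-channel-times-per-window cross product would
yield nine channels, contradicting the 3-channel input. Windowing is applied
after the resize, on HU values; anyone attempting bit-compatibility with a
system that windows first should note the order.

## The detector

Keypoints are found by a two-stage detector in the R-CNN family: a
convolutional backbone, a region-proposal stage (objectness plus box deltas
against one brain-sized anchor per feature cell), and a second stage that
crops ROI features and runs three heads — classification (detection score),
box refinement, and a keypoint head that predicts a one-hot spatial heatmap
per landmark inside the ROI, decoded by argmax to the cell centre. At most
one instance is kept per slice (a brain appears once); slices scoring below
`score_threshold` (default 0.5) are excluded from the per-scan maximum.

Two backbones share this contract:

* `tiny` (default): a strided CNN (8, 16, 32 channels, stride 8) that trains
  on phantoms in minutes on one CPU;
* `fpn50`: a bottleneck-residual backbone with stages (3, 4, 6, 3) and a
  single-level feature-pyramid merge, the width-reduced analogue of the
  50-layer residual FPN family.

The whole network is implemented in the package (im2col/col2im in C++, the
rest base-R matrix algebra) with hand-written backward passes; a
finite-difference gradient check is part of the test suite. There is no
external deep-learning runtime to install, and determinism under a seed is
exact given single-threaded BLAS.

### Training protocol

Defaults follow the reference schedule: Adam (beta1 0.9, beta2 0.999, weight
decay 0), initial learning rate 1e-4 divided by 10 after 100 epochs, batch
size 16, 200 epochs, and four augmentations — random sagittal flip (which
mirrors x and relabels nothing: anterior stays anterior), random affine
(rotation ±8°, scale 0.9–1.1, translation ±4%, applied identically to image
and keypoints, resampled up to 10 times if a keypoint would leave the image,
then skipped), random erasing (a blanked rectangle; keypoints are never
relocated), and simplified metal streaks. The ground-truth box for the
proposal stage is derived from the falx line: height = 1.2 x falx length,
width = 0.8 x height, axis-aligned and centred on the falx midpoint. With
the falx within ~16° of the anterior-posterior axis — always true
anatomically — the 1.2 factor guarantees both falx endpoints fall inside the
box.

Region-proposal supervision marks the 3x3 cell neighbourhood of the box
centre positive (each cell regressing the box against its own anchor) and
samples negatives only well clear of the centre; nearby cells look identical
to the positive and would receive contradictory labels. The ROI heads train
on jittered ground-truth boxes plus one random background box per image;
background slices (no septum) and fully empty slices supply additional
negatives so the score head learns to stay silent off the ventricle levels.

### Desk-scale settings

The reference schedule is designed for a large pretrained backbone on a GPU.
The package's desk-scale configuration — used in its own tests and in
`scripts/acceptance.R` — trains the `tiny` backbone from scratch for 30
epochs at learning rate 1e-3 (dropped 10x at epoch 20, preserving the
shape of the schedule at 30/20 instead of 200/100), network input 192x192,
ROI heatmap 32x32, on about 300 phantom slices (5 keypoint slices to 3
background/air negatives). At 0.5 mm
pixels a 32-cell heatmap over a brain-height box quantizes each landmark to
roughly 7 mm (half-cell error ~3.4 mm); the midline shift, being a
difference of midpoints, partially cancels the shared part of that error. A
finer 48-cell heatmap was evaluated and learned more slowly at this budget
without improving scan-level error. These sizes were chosen so a full
train-evaluate cycle runs in a few minutes on one CPU; they are stated here
so readers know the scale at which the package's own checks operate.

COCO-style pretraining is out of scope (it would require a download); the
backbone trains from random initialisation.

## The phantom generator

Real head CT with expert landmark annotations cannot ship with a package, so
`mlshift` tests itself end to end on synthetic phantoms with exact ground
truth. Each phantom is deliberately schematic: an elliptical skull ring at
+1000 HU over a −1000 HU air background, noisy parenchyma at 30 HU
(Gaussian sd 4 HU), a falx drawn as a thin 60 HU line entering from the
anterior and posterior inner table, two dark (5 HU) ventricles flanking a 45
HU septum segment, an optional hyperdense lesion blob (70 HU), and optional
alternating-sign linear metal streaks (a schematic stand-in — no
sinogram physics). The HU palette is chosen so each tissue lands in a
distinct region of the three windows.

The septum (with its ventricles) is displaced perpendicular to the falx by a
truncated raised-cosine per-slice profile whose peak equals the requested
`true_mls_mm` exactly at the central ventricle slice, so the per-scan
maximum is the requested value by construction. The shift direction is
randomized per scan. Annotations carry sub-pixel (float) coordinates; the
geometry module therefore reproduces the ground truth to machine precision,
and the 0.1 mm tolerance quoted in the tests covers any future integer
rounding of annotations rather than a property of the current generator.

Default geometry: 512x512 pixels at 0.5 mm, 24 axial slices at 5 mm (a
typical axial brain reconstruction). Cohort simulations in the tests use 12
slices (the ventricle-bearing middle of a scan) and, for the large
noise-response cohort, 256x256 at 0.9 mm — the preprocessing resize to 512
is then exercised rather than bypassed. `generate_phantom(render_voxels =
FALSE)` computes only geometry and annotations, for cohorts whose voxels are
never read.

What the phantoms do **not** emulate: real parenchymal texture, anatomical
variation of the falx and ventricles, partial-volume effects, gantry tilt,
non-midline pathology that confounds human readers. Passing phantom tests
shows the geometry, training harness and evaluation machinery are correct —
it does not certify clinical performance on real CT.

### Dataset assembly

`build_dataset()` draws per-scan true MLS from a configurable distribution
(default uniform on 0–15 mm, spanning clinically trivial to severe shift),
assigns each patient one of six hemorrhage classes (ICH, IVH, SAH, acute
SDH, chronic SDH, EDH), gives a patient a second scan with probability 0.1,
and splits **by patient** 8:1:1 into train/valid/test with largest-remainder
rounding within each class. A class with fewer than 3 patients cannot be
split and goes to train with a warning. Splitting by patient, never by scan,
prevents the leakage of a patient's anatomy across partitions.

## Evaluation protocol

`evaluate_cohort()` pairs predictions with ground truth by scan id and
reports:

* **MAE** — mean (and max) absolute error of per-scan MLS in mm;
* **ICC(2,1)** — two-way random-effects, absolute-agreement, single-rater
  intraclass correlation, with the F statistic (MSR/MSE) and the 95%
  McGraw–Wong confidence interval. The absolute-agreement form penalizes a
  constant between-method bias, which a consistency ICC would forgive; the
  form is fixed but documented, since agreement studies often leave it
  implicit. Agreement is computed strictly at scan level.
* **Sensitivity/specificity** at 2, 5 and 10 mm. Thresholds are strict:
  "greater than 2 mm" means a value of exactly 2 mm is negative. When the
  ground truth has no positives (or no negatives) the undefined rate is
  reported as `NA`, never 0.
* **Pearson r** against an optional per-scan covariate.

A prediction with no detected slice is scored as 0 mm and counted
(`n_undefined_pred`) rather than dropped: silently removing missed scans
would flatter every aggregate metric.

## Numerical and degenerate-input choices

* Window maps are total functions on finite HU; clipping is idempotent.
* A falx annotation with coincident endpoints is rejected (the midline is
  undefined). A *predicted* degenerate falx (both heatmap argmaxes in one
  cell) marks the slice undetected instead of erroring the pipeline.
* Empty per-slice sets aggregate to `defined = FALSE` with `NA` mm.
* ICC with zero error mean-square returns estimate 1 and an infinite F; an
  all-constant matrix is undefined (`NaN`) rather than silently 1.
* Box-delta decoding clamps log-scale deltas to ±2 so an untrained box head
  cannot produce unbounded boxes.
* DICOM reading supports uncompressed little-endian transfer syntaxes
  (explicit and implicit VR) and fails loudly on anything else, on missing
  PixelSpacing, on mixed slice shapes and on mixed orientations. Slices are
  ordered by image position along the slice normal.

## Known limitations

* Phantom realism, as above; no claim transfers to clinical data without
  retraining and validation on real annotated CT.
* The desk-scale detector quantizes keypoints to heatmap cells; at phantom
  scale its scan-level MAE is a few mm — far from what the full-size
  architecture achieves with pretraining on thousands of real slices.
* Laterality of the shift is not reported.
* Agreement statistics are scan-level only; per-slice agreement across
  methods with different slice counts is out of scope.
* The metal-streak model is geometric, not physical.
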
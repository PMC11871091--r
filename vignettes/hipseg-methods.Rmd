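---
title: "Methods: synthetic phantoms, threshold protocol and Dense U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic phantoms, threshold protocol and Dense U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative CT of the proximal hip resolves seven musculoskeletal tissues
that matter for osteoporosis and sarcopenia research: cortical bone,
trabecular bone, haematopoietic bone marrow (HBM), marrow adipose tissue
(MAT), muscle, intermuscular adipose tissue (IMAT) and subcutaneous adipose
tissue (SAT). Reference segmentations are traditionally produced by an
operator who delineates anatomical compartments and then thresholds
Hounsfield units (HU) within them; a convolutional network can learn the
whole mapping and reproduce it automatically in seconds per slice. This
package implements that pipeline end to end — reference protocol, network,
evaluation and per-tissue quantification — together with a synthetic phantom
generator that stands in for the restricted-access cohort data on which such
models are normally trained.

## The threshold protocol

Tissue intervals in raw HU, applied inside anatomical compartments:

| tissue      | compartment        | interval (HU) |
|-------------|--------------------|---------------|
| cortical    | bone shell         | >= 300        |
| trabecular  | bone shell, marrow | 150–300       |
| HBM         | marrow             | 50–150        |
| MAT         | marrow             | < 50          |
| muscle      | fascia             | −30–500       |
| IMAT        | fascia             | < −30         |
| SAT         | subcutaneous       | < −30         |

Three conventions close the gaps the prose protocol leaves open:

* **Half-open intervals `[low, high)`.** The written ranges touch
  (150–300 vs > 300); half-open intervals make the partition exact, so a
  pixel at exactly 300 HU in the shell is cortical and one at exactly 150 in
  the marrow is trabecular.
* **Residual rule in marrow.** Marrow pixels at or above the trabecular
  lower bound are classified trabecular — the protocol derives trabecular
  bone as the residual of cancellous bone.
* **Calcifications.** Fascia pixels at or above the muscle upper bound
  (500 HU) are background; dense foci inside muscle are out of scope.

IMAT and SAT share one HU distribution (both "fat, < −30") and are
distinguished *only* by compartment. This is why compartment delineation is
part of the protocol, and why a per-pixel intensity classifier cannot solve
the task: spatial context is required.

The original compartments were drawn interactively. `derive_compartments()`
is this package's automated reconstruction: body = largest connected
component above an air cutoff of −200 HU (the calibration rods form separate
smaller components and are excluded); bone = morphological closing plus
hole-fill of the HU >= 150 shell; marrow = bone interior below 150 HU;
fascia = hole-filled envelope of muscle-range attenuation outside bone;
subcutaneous = the remaining body. Morphology uses 8-connectivity and a disk
of radius 2 px at 128 px scale (scaled with image size). The reconstruction
is validated only on phantoms, where it recovers the generating compartments
pixel-exactly in the noise-free case; on real scans an operator would still
review it.

## The synthetic phantom: a stated world

No deposited CT data is usable without access approval, so every stage is
tested against a generator whose ground truth is known by construction. One
phantom slice contains nested ellipses: a body with a SAT ring, a fascial
envelope holding muscle with eight small IMAT islands, and one femoral
cross-section — cortical shell (outer 3% of image width), trabecular zone
(next 3%), and a marrow cavity split into an MAT blob and HBM. Three
calibration rods (nominal 150, 75, 0 mg/cm^3, HU linear in concentration)
sit outside the body. Acquisition defaults mirror the scan protocol: 3 mm
slices, 5-slice stacks, and a 34 cm field of view at any resolution
(340/`image_size` mm pixels, i.e. 2.66 mm at the 128 px desk default). At
these defaults the muscle cross-section is ~230 cm^2 and SAT ~150 cm^2,
in the range reported for older men at the proximal hip.

Default tissue means (cortical 600, trabecular 220, HBM 100, MAT 20, muscle
50, IMAT/SAT −80, air −1000 HU) are centred well inside the threshold
intervals, leaving >= 3 sigma margins at the default noise level
(`noise_sigma = 10` HU, additive Gaussian). Per-subject anatomy jitters
ellipse centres and axes by about ±10%, with rasterized containment checks
so the nesting invariants always hold; in a stack the bone cross-section is
largest at the central slice, giving the reference-slice selector a
constructed peak. A second "scanner domain" B adds a configurable HU offset
(default +40) and a pixel-spacing multiplier to emulate acquisition on
different hardware; the magnitude is a free emulation parameter — the
original study reports no intensity statistics for its two scanners — so
cross-domain results here are directional, not calibrated.

What the phantom deliberately does **not** emulate: partial-volume averaging
at boundaries (every pixel belongs to exactly one tissue), beam hardening
and scatter, anatomically realistic femur shape, or inter-scanner texture
differences. A green test on phantoms therefore establishes that the
implementation is correct and the pipeline learnable under stated
conditions — not that the paper-scale accuracy figures transfer to clinical
scans.

## The Dense U-Net

The network is an encoder–decoder with skip connections in which each block
is dense: layer *l* convolves (3×3, ReLU) the concatenation of the block
input and all previous layer outputs, adding `growth_rate` = 8 feature maps;
a 1×1 transition compresses the concatenation. Defaults: depth 4 (128 px
input gives an 8×8 bottleneck), 2 layers per block, stem width 16, level
widths 16/32/64/64 (capped at 4× the base). The head is a 1×1 convolution to
8 classes with per-pixel softmax; ties at prediction argmax break toward the
lower class code. Inputs are HU clipped to [−1024, 1500] and scaled to
[0, 1]; sizes not divisible by 2^depth are reflect-padded and cropped back.

No deep-learning framework is assumed: forward, backpropagation and Adam are
implemented natively (C++/RcppArmadillo, im2col + GEMM), which keeps the
package self-contained and CPU-reproducible. Weight initialization is
He-normal drawn from R's RNG, and batch shuffling uses R's RNG, so a single
`set.seed()`/`tc$seed` makes training bit-reproducible.

Two training presets:

* `train_config("paper")` — the original recipe: Adam, batch size 2,
  learning rate 1e-4, 200 epochs, unweighted categorical cross-entropy, no
  augmentation.
* `train_config("desk")` — same optimizer, batch size and loss, but 30
  epochs at learning rate 2e-3. Rationale: the original schedule takes
  roughly 18,000 optimizer steps; a desk schedule takes under a thousand,
  and Adam at 1e-4 cannot move He-initialised weights appreciably in that
  many steps. The rate is scaled up for the ~20×-shorter schedule; one
  calibration run on a 60-phantom cohort fixed the pair (30 epochs, 2e-3) at
  the point where training loss reaches ~1e-3, and the schedule is not tuned
  per dataset thereafter. On one CPU the desk preset trains in about 8
  minutes at 128 px.

Class imbalance is left to the unweighted loss (as in the original recipe);
background dominates each slice but is also the easiest class.

## Metrics and evaluation conventions

* **DSC** = 2|A∩B|/(|A|+|B|), reported in percent. If a class is empty in
  both masks the value is undefined: it is flagged and *excluded* from
  aggregation rather than scored 100, which would inflate means for absent
  tissues.
* **ASSD**: boundary pixels are class pixels with a non-class 4-neighbour
  (the image border counts as non-class); the metric is the mean of the two
  directed average nearest-boundary distances, scaled by pixel spacing.
  4-connectivity is a documented choice — the protocol text does not specify
  one.
* **Sensitivity/specificity** are one-vs-rest confusion ratios per class;
  zero denominators are flagged undefined.
* **Aggregation** is per image, then mean within fold, then mean ± sd across
  folds — matching the "average ± standard deviation of 10-fold cross
  validation" reporting convention. CV folds split by *subject*, never by
  slice, so no subject appears on both sides of a fold.
* **Timing** is logged per slice for parity with the manual-vs-automated
  comparison but never asserted in tests (hardware-dependent).

## Quantification conventions

Areas are pixel counts × pixel area (cm^2) on the reference slice; volumes
sum per-slice areas × 3 mm thickness over the 5-slice window centred on the
reference slice. The reference slice maximises a femoral-neck thickness
proxy — bone pixel count in the patient-left half-image (image right under
the radiological display convention; configurable) — with ties broken toward
the inferior-most slice. Average HU (AHU) for muscle is reported raw and
divided by height squared (HU/m^2; the source's unit is unstated, metres are
used here). Marrow fractions HBM/TBM and MAT/TBM are complements computed to
sum to 1 exactly. Both area and volume are exported even though they are
strongly correlated, leaving the choice to downstream analysis. The
calibration fit (HU → mg/cm^3) is exposed but *not* applied before
thresholding: the protocol's thresholds are stated in raw HU, and whether
the original study rescaled by the rods is unrecorded.

## Numerical and design notes

* NIfTI-1 I/O is implemented directly (348-byte header subset, float32
  images, int16 masks): no NIfTI package is available in the deployment
  environment and the format subset needed is small. Files without spacing
  metadata are rejected, never defaulted. 16-bit PNG output is not
  supported (the available PNG writer is 8-bit only).
* Stacks are stored superior → inferior; "inferior-most" = largest index.
* Degenerate inputs error early: even slice counts, non-decreasing rod
  concentrations, tissue means outside their intervals, empty bodies, masks
  without bone.
* The CV-harness oracle (a model factory that returns ground truth) checks
  the harness itself: it must score DSC 100 with sd 0 by construction.

## Known limitations

Phantom realism as listed above; a single bone per slice (no contralateral
hip, no pelvis); 2-D slice-wise segmentation rather than 3-D; the Dense
U-Net here is desk-scale by default (a 512 px / 200-epoch configuration
exists but is not exercised in CI); the robustness experiment's domain
shift magnitude is an assumption; and no statistical association analyses
are included — quantification tables are exported as CSV for external tools.
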
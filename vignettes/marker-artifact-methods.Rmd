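---
title: "Simulating and quantifying passive marker artifacts in interventional MRI"
author: "MarkerVis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying passive marker artifacts in interventional MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MarkerVis)
```

## Scope and scientific setting

MRI-guided endovascular interventions track guidewires through *passive
paramagnetic markers*: small iron-oxide nanoparticle (IONP) inclusions that
locally distort the main field and punch a signal void — a susceptibility
artifact — into each magnitude frame.  Artifact size must be tuned: large
enough to be seen and detected automatically, small enough not to obscure
anatomy.  The size depends on the sequence (GRE vs bSSFP), the echo time,
and the marker's IONP load.

`MarkerVis` packages the full desk-scale analysis of this problem:

1. a **synthetic phantom generator** that renders paired reference (no
   wire) and marker image series of a pulsatile flow phantom at 3-T-like
   contrast, so every downstream stage is testable without scanner data;
2. the **artifact quantification pipeline** (frame discard, blood-intensity
   frame pairing, subtraction, agar-statistics thresholding, mask width,
   CNRs);
3. a **heatmap marker detector** (Gaussian likelihood-map labels, a small
   U-Net regressor, 8-connected maxima extraction, threshold-sweep TP/FP
   evaluation);
4. **statistics and reporting** (exact two-tailed Wilcoxon signed-rank,
   median/IQR tables, boxplot-ready width data).

Real scanner frames for this experiment are not publicly deposited, so the
generator *defines the study conditions* here; everything it emulates and
everything it deliberately omits is listed below.

## The forward model

### Scene

Frames are 144×144 sagittal-like magnitude images at 1.74×1.7 mm pixels.
The scene has three compartments: an air margin on the left (noise ROI
territory), homogeneous agar, and an 8-mm "blood" tube running along the
image rows — the main-field (B0) direction — carrying pulsatile signal at
60 beats/min (0.4 L/min is carried as metadata).  The five markers
(1.5 mm, 0.036 µL each) sit on the tube axis with 20/15/10/5 mm
centre-to-centre gaps, the first at the wire tip.

Absolute signal levels are free parameters (the source experiment reports
none): blood 100, agar 60, per-channel noise SD 1 (arbitrary units), chosen
to give blood-artifact CNRs of the same order as a clinical 3-T
interventional protocol.  The bSSFP blood pool is boosted by a factor 2.5,
reflecting the sequence's blood-signal advantage.

### Marker artifact

Each marker is modelled as a point magnetic dipole aligned with B0:

$$\Delta f(r,\theta) = K\, m\, \frac{3\cos^2\theta - 1}{r^3}\ \mathrm{Hz},$$

with $r$ in mm, $\theta$ the angle from B0, and the moment $m$ proportional
to IONP concentration × marker volume.  The offset vanishes at the magic
angle $\theta=\arccos(1/\sqrt3)$.  The field is sampled on an 8×8 in-plane
sub-grid per pixel and 3 sub-slices across the slice thickness; the pixel
value is the magnitude of the complex mean

$$S = \Big|\tfrac1N\sum_k e^{\,i\,2\pi\,\Delta f_k\,\mathrm{TE}}\Big|,$$

i.e. intravoxel dephasing, which makes the void footprint grow with TE and
with $m$ — the scaling the analysis is designed to measure.  Sub-voxels
within 0.9 mm of a marker centre are a hard signal void (the dipole
expression is singular at $r=0$).  bSSFP contrast additionally weights each
sub-voxel by the banding profile $|\cos(\pi\,\Delta f\,\mathrm{TR})|$
(pass-band on resonance, nulls at odd multiples of π phase per TR) on top
of a linear background off-resonance of 100 Hz across the row extent, so
long-TR bSSFP presets develop the characteristic dark bands while short-TR
ones only show mild shading.

$K$ is the one calibrated constant of the model: it was fixed once
($K = 25000$ Hz·mm³ per concentration-volume unit) so that the baseline
GRE preset with 6.25 mg/mL markers yields a mean artifact width in the
5–8 mm band, and has not been revisited since.  With this calibration the
simulated widths span roughly 6–13 mm over the GRE preset ×
concentration grid (up to ~18 mm for the long-TR bSSFP presets) — a
compressed version of the 6.3–23.2 mm range the physical experiment
spans, which is acceptable because the package's claims about width are
monotonicity claims, not absolute ones.

### Acquisition presets and secondary effects

`acquisitionPreset("a")` … `("h")` reproduce the evaluated sequence grid
(GRE a–d: TE/TR 2.48/4.6 → 6.49/12.1 ms; bSSFP e–h: 1.47/2.9 →
4.85/9.6 ms; flip 12°/39°; 3.3/5 frames/s; bandwidth kept as metadata).
Parallel-imaging, partial Fourier, prescan normalisation and coil geometry
are out of the simulation's scope.  Two deliberately weak effects are
included so the corresponding analysis switches have something to act on:

* **Phase-encoding direction** — a σ=0.5 px Gaussian blur along the phase
  axis; switching PED therefore perturbs widths only slightly, mirroring
  the "limited effect" the physical experiment found.
* **Saturation ramp** — the first 5 frames are brightened by
  $1+0.3\,e^{-(i-1)/2}$, giving the frame-discard rule a real effect to
  remove.

Noise is Rician (additive Gaussian on both complex channels, then
magnitude), the standard MR magnitude statistic; the agar-ROI SD that the
threshold rule needs is therefore realistic.  One integer seed drives all
randomness; series are bit-reproducible.

### What the generator does not emulate

No k-space sampling, no wire motion between frames (the physical pulsatile
flow wiggles the wire; here marker positions are static within a series),
no through-plane wire obliquity, no flow-related artifacts beyond the
intensity modulation, no 3-D artifact structure.  Passing tests therefore
show that the *analysis* is correct under controlled conditions, not that
the simulator predicts scanner frames.

## Quantification pipeline

`quantifyDataset()` chains the stages exactly as the analysis protocol
prescribes:

1. **Discard** the first 5 frames of each 30-frame series (25 analysed).
2. **Pair** each marker frame with the reference frame of closest
   blood-ROI mean (pulsatile intensities make naive index pairing wrong).
   References may be reused; ties go to the lower index.
3. **Subtract** reference − marker, so the void appears positive.
4. **Threshold** at agar mean + 3·SD of the subtraction image (sample SD,
   n−1), **segment** with a strict `>`.
5. **Width**: per row along the wire, mask-pixel count × 1.7 mm, averaged
   over occupied rows (`countEmpty` switches to all-row averaging).
6. **CNR** = (mean(ROI A) − mean(artifact pixels)) / SD(noise ROI),
   computed on the *original* marker frame; signed by default,
   `absolute = TRUE` available (the reported negative IQR bound in the
   source tables suggests signed per-frame values).
7. **Exclusion** of contaminated frames: explicit index list, or
   automatically when a frame's agar mean deviates > 4 SD from the
   dataset median.

ROI conventions: the 2×17 / 6×54 / 31×141-voxel blood/agar/noise ROIs are
placed as 17×2 / 54×6 / 141×31 (rows × cols) rectangles because the
simulated tube runs along rows; voxel counts are unchanged.  All pixel
indices in the package are 1-based (the R convention); physical mm
coordinates have the centre of pixel (1,1) at 0 mm.

## Marker detection

Labels place an unnormalised Gaussian (peak 1, σ=(1,1) px) at every
annotated centre, take the element-wise mean across markers, and min-max
normalise to [0,1].  The amplitude convention (peak-1 vs pdf) is
immaterial after normalisation for well-separated markers, which is why
the unnormalised form was chosen.

The regressor is a depth-3 U-Net (double 3×3 conv blocks with leaky-ReLU
activations, 2×2 max pooling, nearest-neighbour upsampling, skip
concatenation, linear 1×1 output), trained with MSE and Adam at learning
rate 1e-4 — 400 epochs with rotation (±15°), translation (±10 px), scale
(0.9–1.1) and crop-and-resize (≥0.85) augmentation in the full preset.
No R deep-learning framework is assumed: the network, backpropagation and
Adam are implemented in compiled code inside the package, with gradient
correctness checked against numerical differentiation in the test suite.
Inputs are standardised per frame (zero mean, unit SD); predictions are
clipped to [0,1].  Two numerical choices matter for reliability on this
loss: heatmap targets are almost entirely zero, so a plain-ReLU network
fed all-positive images can stall for many epochs in the
predict-zero-everywhere basin before the peak gradient escapes.  Leaky
activations (slope 0.1) and zero-mean inputs remove that stall across
initialisation seeds; both are standard practice for heatmap regression
and neither changes the stated loss, optimiser or learning rate.

Training follows the classic U-Net *tile* regime: each epoch is one pass
over the shuffled training images, with every image contributing
`patchesPerImage` random `patchSize`-px tiles (default 4 tiles of 72 px).
Tiling matters for reliability, not just speed: per pass over the data it
takes four times as many optimiser steps than whole-frame batches at the
same arithmetic cost, and at a fixed epoch budget that extra movement is
what lets the network resolve the closely spaced marker pair (the 5-mm
gap is 3 px) consistently across initialisation seeds.  Whole-frame
training (`patchSize = 0`) is available and was observed to leave the two
closest markers merged into a single likelihood blob for some seeds at
the desk epoch budget.

**Desk preset** (`deskDetectionConfig()`): depth 2, 8 base channels,
60 epochs of 72-px tiles, no augmentation.  Rationale: a depth-2 network
keeps a full-resolution skip path and a single pooling level — enough
context to reject background while preserving the 3-px peak separation —
and at desk scale the evaluation frames share the training acquisition
geometry, so augmentation (whose purpose in the full protocol is
robustness across acquisition changes) is unnecessary.  Single-core
training takes two to three minutes for 30 training images of 144×144.
This preset is what the acceptance script and the end-to-end tests run;
the full preset (`detectionConfig()`: depth 3, 16 channels, 400 epochs,
augmentation on) mirrors the complete protocol.

Extraction and scoring:

* **Local maxima** at pixel connectivity 8.  Plateaus (connected
  equal-valued regions whose outside neighbours are all strictly smaller)
  contribute one candidate at their centroid; a constant map has no
  maxima.  The extraction function of the original analysis is
  unspecified; this rule is fixed and oracle-tested.
* **Matching**: candidates above each threshold (0.1–0.9, step 0.05) are
  matched greedily in descending value to the nearest unmatched annotation
  within 2 voxels *Euclidean* distance (Chebyshev was the alternative;
  Euclidean is the stricter and more common reading).  Greedy one-to-one
  matching avoids double-counting and equals optimal assignment whenever
  annotations are separated by more than twice the tolerance.
* **Summary**: median and IQR of TP and FP over all (frame, threshold)
  pairs.  The aggregation axis of the original tables is ambiguous
  (thresholds, frames, or both); "both" is the default here and the
  per-(frame, threshold) table is returned so any other aggregation can be
  formed.

## Statistics

`wilcoxonSignedRank()` is two-tailed, drops zero differences (Wilcoxon
convention rather than Pratt), mid-ranks ties, and uses the exact sign-flip
null distribution (dynamic programme over the $2^n$ assignments, valid
under ties) for up to 20 nonzero differences, switching to the normal
approximation with continuity and tie correction above.  Quartiles use the
inclusive linear-interpolation convention (`quantile` type 7) — quartile
conventions differ enough to move IQR bounds, so this is fixed and
documented.  No multiple-testing correction is applied, matching the
source analysis; `buildReport()` flags p < 0.05 per comparison.  Paired
samples are formed frame-by-frame across parameter settings (the pairing
used originally is not stated; this assumption is documented here).

## Numerical choices and problem sizes

* Sub-grid 8×8×3 per pixel; dipole window 30 mm around the markers
  (outside it the artifact contribution is < 0.1 Hz and is ignored).
* The attenuation map is frame-independent and is computed once per
  (phantom, wire, acquisition); `simulateSeries(..., attenuation = )`
  reuses it across seeds.
* Strict `>` at the segmentation threshold ("higher than"); sample SD
  everywhere.
* Degenerate inputs: empty masks give width 0; empty centre lists give
  all-zero labels; all-zero paired differences raise an error rather than
  returning p = 1.
* Test/acceptance problem sizes: 30/10/10 train/val/eval frames, 60-epoch
  training, monotonicity over 20 seeds × 30-frame datasets, false-positive
  calibration over 50 wire-free subtraction frames.  These sizes were
  chosen as the package's desk-scale defaults; the full 400-epoch,
  augmented configuration remains available through `detectionConfig()`.

## Known limitations

* The dipole constant is calibrated to a width band, not to field theory;
  absolute widths and CNRs are therefore indicative only, and the
  simulated width range is narrower than the physical one.
* Static wire: per-frame artifact variability comes from noise and
  pulsation only, which understates the frame-to-frame variation a moving
  wire produces.
* The 5-mm intermarker pair merges into a single void at larger widths,
  exactly as in the physical images; per-marker (split-component) width
  analysis is intentionally out of scope — width is measured on the union
  mask.
* Qualitative (observer-score) analysis and 3-D artifact volumetry are out
  of scope.
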
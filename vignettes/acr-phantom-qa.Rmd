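---
title: "Automated ACR CT phantom analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ACR CT phantom analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrct)
```

## The measurement model

The ACR CT accreditation phantom is a water-equivalent cylinder, 200 mm in
diameter and 160 mm long, optionally wrapped in a 330 mm outer body ring for
body-protocol testing. Its four axial modules carry the structures behind the
five image-quality metrics this package computes:

1. **HU accuracy** — five cylindrical inserts (polyethylene ≈ −95 HU, water
   ≈ 0, acrylic ≈ 120, bone ≈ 955, air ≈ −1000). The metric is the mean HU in
   a ~200 mm² ROI centred on each insert, graded against inclusive passing
   ranges (defaults: water −7..7, acrylic 110..135, bone 850..970,
   air −1005..−970, polyethylene −107..−84 HU).
2. **Contrast-to-noise ratio** — a low-contrast rod nominally +6 HU over its
   background; CNR = (mean A − mean B)/SD(B) with ROI A on the rod and ROI B
   in the background. Protocol-class minima default to 1.0 (adult head, adult
   body, pediatric head) and 0.4 (pediatric body).
3. **Uniformity** — five equal ~400 mm² ROIs on the uniform slab, one
   central and four peripheral at 12/3/6/9 o'clock; the statistic is the
   maximum |peripheral − center| mean difference. Below 5 HU passes, 5–7 HU
   is a minor deviation, above 7 a major one.
4. **Image scaling** — two metal ball bearings 100 mm apart; the metric is
   the percent error of the measured sub-voxel centroid separation.
5. **Spatial resolution** — eight bar patterns at 4, 5, 6, 7, 8, 9, 10 and
   12 lp/cm; the score is the highest frequency still modulated, graded
   against 6 lp/cm (head-type protocols) or 5 lp/cm (body-type).

A protocol's scorecard is the nine verdicts together (CNR, resolution, five
materials, scaling, uniformity); "overall pass" requires all nine to pass,
and machine comparisons count criteria met with *no* deviation.

Exact in-module insert coordinates, ball-bearing placement, ROI areas and
module thicknesses are not published at millimetre precision; the values in
`default_head_phantom()` follow public ACR CT quality-control documentation
where available and are otherwise this package's own documented convention
(72° insert spacing at 60 mm radius, peripheral uniformity ROIs 10 mm in
from the edge, 40 mm module slabs). Because the simulator and the analyzer
share this single `phantom_spec`, only internal consistency matters for
validation; all of it is configurable for users matching a physical phantom.

## The synthetic-data generator

`render_volume()` voxelizes the spec: each voxel's HU is the in-plane
area-weighted average of the nominal material HU it covers, computed on a
4× (configurable) supersampled grid; ball bearings get per-voxel spherical
partial-volume weighting; outside the phantom is air. Rendering is noise- and
artifact-free by construction, so every degradation is injected explicitly by
`degrade()` in a fixed, documented order:

1. **geometry** — in-plane magnification, rotation and shift, applied by
   bilinear resampling (emulates scale error and setup misalignment);
2. **blur** — in-plane Gaussian of stated FWHM (mm), the system resolution;
3. **cupping** — a radial field, zero at the phantom centre, reaching
   −amplitude at the peripheral-uniformity ROI ring radius and flat beyond
   it. Normalizing to the measurement ring (rather than the physical edge)
   makes the uniformity metric read the amplitude directly: amplitude 6 HU
   measures ≈ 5.6 HU and classifies as a minor deviation. The reference
   radius is the shared `uniformity_ring_radius()`;
4. **per-material bias** — constant HU offsets inside the (transformed)
   insert discs, for parameter-recovery tests and HU-accuracy failures;
5. **noise** — i.i.d. white Gaussian in HU, seeded; the same volume,
   parameters and seed always give a bit-identical result.

The generator emulates what the ACR metrics *measure*: CT-like HU contrast,
stochastic noise, resolution loss, the cupping that scatter and beam
hardening produce in cone-beam systems, and geometric error. It does **not**
model projection physics: no energy-dependent attenuation, quantum noise
texture, streaks, rings, beam-hardening spectra or reconstruction algorithms.
Passing the property suite therefore demonstrates that the measurement and
scoring chain is correct and self-consistent — not that any physical scanner
would produce these images. Conclusions about real systems come from feeding
real DICOM series or measured-metric tables through the same chain.

Two presets anchor the end-to-end tests: `"clean_diagnostic"` (0.5 mm
voxels, 3 HU noise, 0.6 mm blur, 1 HU cupping) whose ground truth sits well
inside every passing band, and `"cbct_degraded"` (9 HU noise, 1.2 mm blur,
8 HU cupping) built to fail CNR (6/9 ≈ 0.7 < 1) and uniformity (≈ 7.5 HU,
major) while leaving HU accuracy and scaling intact.

## Numerical and scoring choices

* **Resolution threshold.** Human readers score the "last visible" bar
  pattern; an automated pipeline needs a number. Modulation is
  (mean over bar-centre strips − mean over gap-centre strips) / nominal
  contrast, clipped to [0, 1], and a pattern counts as resolved at
  modulation ≥ 0.25, with the resolvable frequency requiring every lower
  frequency to be resolved too (a single aliased mid-frequency cannot
  inflate the score). No exact equivalence with published by-eye scores is
  claimed; validation uses synthetic scans whose answer is far from the
  threshold. The measurement itself is validated against an independent 1D
  oracle (square wave convolved with a Gaussian, closed form via the normal
  CDF, same strip averaging).
* **Standard deviations** are sample (n − 1) everywhere, matching how
  scorecard summaries are conventionally reported.
* **Band edges.** HU passing ranges are inclusive at both bounds; the
  uniformity minor band is inclusive at 5 and 7 HU (consistent with 4.98
  passing and 5.10 minor in the bundled tables). Whether an exact 5.00
  should pass instead is not documented anywhere we know of; the adopted
  convention is fixed here and in `acr_criteria()`.
* **Scaling tolerance** defaults to 1.0 %: a published numeric criterion is
  not available, every bundled measurement at ≤ 0.9 % is reported as
  passing, and 1 % of 100 mm equals the 1 mm distance-accuracy tolerance
  common in radiotherapy QA. Configurable.
* **HU minor bands** default to none — outside the passing range counts as
  failing — because the bundled body-phantom analyses use pass/fail language
  for HU accuracy. Per-material minor bands can be configured.
* **Failure summaries** measure the distance to the *nearest violated bound*
  of the passing range (`deviation_beyond_range()`, continuous, zero on the
  range, 1-Lipschitz). One published air summary (−40.6 ± 3.3 HU) is
  reproducible only as the distance to the *far* bound of the air range
  (−1005 when all failures lie above −970); the nearest-bound convention is
  kept because it reproduces the acrylic, bone and water summaries
  (9.4 ± 4.8, 32.7 ± 28.6, 7.2 ± 3.6 HU), and the air column is simply
  reported under the same convention (5.6 ± 3.3 HU).
* **CNR minima.** 0.4 for pediatric body is required for a 0.7 CNR
  pediatric-abdomen measurement to pass, as the bundled head-phantom
  scorecard implies; 1.0 is used for the other three classes. Some ACR
  documents give pediatric head 0.7 instead of 1.0 — no bundled measurement
  distinguishes the two, and the value is configuration, not code.
* **Localization.** Translation is the non-air mask centroid (threshold
  −300 HU); rotation comes from the ball-bearing pair, which fixes the angle
  modulo 180° (adequate for the small setup errors the pipeline targets);
  the metal threshold is 1500 HU, far above the 955 HU bone insert and bar
  patterns and far below the 3000 HU markers. With more or fewer than two
  metal components the detector rejects rather than guesses. ROI statistics
  pool the central 3 slices of a module; single-slice analysis is supported
  via `nslices = 1`.
* **Degenerate inputs** error early and explicitly: CNR with zero background
  SD, uniformity with ≠ 5 ROIs, ROIs containing no voxel centres, mapped
  ROIs leaving the image, single-exposure stability tables, all-air volumes.

## Validation problem sizes

The test-suite and acceptance simulations are sized for a desk run: 2 mm
voxels on single 40 mm modules for statistics and parameter recovery
(20 seeds for bias / cupping / scale / noise recovery), 0.25 mm voxels on a
reduced field of view for bar-pattern measurements, and 0.5 mm voxels for
the two full-phantom presets. The bundled measured tables exercise the
criteria engine at full scale, since scoring is exact arithmetic.

## Known limitations

* The phantom geometry is the package's reconstruction from public
  documentation, not vendor drawings; absolute coordinates may differ from a
  physical unit even though all relative quantities (100 mm marker spacing,
  insert materials, pattern frequencies) match.
* The simulator's noise is white; real CT noise is correlated by
  reconstruction, so CNR on real scans depends on kernel choices the
  simulator does not represent.
* Rotation estimation assumes the phantom is level (no pitch/roll), as the
  standard couch setup ensures.
* Automated resolution scoring replaces reader judgment; values near the
  modulation threshold should be reviewed rather than trusted blindly.
* DICOM support covers uncompressed Explicit VR Little Endian axial CT
  series with the geometry and rescale tags only.
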
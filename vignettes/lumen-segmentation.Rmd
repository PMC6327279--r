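---
title: "Automated lumen segmentation in intracoronary OCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lumen segmentation in intracoronary OCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlumen)
```

## The problem

Intracoronary optical coherence tomography (OCT) images the artery wall from
a catheter at 10–20 µm resolution. The first quantitative step of almost any
OCT analysis is delineating the lumen border — the inner edge of the bright
intimal ring — on every cross-section of a pullback. Manual contouring takes
on the order of a minute per frame and suffers inter-observer variability,
so `octlumen` implements a fully automated pipeline that runs on every frame
without exclusions, including frames with guide-wire shadows, side-branch
(bifurcation) openings, and residual-blood speckle.

## The pipeline

All segmentation happens in polar coordinates about the catheter center,
where the vessel wall becomes a roughly vertical band. Per frame:

1. **Overlay removal and grayscale.** Burned-in calibration markers and text
   are saturated colors on an achromatic background; pixels whose RGB channel
   spread exceeds 10 % of full scale are blanked, then the NTSC 1953 luma
   weights (0.299, 0.587, 0.114) produce the working grayscale image.
2. **Polar transform.** Bilinear resampling onto 360 angle bins (1°) and one
   radius bin per pixel, `radial_spacing_mm = pixel_spacing_mm`.
3. **Catheter removal.** The imaging catheter has a known physical diameter
   (0.91 mm for the 2.7 Fr catheters modelled here), so the columns covering
   radii up to `diameter/2 + 0.05 mm` are blanked outright. The 0.05 mm
   margin covers the sheath's bright reflection just beyond the nominal
   radius.
4. **Despeckling.** A 5×5 median filter followed by Gaussian smoothing with
   `sigma = 2` bins. The median window is the method's stated constant; the
   Gaussian sigma is a package default chosen so that speckle remnants blur
   away while the intima leading edge moves by at most about one bin. Both
   filters replicate the image border, avoiding dark halos at the
   catheter-adjacent edge.
5. **Automatic thresholding.** Otsu's between-class-variance maximization
   over a 256-bin histogram of [0, 1]. The lumen/tissue histogram is
   strongly bimodal, for which Otsu is the standard parameter-free choice.
6. **Morphological cleaning.** Opening then closing with a flat disk of
   radius `R = 5` bins — the disk preserves the circular character of the
   wall; `R = 5` is the method's stated constant. Components smaller than
   the disk area are then discarded: they are residual-blood clusters, not
   wall.
7. **Gap bridging.** Guide-wire shadows and bifurcations cut the wall band
   into disconnected components. Components are ordered top-to-bottom by
   first angle row and treated cyclically (the vessel is closed, so the last
   component connects back to the first across the angular wrap-around).
   For each consecutive pair, the upper component contributes its
   bottom-left extreme point and the lower one whichever of its top-left /
   top-right extremes is closer; the endpoints are refined to the first
   (innermost) white pixel of their row, then joined by a straight
   rasterized segment.
8. **Border extraction.** Sobel gradient magnitude on the bridged binary
   image; per angle row the innermost edge position on the foreground side
   is the lumen border (the lumen border is by definition the inner boundary
   of the intima; foreground added at larger radii cannot move it).
9. **Smoothing and back-transform.** The radius-per-angle signal is smoothed
   with a Savitzky–Golay filter (window 35, order 2) with cyclic boundary
   handling, then mapped back to a closed Cartesian contour.

### Design choices that were genuinely open

* **Gap length metric.** The 2 mm bifurcation cutoff is a physical length,
  and the distance between two polar pixels is not meaningful in (row, col)
  units — a 1° step means 26 µm at 1.5 mm radius but 9 µm at 0.5 mm. Gap
  endpoints are therefore mapped back to Cartesian mm before measuring, so
  a 30° wedge at 1.5 mm radius yields the chord `2·1.5·sin(15°) ≈ 0.78` mm.
* **The cutoff flags, it does not exclude.** Both guide-wire gaps and
  bifurcations are bridged; `is_bifurcation` records which side of the 2 mm
  cutoff a gap falls on. Bridging everything is what lets the pipeline claim
  "no frame excluded".
* **Endpoint refinement.** The refinement step is implemented as a single
  move to the innermost white pixel of the endpoint's row, for both gap
  kinds. A depth-graded search made no measurable difference on phantoms
  and adds a parameter, so it was dropped.
* **Wrap-around.** The angle axis is treated as cyclic for bridging and for
  contour smoothing, but *not* for the morphological operations: a disk of
  radius 5 bins spans 10° of angle, and on clinically plausible lumens the
  wall band crosses the row seam anyway, where replicate behavior and
  cyclic behavior agree to within the disk radius.
* **Smoothing domain.** The Savitzky–Golay filter is applied to the polar
  radius signal rather than to x/y coordinates: for closed, star-shaped
  contours the two are equivalent in practice, and radius-domain smoothing
  cannot introduce self-intersections.
* **Innermost-edge rule.** Sobel marks both edges of the wall band; the
  per-row innermost edge is selected because the lumen border is the inner
  intima boundary. With two nested bands (e.g. a bridged line inside tissue)
  the inner one wins by construction.

## Quantification and agreement statistics

`lumen_metrics()` reports the shoelace polygon area and diameters measured
as chords through the contour centroid at 180 equally spaced directions
(each chord is the sum of the two opposite-ray border distances). Centroid
chords reproduce the circle and ellipse closed forms and are stable under
rotation; 180 directions resolve min/max diameters of smooth contours to
well under 0.5 %.

Between-method agreement uses the field's standard toolkit:

* relative difference `RD = 100/N · Σ (I_i − O_i)/max(O_i, I_i)` and its
  absolute counterpart ARD (antisymmetric and symmetric respectively);
* ICC(2,1): two-way random-effects, absolute-agreement, single-measure
  intraclass correlation. Absolute agreement is the appropriate form for
  "do two methods give the same number", since it penalizes constant
  offsets that a consistency ICC would forgive. The confidence interval is
  the McGraw–Wong F-based interval — the CI construction was an open
  choice, and the F-based interval is the one the standard implementations
  report;
* Bland–Altman limits of agreement `mean(d) ± 1.96·sd(d)` with the sample
  (N−1) standard deviation.

The package ships the per-method mean table of a 667-frame clinical
four-method comparison (`reported_method_means()`) so the worked
mean-difference arithmetic in the acceptance script operates on real
reported values: automated-vs-manual mean lumen area differs by 0.10 mm²
and minimal diameter by 0.03 mm.

## The phantom generator

Clinical OCT pullbacks are not redistributable, so validation uses
`generate_phantom()`: synthetic cross-sections with exactly known geometry.
The generator emulates the features that drive the pipeline's design:

* a dark lumen bounded by a bright intimal ring (reflectivity 0.9) of
  configurable thickness (default 0.15 mm), with exponentially decaying
  signal outward (decay length 0.2 mm) so thresholding sees a realistic
  bright-leading-edge profile;
* a bright catheter ring at the known 0.91 mm diameter;
* a guide wire: bright spot at the border plus a zeroed radial shadow wedge
  behind it;
* a bifurcation: the ring erased over an angular wedge;
* multiplicative speckle on tissue pixels, modelled as a mean-one Rayleigh
  factor mixed in at a configurable level — the qualitative character of
  coherent-imaging speckle without claiming a physical forward model;
* residual-blood clutter: small bright blobs between catheter and border.

Lumen shapes are circles, ellipses, and Fourier-perturbed circles
(harmonics 2+, amplitudes ≤ 10 %), spanning the clinically plausible
caliber range (radius 1–2 mm) at 0.01 mm/px on 512×512 grids. Intensities
are quantized to the 16-bit grid at generation, so a written 16-bit TIFF
frame reads back pixel-identical.

What the phantoms do **not** emulate: eccentric catheter positions, signal
attenuation with depth, motion/NURD artifacts, thrombus, dissections, and
stent struts. Passing the phantom suite therefore demonstrates that the
implementation realizes the method faithfully on geometry it was designed
for — it does not re-establish the clinical accuracy figures, which were
measured on real pullbacks.

## Numerical choices and degenerate inputs

* The median stage runs on a 16-bit quantized grid (the constant-time
  median implementation used underneath); the resulting error is below
  1e-4, negligible against the 1/256 threshold granularity.
* Morphological neighborhoods are clipped to the image domain at borders
  (no implicit background padding), which avoids eating the wall band where
  it touches the first/last angle row.
* Extreme-point ties are broken toward the named corner (e.g. "top-left" =
  leftmost among topmost boundary pixels).
* A constant polar image (e.g. an all-black frame) raises a
  degenerate-histogram error at the thresholding stage; `segment_pullback()`
  converts per-frame errors into logged failures with the failing stage and
  continues — no frame aborts the pullback.
* Savitzky–Golay weights are computed from the least-squares design matrix
  directly; window 35 / order 2 attenuates a 1-cycle-per-revolution radius
  harmonic by under 3 % and preserves the mean radius exactly.

## Problem sizes in the shipped tests

The test suite and acceptance script validate on 512×512 phantoms with
360×~250 polar grids — full working resolution for this method — using a
22-phantom suite (11 artifact-free, 11 with artifacts) plus per-module
oracle checks on 64×64 morphology instances and 10-pair agreement series.
Measured on the suite, artifact-free lumen area ARD stays below 0.2 %, the
recovered border within 0.5 radial bins of truth, and with-artifact area
ARD below 1.5 %; the recovered-vs-truth area ICC exceeds 0.999.

## Known limitations

* Stented vessels are out of scope: strut reflections and shadows would
  need dedicated handling before thresholding.
* The catheter is assumed at the image center unless a per-frame center is
  supplied; no catheter detection is implemented.
* Only global (Otsu) thresholding is offered; very uneven illumination
  would call for local thresholding the method does not use.
* DICOM support is deliberately minimal: uncompressed little-endian pixel
  data, frame count, size and pixel-spacing tags. Compressed transfer
  syntaxes and vendor private tags are rejected rather than guessed at.
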
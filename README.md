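# octlumen

Fully automated lumen segmentation for intracoronary optical coherence
tomography (OCT), with quantification and method-agreement statistics.

OCT pullbacks produce hundreds of cross-sectional frames per vessel; the
lumen border — the inner edge of the bright intimal ring — must be contoured
on each of them before any stenosis or plaque quantification. Manual
contouring takes about a minute per frame. `octlumen` segments every frame
without manual interaction, including frames with guide-wire shadows,
bifurcation openings, and residual-blood speckle. It is aimed at
cardiovascular imaging researchers who need reproducible per-frame lumen
areas and diameters from DICOM pullbacks or raster frame exports.

## Method

Each frame is resampled to polar coordinates `(θ, r)` about the catheter,
where the wall is a straightened vertical band. The stages, with their
standard constants:

1. colored-overlay removal and NTSC grayscale, `0.299 R + 0.587 G + 0.114 B`;
2. catheter-ring blanking at the known physical radius (2.7 Fr → 0.91 mm);
3. despeckling: 5×5 median filter, then Gaussian smoothing (σ = 2 bins);
4. Otsu automatic thresholding of the polar image;
5. morphological opening and closing with a flat disk, R = 5 bins;
6. extrema-driven gap bridging: consecutive wall components (cyclic in θ)
   are joined from the upper component's bottom-left extreme point to the
   nearer of the lower component's top-left/top-right points; gaps longer
   than 2 mm are flagged as bifurcations, and all gaps are bridged;
7. Sobel border extraction — per angle row, the innermost tissue edge;
8. Savitzky–Golay smoothing of the radius signal, `(y_k)_s = Σ A_i y_{k+i} / Σ A_i`,
   window 35, order 2, cyclic in θ; back-transform to a closed Cartesian
   contour.

Quantification reports the shoelace area and centroid-chord diameters
(mean/min/max over 180 directions). Method agreement between two
per-frame measurement series uses the relative difference
`RD = 100/N · Σ (I_i − O_i)/max(O_i, I_i)`, its absolute counterpart ARD,
the absolute-agreement single-measure intraclass correlation ICC(2,1) with
F-based 95 % CI, and Bland–Altman limits of agreement `mean(d) ± 1.96 sd(d)`.

A synthetic phantom generator (`generate_phantom()`) renders cross-sections
with exactly known geometry — intimal ring, catheter ring, guide-wire
shadow, bifurcation wedge, speckle — so the whole pipeline is testable
end-to-end against ground truth. See the methods vignette
(`vignettes/lumen-segmentation.Rmd`) for the design rationale.

## Worked example

Segment a speckled elliptical phantom with a guide-wire shadow and compare
against its ground truth:

```r
library(octlumen)

spec <- phantom_spec("ellipse", semi_axes_mm = c(1.8, 1.4),
                     guide_wire = c(200, 15), speckle_level = 0.2, seed = 42)
ph  <- generate_phantom(spec)
res <- segment_frame(ph$frame)

res$metrics
#> lumen: area 7.947 mm^2, diameter 3.168 mm (min 2.800, max 3.604)
ph$truth$metrics
#> lumen: area 7.917 mm^2, diameter 3.162 mm (min 2.800, max 3.600)
res$bridges[, c("gap_length_mm", "is_bifurcation")]
#>      gap_length_mm is_bifurcation
#> row     0.51056087          FALSE
#> row1    0.03141553          FALSE
```

The recovered area differs from truth by 0.38 % despite the 15° wire shadow;
the bridge table shows the 0.51 mm wire gap (below the 2 mm bifurcation
cutoff) and the trivial wrap-around closure. On artifact-free phantoms the
recovered border stays within half a radial bin (5 µm) of the analytic
border.

Real data go through the same calls:

```r
cfg <- pipeline_config(calibration = calibration_spec(catheter_diameter_mm = 0.91))
run <- segment_pullback("pullback.dcm", cfg, output_dir = "out")   # metrics.csv, contours.csv
cmp <- compare_methods("out/metrics.csv", "manual/metrics.csv")
cmp$area_mm2      # difference, RD/ARD, ICC(2,1) + CI, limits of agreement
```

A thin CLI wraps the same functions:
`inst/cli/octlumen segment|phantom|suite|compare`.

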
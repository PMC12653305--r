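---
title: "Standardized NDVI anomalies for forest health monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized NDVI anomalies for forest health monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zndvi)
```

## The model

Optical satellites observe forest canopies through vegetation indices. The
workhorse is the Normalised Difference Vegetation Index,

$$\mathrm{NDVI} = \frac{\mathrm{NIR} - \mathrm{RED}}{\mathrm{NIR} + \mathrm{RED}},$$

a proxy for photosynthetic activity, high over dense healthy canopies and
depressed by defoliation, drought stress or mortality. A single year's NDVI
is a state, not a change; to detect *anomalies* each pixel is standardized
against its own multi-year record of growing-season composites:

$$z_y = \frac{\mathrm{NDVI}_y - \overline{\mathrm{NDVI}}}{\sigma_{\mathrm{NDVI}}},$$

where the mean and standard deviation are taken over a baseline period that
includes the evaluated year. Negative z means degradation relative to the
pixel's own normal, positive z recovery. The z surface is cut into five
damage classes

| class code | label | interval |
|---|---|---|
| 0 | severe damage | $z < -2$ |
| 1 | damage | $-2 \le z < -1$ |
| 2 | moderate / unchanged | $-1 \le z < 0$ |
| 3 | regeneration | $0 \le z < 1$ |
| 4 | strong regeneration | $z \ge 1$ |

The source class list ("< −2", "< −1", "< 0", "< 1", "> 1") leaves $z = 1$
unassigned and the boundaries ambiguous; we use lower-inclusive half-open
bins so the classes cover the real line totally and disjointly, with
$[1, \infty)$ as strong regeneration.

Upstream of the anomaly, each year's composite is built in three masking
stages followed by a median reduction:

1. **Scene prefilter** — scenes with metadata cloud cover *above* 5% are
   dropped ("more than 5%" excluded, so exactly 5% is retained), as are
   scenes outside the April 1 – October 31 season (inclusive bounds,
   compared within the scene's own calendar year).
2. **QA bitmask** — pixels with any configured quality bit set are invalid.
   The method text targets bits 9, 10 and 11, but the standard Sentinel-2
   QA60 layout defines only bit 10 (opaque cloud) and bit 11 (cirrus) and
   leaves bit 9 unused. We ship both lists as named presets (`"extended"`,
   `"qa60-standard"`); which one is active is recorded in the run log and
   manifest, and we make no guess about what the unused bit was meant to be.
3. **Scene classification** — pixels whose SCL code is in {3, 7, 8, 9}
   (cloud shadow and the cloud-probability classes) are invalid.
4. **Median composite** — per pixel and band, the median over the valid
   observations of the season; the even-count median is the mean of the
   two central values. Pixels with zero valid observations are carried as
   invalid, never silently filled.

By default the bands are composited first and NDVI computed from the
composited RED/NIR ("single cloud-free image per year", then the index). The
alternative — NDVI per scene, then the median — is available via
`median_composite(stat_on = "ndvi")` for sensitivity checks; the source
method is ambiguous between the two, so neither is asserted as *the*
original.

## Downstream statistics

**Plot extraction.** Field-monitoring networks record crown defoliation on
plots. The extraction support of the original analysis is unstated; we use a
3×3 pixel window (≈30 m at 10 m pixels, the scale of a monitoring plot),
average z over valid member pixels, and classify the mean with the same
intervals. A modal-class mode is available (`agg = "modal"`); neither is
claimed as the original rule. Plot-years with zero valid pixels get an
explicit missing marker and are counted, never dropped silently.

**Agreement.** Defoliation percent is binned into None (0–10), Weak
(>10–25), Medium (>25–60), Severe (>60–99) and Dead (100). To compare
satellite classes against field categories, both are binarized: by default
satellite-positive is class ∈ {severe damage, damage} and field-positive is
defoliation > 25% (Medium or worse). The original mapping between the five z
classes and the five defoliation categories is never stated, so the rule is
an explicit, serialized object attached to every report. From the binary
pairs we tally TP/FP/FN/TN and derive precision, sensitivity, specificity,
total accuracy and F1; metrics with zero denominators are reported as `NA`
markers, never as silent zeros. Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ supports both the binary and the general
K-category case, with $p_e = 1$ flagged undefined. Continuous agreement uses
OLS of defoliation percent on plot z, reporting $R^2 = 1 - RSS/TSS$ and RMSE
in defoliation-percent units.

The reference metric tables this implementation validates against are only
partially reproducible from their own printed cells: with FP = FN in every row, precision, sensitivity and F1 all
collapse to the printed TP value (and do match it), but the printed
specificity follows from TN/(TN+FP) only in the first year's row, and total
accuracy never follows from the printed cells. The acceptance suite pins
exactly the internally consistent cells and no others.

**Climate.** The Temperature–Precipitation Factor
$\mathrm{TPF} = 100\,\bar{T}_{\mathrm{Mar-Aug}} / \sum P_{\mathrm{Mar-Aug}}$
summarizes growing-season drought stress (higher = drier). "Average
temperature" is read as the unweighted mean of the six monthly means — the
source does not state day-weighting. TPF is regressed on plot-level mean z
per site; the response defaults to continuous z, with the ordinal class-code
variant available, because the original regression's response is ambiguous.

## The synthetic world

Every stage is exercised on a simulator with known ground truth
(`simulation_config()`, `simulate_forest()`). Its defaults state one world:

* 7 consecutive years (a 2017–2023 analogue) on a 10 m grid; 8 scenes per
  season; healthy NDVI 0.8 with a fixed smooth spatial field of amplitude
  0.05.
* **Interannual variability is a shared year-quality signal**, scaled to
  `interannual_sd = 0.05`, with the first year an exceptionally favourable
  reference season and later years slightly below the long-term mean
  (standardized values $\sqrt{n-1}$ and $-1/\sqrt{n-1}$). This is a design
  decision with a mathematical reason: per-pixel standardization is
  scale-invariant, so a world whose interannual variation is i.i.d. pixel
  noise flags a fixed ≈16% of healthy pixels below $z = -1$ in any given
  year *no matter how small the noise is*. Real composite series are
  dominated by common good-year/bad-year forcing; modelling that forcing as
  shared (and keeping it clear of the damage thresholds) makes the damage
  classes attributable to the injected disturbances alone.
* One disturbance event by default: year 6 (the "2022 drought"), 40% of the
  tile, NDVI drop 0.3 — roughly the scale of the severe-drought signal the
  method was built to detect.
* Clouds arrive as 4×4 pixel blocks with per-block probability 0.05, split
  into opaque cloud, cirrus and cloud shadow, with QA bits and SCL codes set
  accordingly and scene metadata equal to the realized contaminated
  fraction. Blocks, not single pixels, so that the 5% scene prefilter
  actually rejects some scenes.
* Reflectance pairs invert the index with the band sum fixed at 0.5
  (NIR = 0.25(1+NDVI), RED = 0.25(1−NDVI)); only the ratio matters
  downstream, so the inversion is made unique.
* 78 Level-I-like and 7 Level-II-like plots on jittered regular grids, with
  defoliation = clamp(5 + 100 × local NDVI drop + noise, 0, 100), so a 0.3
  drop produces 35% defoliation ("Medium").
* Monthly temperate-continental climate per Level-II site; disturbance years
  get precipitation × 0.6 and temperature + 1.5 °C, so TPF is strictly
  higher in drought years.
* One master seed feeds four sub-streams drawn in a fixed order (scenes,
  clouds, plots, climate); regeneration under the same seed is bit-identical
  and the streams are isolated (the climate draw does not depend on whether
  scenes were generated).

What the generator does **not** emulate: radiative transfer, topography,
species-specific spectra, phenology within the season, cloud-shadow
geometry, sensor geometry and registration error. A green test therefore
establishes the correctness of the *computations* on data with the stated
statistical structure, not the field performance of the method on real
imagery — the published national-scale agreement values depend on real
scenes and surveys and are not reproducible at desk scale.

## Numerical choices

* Degenerate pixels (baseline SD < 1e−6 NDVI units) get z = 0 in every year
  and are counted; with zero noise and no interannual signal the whole
  background takes this path, which is what makes exact footprint recovery
  meaningful.
* SD convention defaults to population (divide by N) over the baseline
  years, configurable to sample (N−1). With a 7-year baseline the choice is
  material (the two differ by ≈8%), so it is surfaced in the configuration
  and echoed in outputs.
* The baseline includes the evaluated year, following the stated reference
  period.
* Nearest-pixel snapping of plot coordinates breaks ties toward smaller
  row/column; modal plot classification breaks ties toward the worse class.
* Report CSVs round to 2 decimals to match the source tables; full
  precision is retained in memory.

## Known limitations

* No geospatial referencing: rasters are plain matrices and persistence is
  plain-text TSV/CSV/JSON (the execution environment provides no GeoTIFF
  stack); the module boundaries match a raster-backed implementation, so
  swapping in a GeoTIFF reader/writer would be localized.
* The pipeline targets desk-scale tiles (≤ a few hundred pixels a side);
  compositing uses straightforward per-pixel medians, not tiled execution.
* Only NDVI is implemented; moisture and red-edge indices, trend/breakpoint
  detection and machine-learning classifiers are out of scope.
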
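# zndvi

Standardized NDVI anomaly mapping and field validation for forest health
monitoring.

## What it is for

Ground-based forest condition surveys (crown defoliation scored on sparse
monitoring-plot networks) are accurate but labour-intensive and spatially
thin. High-resolution optical satellites can scale them up: compose one
cloud-free growing-season image per year, turn it into a vegetation index,
standardize each pixel against its own multi-year record, and read damage
off the anomaly. This package implements that pipeline end to end as tested,
reusable R, together with the statistics used to validate the satellite
signal against field defoliation — and a synthetic-scene generator with
known ground truth so every stage can be verified without any satellite
data. It is aimed at remote-sensing and forest-health analysts who want the
method's machinery (and its test harness), not at reproducing any particular
country's survey.

## The statistics at its core

For each pixel and year $y$,

$$\mathrm{NDVI} = \frac{\mathrm{NIR}-\mathrm{RED}}{\mathrm{NIR}+\mathrm{RED}},
\qquad
z_y = \frac{\mathrm{NDVI}_y - \overline{\mathrm{NDVI}}}{\sigma_\mathrm{NDVI}},$$

computed on April–October median composites after three-stage cloud
screening (scene-level 5% prefilter, QA bitmask, SCL class exclusion). The
anomaly is cut into five damage classes ($z<-2$ severe damage, $[-2,-1)$
damage, $[-1,0)$ moderate, $[0,1)$ regeneration, $\ge 1$ strong
regeneration). Plot-level means of $z$ are validated against field
defoliation via confusion matrices (precision, sensitivity, specificity,
total accuracy, F1), Cohen's kappa $\kappa=(p_o-p_e)/(1-p_e)$, and OLS
$R^2$/RMSE. Growing-season drought is summarized by
$\mathrm{TPF} = 100\,\bar T_{\text{Mar–Aug}}/\sum P_{\text{Mar–Aug}}$ and
regressed against plot anomalies.

See `vignettes/forest-health-anomalies.Rmd` for the full model description,
the stated synthetic world, and every numerical convention.

## Worked example

Simulate the default world — 7 years on a 20×20 tile at 10 m, 8 scenes per
season, block clouds, 78 + 7 monitoring plots, and one drought-year
disturbance (year 6, 40% of the tile, NDVI drop 0.3) — and run the full
pipeline:

```r
library(zndvi)
cfg <- pipeline_config(sim = simulation_config(seed = 1))
res <- run_pipeline(cfg)
#> [zndvi] prefilter kept 38 of 56 scenes (QA preset 'extended')
#> [zndvi] standardized 7 years; 0 degenerate pixels
#> [zndvi] extracted 595 plot-year values (0 missing)
```

The class distribution (percent of pixels per damage class and year) shows
the injected disturbance and nothing else:

```
               label 2017  2018 2019 2020 2021  2022 2023
       severe damage    0  0.00  0.0  0.0  0.0 40.00  0.0
              damage    0  0.25  0.0  0.0  0.0  0.00  0.0
            moderate    0 60.00 58.8 58.8 59.5 58.75 59.8
        regeneration    0 39.75 41.2 41.2 40.5  1.25 40.2
 strong regeneration  100  0.00  0.0  0.0  0.0  0.00  0.0
```

2017 is the favourable reference season (everything strongly positive), the
2022 analogue puts exactly the injected 40% footprint into "severe damage",
and the other years sit in the neutral classes. Plot-level agreement against
the simulated field defoliation, stratified by year:

```
 stratum n_used kappa precision sensitivity f1 r_squared rmse
    2017     85    NA        NA          NA NA  7.45e-03 1.97
    ...
    2022     85     1         1           1  1  9.22e-01 4.11
  pooled    595     1         1           1  1  2.56e-01 6.22
```

In healthy years there are no damaged plots on either side, so kappa and the
positive-class metrics are undefined (`NA` markers, not zeros). In the
disturbance year the satellite classes and the field categories agree
perfectly (κ = 1) and defoliation regresses on plot z with R² = 0.92. The
drought coupling is visible in the TPF series of any Level-II site — year
2022 roughly doubles:

```
 site_id year  tpf
  L2-001 2017 4.73
  L2-001 2018 5.04
  L2-001 2019 4.87
  L2-001 2020 5.15
  L2-001 2021 5.02
  L2-001 2022 9.10
  L2-001 2023 4.93
```

With `out_dir` set, `run_pipeline()` writes all tables as CSV, the z and
class grids as plain-text TSV, and a JSON manifest with the configuration,
seed, per-stage counts and file checksums. A thin command-line front end
lives at `inst/cli/zndvi.R`.

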
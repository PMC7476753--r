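# cortexgrad

Spatial gradients of oscillatory peak frequency across the cortical
surface, from raw parcel time series to mixed-effect statistics.

## The problem

Resting-state cortical activity mixes narrowband oscillations (theta,
alpha, beta) with an arrhythmic 1/f background. The frequency of the
dominant oscillatory peak (PF) varies systematically over the cortex —
decreasing from posterior sensory to anterior association areas — and
this gradient, not just oscillation amplitude, carries information about
cortical hierarchy. Quantifying it requires a chain of steps, each with
well-known failure modes: robust spectral estimation from multichannel
parcel data, separation of oscillatory peaks from the 1/f background
(whose own offset and slope form spatial gradients and confound naive
peak picking), geodesic rather than Euclidean distances along the cortical
sheet, and statistics that respect the nesting of parcels within
participants and hemispheres.

cortexgrad implements that chain for researchers analysing parcellated
electrophysiological (MEG/EEG source) data, together with a
synthetic-cohort generator with known ground truth so the whole pipeline
is validated by parameter recovery.

## The model

Per ROI and participant, the spectrum is estimated as the per-bin 10%
trimmed mean over DPSS multitaper epoch spectra (2-s epochs, 2 Hz
smoothing, 7 tapers) of the SVD components carrying 95% of the channel
variance. The aperiodic background is a power law, fitted robustly as a
line in log-log space over 3–45 Hz:

    log10 P(f) = offset + slope · log10 f  + peaks

Peaks are local maxima of the 1/f-corrected spectrum (height and
prominence ≥ 0.05 log10 units, bin resolution); the dominant PF is the
peak with strongest power in the original spectrum. The central spatial
model is a linear mixed-effect regression of PF on ROI centroid
coordinates (mm),

    PF_ij = β0 + S0j + (β1+S1j)X + (β2+S2j)Y + (β3+S3j)Z
            + β4·XY + β5·XZ + β6·YZ + e_ij

with random intercepts and coordinate slopes by participant j and a
random intercept for hemisphere within participant. Companion models use
the geodesic distance to a posterior reference parcel as a
leakage-robust axis (full cortex, three consecutive Y windows, a
20–30 mm annulus control), an ordinal hierarchy vector, and categorical
resting-state networks; robust descriptives (trimmed means, skipped
Pearson correlation, per-participant correlation consistency) complete
the surface.

## Worked example

A small synthetic cohort (3 participants, 12 ROIs, 20 s at 300 Hz — the
defaults are 20 × 96 × 300 s) through the full chain:

```r
library(cortexgrad)
library(dplyr)

cfg <- pipeline_config(
  cohort = cohort_config(n_participants = 3, n_rois_per_hemisphere = 6,
                         n_vertices_per_hemisphere = 120,
                         duration = 20, seed = 5))
res <- run_pipeline(cfg, "example_out")

tidy(res$fits$coordinate_pf) |> filter(term %in% c("y", "z"))
```

```
# A tibble: 2 × 8
  term  estimate std_error    df statistic  p_value   ci_low  ci_high
  <chr>    <dbl>     <dbl> <int>     <dbl>    <dbl>    <dbl>    <dbl>
1 y     -0.0192    0.00123    29   -15.7   1.11e-15 -0.0217  -0.0167
2 z      0.00199   0.00360    29     0.554 5.84e- 1 -0.00536  0.00935
```

The generator injected a PF gradient of −0.02 Hz/mm along the
posterior-anterior (Y) axis and none along Z; the model recovers a
significant negative Y effect of about that size and a null Z effect.
Even at this toy size the per-ROI trimmed-mean PF tracks the axis:

```r
res$summary$skipped_r_pf_y
#> [1] -0.9910856
res$summary$fraction_individually_significant
#> [1] 1
```

`example_out/` now contains every numeric table (TSV with a config-hash
header), `summary.json`, `manifest.json`, figures and `report.md`. At the
default desk scale (20 participants × 96 ROIs × 5 min) the run takes a
few minutes and additionally exercises the three Y-window models, the
annulus control, the hierarchy and network models and data-driven band
delineation.

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/scripts/cortexgrad run --config config.yaml --out out_dir
```

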
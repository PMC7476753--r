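---
title: "Modelling spectral peak-frequency gradients on a cortical surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spectral peak-frequency gradients on a cortical surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cortexgrad)
```

## The analysis in one paragraph

Resting-state cortical activity shows narrowband oscillations riding on an
arrhythmic, 1/f-shaped background. The frequency of the dominant
oscillatory peak (PF) is not uniform over the cortex: it decreases along
the posterior-anterior axis, and tracks the cortical hierarchy. cortexgrad
implements the full chain needed to quantify such gradients: robust
parcel-level power spectra from multichannel time series, separation of
the aperiodic 1/f component from oscillatory peaks, extraction of dominant
and band-specific peak frequencies, and linear mixed-effect (LMEM) models
of their spatial and hierarchical organisation — plus a synthetic-cohort
generator with known ground truth, so every stage can be validated by
parameter recovery rather than by eyeballing.

## Spectral estimation

For each ROI the vertex channels are reduced by SVD to the components
carrying 95% of the variance (`svd_reduce()`), segmented into 2-s epochs,
and transformed with a DPSS multitaper estimator (`multitaper_psd()`):
`K = max(1, floor(2TW - 1))` Slepian tapers, so the default T = 2 s,
W = 2 Hz gives 7 tapers, 0.5 Hz resolution and +/-2 Hz spectral
smoothing. Epoch spectra are pooled across epochs and components, and the
ROI spectrum is the per-frequency-bin 10% trimmed mean
(`pooled_roi_spectrum()`): at each bin the lowest and highest 10% of the
pooled values are discarded before averaging. Trimming per bin is what
makes the estimator provably robust — eight epochs with 10x amplitude
artefacts move the pooled spectrum by under 5% where the plain mean is off
by more than 50% (this is a test in the suite). Epoch spectra are pooled
raw, without per-component normalization (each epoch x component spectrum
counts once); a variance-weighted pooling would re-introduce sensitivity
to single loud components.

The PSD scaling is one-sided with the integral over frequency equal to the
signal variance; tapers are unit-energy, and the per-epoch mean is removed
before tapering (no further detrending — any high-pass filtering is
assumed to have happened upstream, outside this package's scope).

## Aperiodic fit and peak extraction

`fit_aperiodic()` models the background as a single power law — a line in
log10 power vs log10 frequency over 3-45 Hz, without a knee. The fit is
robust by iterative masking: OLS, exclusion of bins whose positive
residual exceeds 2x the MAD of the residuals (peaks only stick up), refit,
at most five passes. On an exact power law the MAD collapses to zero and
the loop exits immediately, which is why noiseless spectra are recovered
to near machine precision. The `offset` is log10 power at 1 Hz and
`slope` is signed (negative for 1/f decay); the "exponent" convention of
other tools is `-slope`.

`flatten_spectrum()` subtracts the fitted line; `detect_peaks()` finds
local maxima of the residual with height and topographic prominence of at
least 0.05 log10 units (both configurable; no published value exists for
these thresholds, so they are explicit parameters rather than constants).
Peak frequencies are reported at bin resolution with no interpolation,
matching the 0.5 Hz granularity at which band edges are usually quoted.
The *dominant* PF is the detected peak with the strongest power in the
*original* spectrum, 1/f background included — on a steep background a
theta peak can dominate even when an alpha peak has the larger corrected
amplitude. ROIs with no detected peak are missing data downstream, never
zero-filled. *Band-specific* PFs instead take the largest corrected
amplitude within each band.

One property of this estimator is worth stating explicitly because the
synthetic experiments made it visible: the bin-resolution argmax of a
flattened spectrum is biased slightly upward in frequency, because
flattening divides by a background that decreases with frequency, tilting
the top of every peak toward its high-frequency edge. The size of the
shift grows with the effective spectral width of the peak (oscillation
width convolved with the +/-2 Hz taper smoothing) and with the local 1/f
slope. For peaks whose intrinsic width is comparable to the smoothing
bandwidth the shift is about one 0.5 Hz bin and — crucially — nearly
constant across the cortex, so gradient estimates are unaffected. For
peaks much narrower than the smoothing bandwidth the flattened top becomes
a plateau and the argmax is pushed a full smoothing bandwidth upward, by
an amount that varies with local SNR; gradient estimates then inherit a
spurious spatial trend. The synthetic generator therefore uses
oscillations of realistic width (below), and analyses of real data with
this package should keep the smoothing half-bandwidth below the expected
peak width.

Band boundaries can also be derived from the data: `peak_histogram_bands()`
histograms all detected peaks (0.5 Hz bins, 3-bin moving average) and
places boundaries at local minima of the smoothed histogram.
`default_bands()` ships the classical set (theta 4-7.5, alpha 8.5-13, low
beta 15-25, high beta 27.5-34 Hz); one alternative reading puts the theta
lower edge at 3.5 Hz, a discrepancy we resolve in favour of the values
used for band-specific analyses.

## Surface geometry

Geodesic distance is shortest-path distance on the mesh edge graph with
Euclidean edge weights (Dijkstra via igraph) — the common parcel-scale
approximation, chosen over exact polyhedral geodesics because it admits an
exact brute-force oracle (dense Floyd-Warshall), against which the test
suite checks equality on random meshes. ROI centroids minimize the summed
within-parcel geodesic distance, ties broken by lowest vertex index for
determinism. The distance axis to a posterior reference parcel is computed
per hemisphere; cross-hemisphere distances are explicitly infinite, and
hemispheres are analysed jointly with hemisphere as a (nested) random
effect. Units are mm throughout; the "2-3 cm" annulus control is
`select_annulus(geom, 20, 30)` with closed bounds. `split_y_windows()`
cuts the centroid Y range into equal-width consecutive windows (half-open,
last closed).

## Mixed-effect gradient models

The central model (`fit_coordinate_gradient()`) regresses a response on
ROI centroid coordinates X, Y, Z and their two-way interactions XY, XZ,
YZ (fixed effects), with random intercept and X, Y, Z slopes by
participant and a random intercept for hemisphere nested in participant —
the smallest random structure consistent with "nested within participants
as well as within hemispheres"; hemisphere random slopes are deliberately
not included, and interactions get no random terms. Two numerical choices
matter:

* coordinates are centred at their ROI-wise means before interactions are
  formed (a flag disables this), which removes most of the
  main-effect/interaction collinearity;
* internally the model is fitted on coordinates divided by 50 mm and the
  estimates are rescaled to per-mm units afterwards. This is invisible in
  the output but essential: with raw mm coordinates the random-slope
  covariance optimization is so badly scaled that lme4 routinely reports
  spurious convergence failures.

Fixed-effect t values are estimate/SE; p values use residual degrees of
freedom (`n_obs - n_fixed`) by default, with Satterthwaite (lmerTest)
available via `df_method`. p values are two-sided and reported raw — no
multiple-testing correction, which the reader should keep in mind. A fit
that genuinely fails to converge is refitted without random slopes and
flagged `reduced` with a warning, never silently; a constant response
returns a flagged degenerate fit. Collinear fixed terms raise an error
naming the aliased terms. `predict_fixed_surface()` evaluates the fixed
part at every centroid, by default zeroing terms with p >= 0.05.

`residualize()` implements the nuisance-regression step (e.g. PFres after
removing 1/f offset and slope): the response is modelled on the
(within-participant standardized) covariates with random intercepts only,
and the fixed-effect prediction is subtracted. Residuals from a REML fit
with random intercepts have a grand mean only approximately zero, so the
residual scores are centred after subtraction; this makes the stated
zero-mean property exact and is harmless because every downstream model
has an intercept.

`fit_axis_gradient()` is the one-dimensional version used for the
geodesic-distance axis, the three Y windows and the 20-30 mm annulus
control; `fit_hierarchy_model()` regresses the standardized response on an
ordinal hierarchy vector (levels 1..7); `fit_network_model()` treats the
eight resting-state networks as a categorical factor, reports a Wald F for
the factor (computed from the fixed-effect covariance, residual df),
per-network cell means, and a sensory (VIS, AUD, SOM) versus association
contrast.

Robust descriptives follow the same philosophy: `skipped_pearson()` flags
bivariate outliers by the projection rule (spatial-median centre,
MAD-median cutoff `sqrt(chi2_{0.975,2})` on every data-point direction) and
correlates the rest; it matches the clean-subset Pearson to within 0.05
under 5% gross contamination and plain Pearson to within 0.01 on clean
data. Which exact variant of the projection rule the original toolbox
family uses is not documented precisely; acceptance here is by constructed
contamination, not bit-for-bit agreement. The per-participant consistency
summary (`individual_correlation_consistency()`) tests the raw r values
against zero by default; a Fisher-z flag exists.

## The synthetic cohort

`cohort_config()` holds the generative model; defaults define the
reference experiment, scaled down from a typical large MEG study
(hundreds of participants, hundreds of parcels) to a desk-scale cohort of
**20 participants x 96 ROIs (48 per hemisphere) x 300 s at 300 Hz** on a
2000-vertex two-sheet mesh:

* `true_pf[i,j] = 11 + u0_j + (-0.02 + uY_j) * (y_i + 75)` Hz, with
  `u0_j ~ N(0, 0.5^2)` Hz and `uY_j ~ N(0, 0.004^2)` Hz/mm — a 3 Hz
  population drop across the 150 mm Y span, with participant variability
  of realistic size (slope SD = 20% of the slope);
* aperiodic background `10^offset * f^slope` with offset
  `-1.0 + 0.002/mm` and slope `-1.2 + 0.001/mm` along Y plus per-ROI
  jitter (SD 0.03), so the 1/f parameters carry their own gradients;
* cortical thickness `2.0 + 0.004/mm` along Y (SD 0.08 mm), anticorrelated
  with PF by construction;
* the dominant oscillation is band-limited Gaussian noise with a Gaussian
  spectral profile (sigma = 1.5 Hz; about 3.5 Hz FWHM, typical of alpha),
  unit variance, amplitude 1.0; secondary theta (4.5 Hz + 0.005/mm) and
  beta (18 Hz + 0.04/mm) components at amplitude 0.35 increase in
  frequency toward anterior, and alpha dominates everywhere;
* each ROI emits 3 channels with loadings Uniform(0.5, 1.5) plus white
  vertex noise (SD 0.3); optional Gaussian-in-geodesic-distance leakage
  mixing is off by default.

Two generator choices deserve their rationale. First, oscillations are
band-limited noise, not sinusoids, so spectra show finite-width peaks as
real data do. Their default width is set *comparable to the analysis
smoothing bandwidth*: a much narrower oscillation would be smeared into a
+/-2 Hz plateau by the multitaper kernel, and the bin-resolution peak
estimator would then sit a full bandwidth above the true frequency by an
SNR-dependent amount (the estimator-bias mechanism described above) —
an unrealistic regime for cortical alpha, whose peaks are typically
2-4 Hz wide. Second, the theta component's frequency field stays below
about 5.5 Hz so that theta and alpha peaks remain separated by more than
the smoothing bandwidth everywhere on the cortex; components closer than
the spectral resolution are not resolvable by any estimator at these
settings and would only measure the smoothing kernel.

The 1/f background is synthesized by frequency-domain amplitude shaping of
white noise, giving direct control of the ground-truth offset and slope
(the shaped periodogram's log-log OLS slope over 3-45 Hz is within 0.05 of
the configured value — a suite invariant). Everything is deterministic
given the master seed: stage k uses child seed
`(seed mod 1000003) * 2049 + k`, participant j's recording uses stage
`1000 + j`, so single participants can be re-simulated in isolation and
streamed — `run_pipeline()` never holds more than one participant's raw
recording in memory.

`cohort_table_from_truth()` produces the feature-level cohort table
directly from the ground-truth fields, adding PF measurement noise
(default SD 0.35 Hz, emulating bin quantization plus detection jitter of
the spectral chain). It exists for statistical calibration experiments —
type-I error of the coordinate model over many null cohorts, estimator
consistency — where re-running the full signal chain for every replicate
would add nothing but hours; the signal chain itself is validated
separately by the end-to-end recovery experiment.

What the generator does *not* emulate: sensor-level physics (no forward
model, no beamforming), artefacts (no ECG/EOG, no movement), non-Gaussian
or non-stationary dynamics, spatially structured CT noise, and realistic
folded cortical geometry. Passing tests therefore demonstrate that the
*analysis chain* is correct and well calibrated under the stated
generative model, not that any particular real dataset satisfies that
model.

## Problem sizes used in validation

The validation experiments run at deliberately chosen sizes: the
end-to-end recovery experiment uses the full default cohort above (the
reference conditions); type-I calibration uses 40 null cohorts of 8
participants x 24 ROIs at feature level; peak-recovery uses 1000 random
synthetic spectra whose log-power noise (SD 0.015) matches the
variability of a pooled spectrum averaged over roughly a thousand
taper x epoch estimates, as the default chain produces; geodesic oracle
checks use twenty random meshes of up to 200 vertices, where dense
Floyd-Warshall is exact and fast.

## Known limitations

* Geodesics are graph shortest paths; on coarse meshes they overestimate
  true surface distance slightly and anisotropically.
* The aperiodic model has no knee; spectra with a clear low-frequency
  bend will bias the offset (the fit range's 3 Hz lower edge mitigates
  this).
* Peak frequencies are quantized to the 0.5 Hz grid, and the dominant-PF
  estimator carries the small upward bias discussed above; comparisons
  *across* space and groups are unaffected, absolute values should be
  read with a one-bin grain of salt.
* Residual-df p values are mildly anticonservative for small cohorts;
  Satterthwaite is available and recommended when participant counts are
  below ~10.
* The skipped-correlation outlier rule is one member of a family; on
  pathological point clouds different members flag different points.
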
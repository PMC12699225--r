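---
title: "Quantifying cerebrovascular function from awake-mouse optical imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebrovascular function from awake-mouse optical imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mesovasc)
```

mesovasc implements a quantification chain for longitudinal awake-mouse
cerebrovascular imaging: widefield optical imaging of neurovascular coupling
(whisker stimulation) and cerebrovascular reactivity (hypercapnia),
single-vessel diametry, two-photon amyloid pathology, and the cohort-level
mixed-model statistics that tie them together. This vignette explains the
models and procedures, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices made where the
underlying methodology left the design open.

## The measurement model

A widefield session interleaves three LED channels at 30 Hz (10 Hz each):
470 nm GCaMP6f fluorescence reporting neuronal calcium, 570 nm reflectance at
a haemoglobin isosbestic point tracking total haemoglobin ("OIS CBV"), and
620 nm deoxyhaemoglobin-weighted reflectance ("OIS BOLD"). All evoked metrics
are fractional changes against a pre-stimulus baseline, so gain factors
cancel:

$$\frac{\Delta F}{F_0}(t) = \frac{F(t) - F_0}{F_0}, \qquad
  F_0 = \text{per-pixel mean over the baseline window}.$$

`demux_channels()` splits the raw frame sequence by LED cycle position. A
trailing partial cycle is dropped rather than imputed — acquisition routinely
ends mid-cycle, and imputation would fabricate frames. Each channel keeps its
own acquisition timestamps; all downstream windows are expressed in seconds,
never frame indices, so the three channels never need resampling to a common
grid.

## Preprocessing

Three steps run before any quantification, in this order:

1. **Spatial binning** (`spatial_bin()`, factor 2 by default): block means;
   trailing rows/columns that do not fill a block are discarded, and the
   pixel size scales with the factor.
2. **Rigid registration** (`register_rigid()`): per-frame translation
   estimated by Fourier cross-correlation against the first frame, refined
   on an upsampled grid (default factor 20, i.e. 0.05 px resolution) by
   direct evaluation of the cross-correlation surface near its integer peak.
   Frames are resampled by the inverse shift with the Fourier shift theorem;
   because that wraps content at the edges, a 2-px border is replaced by
   replicating the nearest interior pixels. Shifts are estimated once on the
   570 nm channel — vessel contrast is strongest at the isosbestic point —
   and applied to all three channels via the `shifts` argument, since the
   channels are near-simultaneous. A constant (degenerate) reference yields
   a warning and zero shifts rather than garbage estimates.
3. **Illumination correction** (`intensity_correct()`): the mean time series
   of a skull/head-bar control region is regressed out of every pixel. The
   pixel's temporal mean is added back after the regression so that the
   baselines entering dF/F0 and dR/R0 denominators remain physically
   meaningful; removing the projection of the *centered* control trace makes
   the operation exactly idempotent. The raw control trace is used (no
   smoothing): low-pass filtering it would leave high-frequency source
   flicker in the data, and the regression is harmless if the trace is
   already smooth.

## Whisker-evoked neurovascular coupling

For each trial, F0 is the per-pixel mean over the 2 s preceding the onset,
and the epoch runs from onset to onset + 2 s stimulation + an 8-s response
window — long enough to capture the slower hemodynamic peak while fitting
inside the shortest (16 s) inter-stimulus interval. Trials are averaged;
pixels with non-positive baseline are flagged invalid and excluded from ROI
search.

The barrel ROI is the *top 100 connected pixels with the highest activation*:
greedy 8-connected growth seeded at the global maximum of the activation map
(per-pixel peak of the trial-averaged dF/F0 movie over the stimulus epoch),
repeatedly absorbing the highest-valued frontier pixel until the region holds
k = 100 pixels. The construction is deterministic; an alternative
threshold-then-component construction is available behind
`extract_barrel_roi(method = "threshold")` for sensitivity checks. The suite
verifies the greedy region against an independently implemented
priority-queue oracle.

Session metrics are the ROI-mean trial-averaged peak dF/F0 (GCaMP), the
analogous 620 nm peak dR/R0 (reported as-is: a reflectance rise is
BOLD-positive), and their ratio `peak_bold / peak_gcamp` — the per-session
neurovascular coupling index. Frames with registration shifts above 5 px can
be excluded from trial averages (`bad_frames`), a quantitative stand-in for
the qualitative motion-exclusion rule used during acquisition.

## Hypercapnic CO2 reactivity

The CO2 paradigm is 30 s baseline, 90 s of 10% CO2, 270 s recovery, repeated
twice. Within the manually drawn brain ROI, large surface vessels are removed
before tissue averaging (`remove_large_vessels()`): the mean 570 nm image is
divided by a heavy Gaussian blur of itself (sigma 20 binned px) to flatten
illumination, and two-class K-means on the flattened 1-D intensity separates
haemoglobin-dark vessel pixels from tissue. For one-dimensional data the
K-means optimum is a threshold partition, so the package computes the exact
optimum by scanning every split point — no random initialisation, fully
deterministic. Two degeneracy guards refuse the split (warning, nothing
removed): a simplified-silhouette floor of 0.1, and a minimum relative centre
separation of 5% — vessels at 570 nm are tens of per cent darker than tissue,
whereas splitting a single-mode histogram separates centres by only a few
noise SDs.

Tissue time series are per-frame means over the retained pixels; each
repeat's epoch is re-baselined to its own preceding 30-s baseline, the two
epochs are averaged at the epoch level (one peak per session, matching the
twice-repeated design), and the peak is the signed extremum of largest
magnitude within the 90-s stimulus window. The 570 nm trace is negated before
reporting so that a CBV (absorption) increase is positive in both channels;
the convention is recorded in the function documentation and the full trace
is returned for re-analysis.

## Single-vessel FWHM diametry

Vessel probes (centreline point, unit normal, half-length, artery/vein label)
are inputs — automatic centreline tracing is out of scope. Profiles are
sampled by bilinear interpolation at 0.25 pixel steps. `fwhm_diameter()`
then:

- lightly smooths the profile (moving average, width 3);
- takes the local baseline as the median of the outer 20% of samples at each
  end, so neighbouring vessels cannot bias the half level;
- estimates the extremum level as the mean over a ±2-sample window around
  the argmax — using the raw maximum would select the largest noise
  excursion and bias widths low on noisy profiles;
- places the half level at baseline + 0.5 × contrast and finds the two
  flanking crossings by linear interpolation.

Measurements fail cleanly (NA, vessel skipped) when the extremum sits at the
profile edge, fewer than two crossings bracket it, or the contrast is below
3 SDs of the outer samples. FWHM is exactly invariant to affine intensity
transforms. Polarity (dark at 570 nm) is configuration, never inferred.

Percent dilation is 100 × max over the stimulus window of |D(t) − D0| / D0
with the sign of the extremal deviation attached, where D0 is the mean over
the 30-s baseline. Diameters are measured per frame — required, since the
metric is a peak over time — and smoothed with a 3-frame moving average first
so a single-frame noise excursion cannot set the peak. Vessels with more than
20% failed frames in the baseline or stimulus window are excluded. For
*baseline* diameters, pooling the baseline window before measuring (FWHM of
the baseline-averaged frame) is the lower-variance estimator and is what the
recovery tests exercise.

The cohort median of arterial baseline diameters defines the small/large
split (`median_split()`); the median is an output of the data, never an
input, and ties at the median go to "large".

## Two-photon CAA and plaque quantification

Volumes carry methoxy-X04 (amyloid) and SR101 (vessel) channels at
2.207 um/pixel in-plane — 1130 um across 512 pixels — and 3-um z steps.
Preprocessing per slice: exact 3×3 median filter, Gaussian smoothing
(sigma 0.4 px), division by a heavy blur (sigma 50 px) of the z-mean image.
Depth attenuation is corrected by splitting the z-extent into Q equal-depth
bins (Q = 4, i.e. quartiles; configurable) and rescaling each bin's mean to
the shallowest bin.

CAA is defined on the maximum-intensity projection: per manually outlined
vessel, the threshold is the within-vessel mean + 1.5 SD of MIP methoxy
intensity, CAA pixels are strictly above it, and coverage pools all vessels
(100 × CAA pixels / outline pixels). Both thresholds in this module use
strict inequalities, consistently with the "greater than" plaque rule.
Plaque segmentation removes CAA from the volume (the MIP-derived CAA mask
extruded through z — CAA is defined only on the MIP), thresholds at strictly
above 0.6 × the volume maximum (computed per image, after preprocessing and
CAA removal), labels 26-connected components (6-connectivity by flag), and
keeps components strictly larger than 15 voxels. Volume is voxel count ×
voxel volume; session values are arithmetic means over the session's 2–4
images.

A note on small objects: the per-slice median and Gaussian filters erode the
z-caps of spheres smaller than about 4 voxels in radius, so sub-5% volume
recovery is only achievable for plaques of roughly 18 um diameter and above;
the generator's default plaque sizes (radii 4–5 voxels, ~18–22 um) reflect
typical real plaques and that resolution limit.

## Cohort statistics

`fit_lme()` fits REML linear mixed models with a random intercept per mouse
via nlme, reporting marginal (Type-III) F tests with the between-within
denominator-df convention; the convention travels with every fit object
(`glance()`), since ANOVA df conventions differ across software and the
choice is otherwise invisible. Designs with one observation per mouse make
the random intercept inestimable: the fit falls back to OLS with a warning
and says so in its metadata. An independent lme4 fit cross-checks the fixed
effects in the test suite.

The Johnson–Neyman region for a conditional slope in
$y = b_0 + b_1 x + b_2 m + b_3 x m + u_{\text{mouse}} + \varepsilon$ solves

$$\theta(m)^2 = t^2_{\mathrm{crit}} \, \widehat{\mathrm{Var}}\,\theta(m),
  \qquad \theta(m) = b_1 + b_3 m,$$

a quadratic in the moderator $m$, with $t_{\mathrm{crit}}$ at the fit's
fixed-effects residual df and two-sided alpha 0.05. Zero, one or two real
boundaries arise; the package reports each interval's significance by direct
evaluation, and the suite checks the closed-form roots against a dense
grid-search oracle to 1e-4.

Holm adjustment is `stats::p.adjust(method = "holm")` behind a validating
wrapper. `split_contrasts()` bins ages at 11 months, fits percent dilation on
the sex-by-age-bin group factor with a mouse random intercept per size class,
tests young-vs-old within each sex via emmeans, and Holm-adjusts the whole
contrast family together; empty cells are reported as missing rather than
silently dropped.

## The synthetic-data generator

No imaging data are deposited with the study this chain is designed for, so
`gen_widefield_session()`, `gen_vessel_frame_series()`,
`gen_twophoton_volume()` and `gen_cohort()` generate every input with known
ground truth; identical seeds give bit-identical outputs, and every
observable's truth is recorded alongside.

What they emulate: the trichromatic interleaved acquisition and its paradigms
(2-s whisker trains; 30/90/270-s CO2 blocks repeated twice); a
barrel-localised fast GCaMP response (gamma kernel peaking at 0.5 s) and a
slower hemodynamic response (1.5-s peak) — plausible kernels, explicitly not
claims about the underlying study; global CO2 plateaus positive at 620 nm and
negative at 570 nm; dark-vessel texture covering a configurable fraction of
the brain ROI; shared multiplicative illumination drift written into the
skull-control region as well; sub-pixel random-walk motion; vessel movies
with lognormal baseline diameters (median 54 um) dilating along the CO2
epoch; two-photon volumes with CAA bands of known pixel fraction, spherical
plaques of known voxel counts, and exponential depth decay; and longitudinal
cohorts of 8 mice per genotype-by-sex cell, ages 3–20 months, visit counts
drawn around 5.4 ± 3.1 with 1.52 ± 0.5-month intervals, outcomes from the
stated mixed model. The barrel response uses a flat-top (super-Gaussian)
spatial profile so the planted amplitude is exactly what a top-100 ROI mean
should recover; vessel cross-sections default to a PSF-blurred dark column
(2-px linear edge), with a Gaussian cross-section selectable. For a planted
Johnson–Neyman boundary, the diameter main effect is solved from the realized
design's covariance so the conditional slope loses significance exactly at
the requested age.

What they do not emulate: biophysical light transport, haemoglobin
spectroscopy or pathlength corrections, GCaMP hemodynamic crosstalk,
behavioural motion beyond rigid translation, vessel branching or curvature,
and longitudinal within-mouse pathology trajectories. Passing recovery tests
therefore demonstrates that the estimators are correct and calibrated under
the stated noise, drift and motion model — not that they are robust to every
artefact of real data.

Noise is parameterised as an amplitude-to-noise ratio: `snr` is the peak
fractional response amplitude divided by the per-pixel, per-frame fractional
noise SD (widefield), the vessel-contrast-to-noise ratio (vessel movies), or
the CAA-contrast-to-noise ratio (two-photon).

## Numerical choices and degenerate inputs

- Pixel grids are 0-based, row-major, pixel-centre coordinates everywhere.
- Binning discards trailing rows/columns; demultiplexing discards trailing
  partial cycles; both report what they dropped.
- Registration clips estimates at a configurable maximum (10 px) and wraps +
  replicates 2-px borders; interpolation is Fourier phase shifting, chosen
  because spline interpolation biases FWHM diametry near vessel edges.
- K-means on 1-D intensity is solved exactly (threshold scan), making vessel
  removal deterministic without a seed.
- Strict inequalities at both pathology thresholds; the 0.6× maximum is per
  image, after preprocessing and CAA removal.
- Flat or contrast-free profiles, empty ROIs/masks, all-zero volumes, empty
  p-value lists and missing contrast cells all return defined results or
  clean, named failures rather than propagating NaN.

## Problem sizes in the test suite

The suite runs everything at desk scale, chosen as the smallest sizes at
which each property is meaningfully exercised: widefield canvases of
32 × 44 to 64 × 86 px instead of the full 130 × 174 binned grid; hypercapnia
stacks at 0.1–1 Hz per channel instead of 10 Hz (windows are defined in
seconds, so frame rate is a free parameter); two-photon volumes of
16 × 96 × 96 to 24 × 110 × 110 voxels; 200 simulated cohorts for boundary
recovery; 1000 null cohorts for calibration; and 200 scaled-down end-to-end
pipeline runs (16 mice × 3 sessions each) for interaction-sign recovery.

## Known limitations

- FWHM diametry needs a few pixels across the vessel; at the binned
  widefield resolution (33.7 um/px) vessels under ~20 um are unreliable, and
  per-frame estimates on wide, shallow-edged (Gaussian-like) profiles carry
  noise that the baseline-averaging estimator avoids.
- The top-100-pixel ROI is an area-fixed, not activation-fixed, definition:
  weak sessions yield a valid ROI of weakly activated pixels.
- Vessel removal assumes a bimodal 570 nm intensity histogram within the
  brain ROI; sessions without resolvable surface vessels trip the degeneracy
  guard and keep all pixels.
- The pathology chain defines CAA on the MIP only; genuinely 3-D CAA
  geometry (wrapping deep vessel segments) is projected flat, and plaque
  volumes near the size cut are sensitive to the preprocessing filters (see
  above).
- Between-within denominator df are an approximation; Satterthwaite or
  Kenward–Roger df would differ in small, unbalanced designs. The convention
  is attached to every output so results are comparable.
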
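---
title: "Cardio-cerebral haemodynamics from gated cine phase-contrast MRI"
author: "cineflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardio-cerebral haemodynamics from gated cine phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineflow)
```

## The measurement problem

Cerebral arterial inflow and venous outflow pulse with every heartbeat.
Cardiac-gated cine phase-contrast MRI (PC-MRI) measures this directly: a
slice is placed perpendicular to a vessel, the through-plane blood velocity
is encoded in the image phase (a phase of $\pi$ corresponds to the
velocity-encoding limit, VENC), and acquisition is triggered by the ECG
R-wave so each frame samples a known position in the cardiac cycle (CC). In
the small-primate setting this package targets, one coronal slice crosses
the three arterial inflows — the basilar trunk (BT) and the right and left
internal carotids (RC, LC; VENC 50 cm/s) — and one oblique slice crosses the
two main venous outflows, the superior sagittal (SS) and straight (StS)
sinuses (VENC 20 cm/s).

From these images the pipeline computes, per subject: per-frame lumen area,
mean velocity and flow for each vessel; flow waveforms normalized to a
common 32-step cycle grid; waveform features (peak timing, dicrotic notch,
systolic upslope, pulsatility and resistive indices); per-cycle blood
volumes, perfusion and cerebral blood flow (CBF); and the arterio-venous
coupling quantities implied by the Monro–Kellie constraint (venous
correction factor, cyclic volume balance, oscillating volume, flow–flow
hysteresis loop). Group statistics compare young-adult (YA) and old-adult
(OA) cohorts with exact nonparametric tests.

No public raw data accompany the study population this emulates, so the
package ships a synthetic-cohort generator with known ground truth; every
downstream stage is tested against that truth.

## Processing model, stage by stage

### Lumen segmentation

The vessel lumen on each magnitude frame is segmented by thresholding at
**twice the background noise standard deviation**. `estimate_background_sd()`
returns the SD of magnitude in a background region (by default the four
10%-corner patches). Because magnitude noise is Rician — the generator adds
complex Gaussian noise before magnitude extraction — the background
magnitude is Rayleigh-distributed and its SD understates the channel noise
$\sigma$ by the factor $\sqrt{2-\pi/2}\approx0.655$. `segment_series()`
therefore converts the measured background SD to $\hat\sigma$ before
doubling it (`rician_correction = TRUE`). This matters: thresholding at
$2\times0.655\,\sigma$ would leave 42% of background voxels supra-threshold,
beyond the 8-connectivity percolation threshold, and the seeded mask would
flood the image.

The mask is the 8-connected supra-threshold component containing a
per-vessel seed voxel (the seed stands in for the operator who, in practice,
outlines each vessel). Two cleanup steps, both stand-ins for the manual
speckle editing of an interactive workflow, are applied by default
(`clean = TRUE`): a seeded 3×3 opening (erode; take the seed component of
the eroded core; dilate one step; clip to the supra-threshold set), which
removes the one-voxel-wide chains of background noise that otherwise attach
to the lumen, and removal of mask voxels dimmer than half the mask's median
magnitude, which removes isolated background voxels (reading ~2–4 noise SDs)
that slip in directly beside the lumen (at ~10 SDs). Without these, attached
noise voxels carry uniformly random phase — up to ±VENC in decoded velocity —
and dominate the per-frame flow error. A rasterized disk of radius ≳2.25
pixels passes through the cleanup essentially unchanged; near degenerate
radii (where a tip voxel lies two Chebyshev steps from the eroded core) up
to four low-velocity tip voxels can be shaved, a ≤1% effect on flow.

### Velocity decoding and flow

`decode_velocity()` applies the standard linear one-sided map
$v = \mathrm{VENC}\cdot\phi/\pi$ (cm/s, sign = direction). Per frame, the
vessel's mean velocity is the arithmetic mean over mask voxels (the mean
over the section, not the maximum voxel), and
$Q\;[\mu l/s] = \bar v\,[\mathrm{cm/s}] \times 10 \times A\,[\mathrm{mm^2}]$.
Voxels above 95% of VENC raise a near-aliasing flag; no unwrapping is
attempted (none is needed at these velocities). Frames where a vessel is not
detected propagate as missing samples, never silently dropped.

### Cycle normalization

Prospective gating covers only ~55–90% of the cycle, so each vessel's flow
samples are mapped onto the canonical grid of **32 steps of 3.125 %CC**
(step $k$ at $k\times3.125$ %CC; step 3 = 9.375 %CC, step 8 = 25 %CC,
step 32 = the next R-wave). Steps inside the sampled span are linear
interpolations. For the unsampled late-diastolic span two linear
extrapolation modes exist:

* `periodic` (default): interpolate between the last sample and the
  next-cycle R-wave sample. The waveform is periodic and acquisition starts
  exactly at the R-wave, so both endpoints are observed; the fill is bounded
  by data.
* `secant`: continue the terminal trend, with the slope fit by least squares
  over the last up-to-4 samples (`n_fit`), floored at 0 for sinuses and at
  the minimum observed flow for arteries.

The periodic default is a deliberate numerical choice. With 55–70% coverage
the trend extrapolation spans 30–45 %CC starting near the dicrotic notch;
even without noise it can err by tens of percent in volume and place the
profile maximum at step 32, and sample noise in the terminal slope is
amplified across the whole tail. Measured on calibrated cohorts, periodic
closure recovers 100% of per-vessel volumes within 15% (94.6% of peaks
within one step), against 94.6%/92.5% for the robustified secant.

### Waveform features

On 32-step profiles: peak M = argmax (ties to the earliest step); dicrotic
notch D = the step after the peak with the largest positive second
difference within (peak, 75 %CC] (the steep-to-slow slope break at
end-systole), reported absent when no positive second difference exists;
systolic upslope = (peak flow − flow at step 3) / elapsed time; PI =
(max − min)/mean and RI = (max − min)/max. Peak-arrival lags are differences
of peak %CC for ordered vessel pairs (BT→RC, BT→LC, BT→SS, LC→SS, StS→SS,
Art→Ven), computed per subject and then averaged — not differences of group
means. PI/RI are computed on normalized profiles, not raw frames.

### Volumes and arterio-venous coupling

Per-cycle volume is the step-rectangle sum
$V=\sum_k Q_k\,(RR/32)/1000\;[\mu l]$. Perfusion = total arterial
$V \times HR/1000$ (ml/min), drainage likewise from the sinuses, CBF =
perfusion per 100 g of brain tissue (GM+WM volume × 1.05 g/ml). The measured
venous outflow misses peripheral pathways, so the venous profile is scaled
by $CF = V_{art}/V_{ven}$ before balance analysis. The step-wise balance
$(Q^{art}_k - CF\,Q^{ven}_k)\,\Delta t$ alternates between surplus and
deficit; its running sum closes at zero at step 32 by construction of CF,
and the **oscillating volume** is the peak-to-peak range of that cumulative
curve (a maximum-positive-excursion variant is available) — the volume the
craniospinal system must buffer each cycle. The loop of
$(Q^{art}_k, Q^{ven}_k)$ points, closed 32→1, is the arterio-venous
hysteresis loop; its area (absolute shoelace area, self-intersections
flagged) indexes the phase lag and viscoelastic buffering. Vessel-wise
contribution percentages are computed per subject and summarized as means
of per-subject ratios (the ratio of group means is a different estimator
and is left to the caller).

### Group statistics

`compare_groups()` runs Mann–Whitney (unpaired) or Wilcoxon signed-rank
(paired) tests. For group sizes ≤ 10 the two-sided p is exact, enumerating
all relabellings/sign patterns on the observed data with mid-ranks under
ties (ties break the closed-form null, so the permutation distribution is
computed on the data at hand); larger groups use the normal approximation.
Fisher's exact test covers 2×2 associations; `bonferroni()` applies
$p_{adj}=\min(1, m\,p)$ with the family size $m$ declared explicitly.

## The synthetic cohort: what it emulates

`make_cohort()` draws YA/OA subjects around a calibration table of published
group statistics for the emulated population: heart rate 189 ± 58 (YA) vs
152 ± 42 (OA) bpm; per-vessel per-cycle volumes (BT 19.0 vs 30.3 µl, RC
13.2 vs 19.3, LC 15.5 vs 19.5, SS 6.2 vs 5.6, StS 6.8 vs 5.7); arterial
peaks placed so the composite arterial profile peaks at 31 %CC (step 10) in
YA and 25 %CC (step 8) in OA, with BT preceding the carotids; venous peaks
44.2/38.4 %CC (YA) vs 33.5/28.6 %CC (OA) with the published SDs (draws
bounded to the physiologic 12–65 %CC window); dicrotic notch at 53.1 %CC
(step 17); pulsatility-index targets (BT 1.48/1.51, RC 1.03/1.37, LC
1.29/1.65, sinuses ~0.35/0.5) solved into baseline levels; tissue volumes
and body weight per group; cycle coverage 0.79 ± 0.06 (YA) vs 0.70 ± 0.16
(OA), truncated to [0.55, 0.92]; frames every 15 ms (12–22 per cycle).

Two RR couplings are built into the per-subject draws because the published
dispersions demand them: per-cycle volume scales as $\sqrt{RR}$ with
correspondingly reduced residual lognormal jitter (the published perfusion
CV of 0.26 is far below the 0.39 implied by independent volume and HR
draws — stroke volume anti-correlates with rate), and systolic timing in
%CC scales as $\sqrt{RR_{group}/RR}$ (ejection time varies much less than
the RR interval; without this the upslope disperses with CV ≈ 0.66 where
the published group values imply ≈ 0.26). Group-mean parameters at the
group-mean heart rate are unchanged by either coupling.

The renderer draws each vessel as a filled disk with a parabolic
(Poiseuille) through-plane velocity profile, discretely rescaled so that
lumen-mean velocity × area equals the true flow at every frame time — the
noiseless acquisition is exactly invertible by design. Lumen caliber scales
with each subject's peak flow through fixed peak mean-velocity targets
(18 cm/s arteries, 5 cm/s sinuses, the scale reported for these vessels),
which keeps every subject inside the one-sided VENC — the emulated protocol
observed no aliasing, and `render_cine()` treats aliasing as an error — and
yields lumen cross-sections of ~13–45 voxels at 150 µm pixels, spanning the
published 13–31 mean counts. Velocity maps to phase as
$\phi=\pi v/\mathrm{VENC}$; complex Gaussian noise (default SD 0.5 against
a lumen amplitude of 10, i.e. SNR 20, a realistic figure for a 7 T
surface-coil protocol and one at which venous peak localization — flat
venous waveform tops — stays within the pipeline's stated tolerance) is
added to both channels before magnitude/phase extraction, making magnitude
noise Rician. An optional `area_pulse_fraction` modulates the lumen over
the cycle.

Waveform shapes are gamma-variate systolic pulses (plus a smaller
secondary bump whose onset creates the dicrotic slope break) for arteries,
and the same pulse circularly convolved with a causal exponential kernel,
shifted to the target peak, for sinuses. The functional form is the
package's own; it reproduces the morphology of published example waveforms
with few parameters.

**What passing tests do and do not show.** The generator emulates gating,
partial coverage, Rician noise, discretization and between-subject spread —
so recovery tests validate the pipeline's numerics end to end. It does not
emulate eddy-current phase offsets, gating jitter, vessel angulation,
partial-volume rims, motion, or manual ROI judgement; performance on real
data depends on those and is not certified by these tests.

## Numerical choices and degenerate inputs

* Noiseless frames have background SD 0; the segmentation threshold then
  falls back to a minimal positive floor so thresholding degenerates
  gracefully to "any signal".
* Constant profiles: the peak tie-breaks to step 1; the upslope is then
  undefined and flagged; PI = RI = 0.
* Profiles with < 3 valid samples refuse normalization; an all-missing
  vessel is an error, and skipped lag pairs are recorded.
* The cumulative balance closes at zero to 1e-9 relative tolerance; CF
  requires positive venous volume.
* Exact tests: two-sided p = min(1, 2·min(P≤, P≥)) with an 1e-9 comparison
  epsilon; Bonferroni never lowers a p-value.
* Simulation problem sizes used by the test-suite: unit tests render on a
  64×64 grid; end-to-end checks use 7+7 cohorts at the full 200×160 grid,
  and the group-contrast checks use 24 replicate cohorts — sizes chosen to
  exercise the full pipeline at the study's own scale.

## Known limitations

* The hysteresis-area young-vs-old contrast is weak under the published
  calibration (expected OA/YA ratio ≈ 1.25 against large between-subject
  spread); replicate cohorts concord with the published direction in only
  ~80–90% of draws, and single cohorts can reverse it.
* Published venous peak SDs are large (up to 15.6 %CC); venous peak
  localization at realistic SNR wanders ±1 step on flat tops, so ~5% of
  vessel series miss the one-step recovery tolerance at default noise.
* The per-frame threshold rule cannot distinguish a supra-threshold noise
  voxel adjacent to the lumen from lumen signal by intensity alone; the
  cleanup removes most but not all, leaving a small per-frame flow noise
  floor.
* Drainage (venous volume × HR) is reported as defined; published drainage
  figures for the emulated study are internally inconsistent with its
  per-cycle venous volumes (they match mean venous flow in µl/s instead),
  so no numerical agreement is attempted there, nor for published
  flow-range figures with the same unit inconsistency.
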
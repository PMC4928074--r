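---
title: "Methods: synthetic optical-mapping movies and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic optical-mapping movies and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomap)
```

cardiomap analyzes voltage- and calcium-sensitive fluorescence movies of
cardiac tissue slices, and ships a kinematic simulator that renders
synthetic movies with exactly known ground truth. This vignette documents
the models and algorithmic choices so that every measurement the package
reports can be traced back to a defined quantity.

## The kinematic tissue model

The simulator is *kinematic*: it does not integrate ionic or monodomain
equations. Instead, activation is scheduled by an event loop and waveforms
are painted onto the schedule. This trades biophysical realism for exact,
cheap ground truth — the right trade when the goal is validating an
analysis pipeline rather than studying mechanism.

A tissue is a pixel grid (`sim_grid()`) covered by one or more regions
(`region_spec()`), each with:

- an **effective refractory period (ERP)**, in ms;
- optionally an **intrinsic cycle length**, making the region automatic
  (pacemaker-like);
- a **waveform parameter set** (`waveform_params()`) controlling action
  potential shape and rate dependence.

Events (field or point stimuli from `sim_protocol()`, plus spontaneous
firings of automatic regions) are processed in chronological order. An
arriving excitation captures a region if and only if the time since that
region's last activation is **strictly greater** than its ERP. Under S1-S1
pacing at cycle length `PCL`, this rule makes the steady-state capture
ratio `floor(ERP / PCL) + 1`: a region with ERP 900 ms follows 1:1 at
1000 ms, 2:1 at 600 ms and 3:1 at 400 ms. Automatic regions start their
spontaneous clock at t = 0 (so they are refractory until their ERP) and
captured beats phase-reset the clock.

Within a captured region the wavefront propagates from its source at the
configured conduction velocity — a scalar speed, or an anisotropic
velocity ellipse `list(long =, trans =, fiber_angle_rad =)`. Travel times
are exact closed-form distances, so per-pixel scheduled activation times
are analytic ground truth (`truth_activation_times()`).

## Beat waveform and restitution

Durations follow a mono-exponential restitution relation in the diastolic
interval `DI` (time from the end of the previous beat to the next
activation):

```
D(DI) = apd_max_ms - restitution_amplitude_ms * exp(-DI / restitution_tau_ms)
```

The steady-state duration at a given PCL is the fixed point
`D = D(PCL - D)`, which the test suite solves numerically with `uniroot`
as an oracle independent of both renderer and mapping code.

Each beat is rendered as the product of two logistic sigmoids:

- an **upstroke** whose 10–90% rise time equals `upstroke_ms`, centered so
  the 50% crossing falls exactly at the scheduled activation time;
- a **phase-3 downstroke** of width `0.03 * D`, positioned so the
  20%-amplitude crossing falls exactly at activation + `D`.

Both calibrations matter. Activation is *defined* as the 50% upstroke
crossing and duration as the time to 80% repolarization (the 20% level),
so the template makes those observables exact by construction and the
whole pipeline can be held to sub-frame tolerances. The deliberately steep
downstroke keeps the waveform's residual tail negligible at short
diastolic intervals; a slow exponential repolarization shoulder was tried
first and rejected because its shallow slope at the 20% level turned
µ-scale baseline tilt left by conditioning into tens of ms of apparent
duration error.

Calcium-modality rendering shifts activation by `ca_delay_ms` and slows
the upstroke by a configurable factor (default 3), reflecting that
calcium transients trail and blur the voltage upstroke.

Artifacts (`artifact_params()`) are applied last: optional polarity
inversion, a linear drift ramp, and seeded Gaussian noise, on top of a
configurable diastolic level.

Default waveform numbers (`apd_max_ms = 380`, amplitude 140, tau 120,
upstroke 5 ms) are generic working-myocardium values. The nodal-like
parameter set used in examples (long ERP 900 ms, slow 80 ms upstroke,
long durations) encodes the qualitative signature of pacemaker tissue:
the specific numbers are chosen for clear feature separation, not
measured values.

## Signal conditioning

`condition_stack()` applies, in order:

1. **3×3 spatial averaging** (`spatial_bin()`), mask-aware and shrinking
   at borders, to raise SNR at the cost of spatial resolution.
2. **Zero-phase low-pass filtering** (`lowpass()`), a 4th-order
   Butterworth run forward-backward so activation times are not delayed.
   Records are odd-reflected at both ends and a linear baseline anchored
   at the padded endpoints is removed before filtering (and restored
   after); without this, the filter's zero initial conditions leave edge
   transients on any record that starts away from zero.
3. **First-order drift removal** (`remove_drift()`). The default fits the
   drift line on the *lowest 20% of samples only* (a diastolic
   approximation). A full-trace linear fit — the obvious choice — is
   systematically tilted by the action potentials themselves whenever the
   record does not contain a whole number of beats, and that tilt biases
   duration measurements; the diastolic-only fit does not.
4. **0–1 normalization** (`normalize01()`) per pixel.
5. **Polarity orientation** (`orient_polarity()`). Voltage dyes commonly
   report depolarization as *decreased* fluorescence, so traces may arrive
   inverted. When stimulus times are available the sign of the mean
   post-stimulus deflection decides (a captured stimulus always drives the
   signal away from diastole). This criterion was chosen over the
   simpler skewness heuristic because skewness fails at fast pacing: once
   the action potential occupies more than half the cycle, the skewness
   confidently points the wrong way. Skewness remains the fallback for
   stimulus-free recordings, with an explicit ambiguity warning and
   override when it is weak.

Tissue masks (`make_mask()`) threshold a per-pixel SNR: signal amplitude
is the 2nd–98th percentile range of the linearly detrended trace (about
4.1 sigma for pure noise, so noise-only pixels score near 1), and noise is
the robust `mad(diff)/sqrt(2)` estimator.

## Mapping and conduction velocity

`segment_beats()` finds upstrokes as groups of samples whose first
derivative exceeds half the record maximum, keeps them if the local rise
exceeds 30% of the record amplitude, and builds one window per beat from
the preceding diastolic minimum. Beats are tagged to stimuli within a
50 ms capture latency; untagged beats are spontaneous.

Per beat, `activation_time()` interpolates the first 50% upstroke
crossing, `duration80()` the first 20%-level downward crossing after the
peak, and `upstroke_metrics()` the 10–90% rise time — all linearly
interpolated between frames for sub-frame resolution, and all invariant
to affine intensity changes. `build_maps()` runs these per pixel.

Conduction velocity uses **local plane fitting**
(`local_velocity_field()`): at each pixel a plane is fitted to activation
times over a 5×5 window in mm coordinates; speed is the inverse gradient
magnitude (mm/ms = m/s) and direction the gradient direction. Pixels are
gated on fit quality (R² ≥ 0.8 by default), a maximum plausible speed, and
window coverage. `summary_cv()` reports a robust median/IQR (or mean/SD)
summary, optionally per labelled region, and `transverse_cv()` regresses
distance on activation time along a ray from a point-pacing site — set the
ray perpendicular to the fiber direction to measure transverse conduction
velocity.

## Pacing protocols

- `capture_ratio()` discards the pacing transient, matches activations to
  stimuli within a tolerance, and reads the steady ratio from inter-
  response intervals; non-integer locking is reported as `NA`.
- `estimate_erp()` brackets the ERP between the longest cycle length that
  lost 1:1 capture and the shortest that kept it; the bracket midpoint is
  accurate to half the protocol step.
- `build_restitution()` pools post-transient 80%-repolarization durations
  per cycle length, excluding (with a warning) any cycle length whose
  region-mean trace lost 1:1 capture.
- `detect_automaticity()` flags activations not attributable to stimuli
  and reports their rate when at least three are present.
- `classify_regions()` separates nodal-like from working pixels by
  2-means on standardized duration and rise time, deterministically
  seeded at the feature quartiles. Centroid separations below 2
  standardized units are treated as unimodal (2-means on pure noise
  yields about 1.6) and a single label is returned with a warning.

## Statistics

`summarize_group()`, `welch_t()` and `anova_tukey()` (one-way ANOVA with
Tukey HSD) cover the group comparisons typical of slice studies;
`welch_t_from_summary()` and `anova_tukey_from_summary()` (Tukey-Kramer
for unbalanced groups) accept printed summary statistics (n, mean,
SD/SEM) so published tables can be re-analyzed. `compare_restitution()`
runs an independent ANOVA + Tukey at every shared pacing cycle length.
`write_report()` writes deterministic, byte-reproducible CSV tables.

Degenerate inputs are handled explicitly: identical zero-variance groups
compare as t = 0, p = 1, and an exactly constant ANOVA response
short-circuits to F = 0, p = 1 (naive `aov` returns round-off noise
there).

## Problem sizes and limitations

The test suite validates on desk-scale grids (6–41 px across) with a
100×100 grid at 1000 fps for the full-resolution duration-recovery check;
all of it runs in well under a minute. Known limitations of the kinematic
model: no curvature- or rate-dependent conduction, no electrotonic
loading between regions, no motion (recordings are assumed mechanically
uncoupled), no fractional or decremental conduction — a stimulus either
captures a region or it does not, and within a region propagation always
succeeds. These are acceptable, and intended, for validating measurement
code against exact ground truth.
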
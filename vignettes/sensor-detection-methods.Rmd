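---
title: "Two-stage template matching for catheter sensor detection in videofluoroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage template matching for catheter sensor detection in videofluoroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorocath)
library(dplyr)
```

## The problem

Esophageal motility work-ups combine three synchronized modalities:
low-dose X-ray videofluoroscopy of the swallow, high-resolution manometry
(36 pressure sensors spaced 1 cm along a catheter), and intraluminal
impedance (15 channels measured between every second sensor starting from
the fourth). To display pressure and impedance *on* the X-ray image, every
catheter sensor must first be located in every frame — under varying
exposure, patient anatomy, a curving catheter, and a radiopaque bolus that
periodically hides whole stretches of sensors.

`fluorocath` implements a two-stage, template-matching detector for this
task, the projection step that paints synchronized physiological values
onto the detected sensors, a radius-tolerant evaluation suite, and a
synthetic fluoroscopy phantom so all of it can be exercised against exact
ground truth without clinical data.

## The detection model

**Stage 1 — catheter line.** Each preprocessed frame is scored with two
*triple-sensor* templates (a large and a small sensor size, for robustness
to exposure-dependent appearance) by normalized cross-correlation (NCC).
NCC is zero-mean and unit-variance, hence invariant to affine intensity
rescaling — the property that matters under per-patient windowing. The
per-pixel maximum over the templates forms a heatmap whose ridge follows
the catheter. The line is extracted row-wise: each row contributes its
top-scoring local maxima (at or above `score_floor`, default 0.3 NCC), and
a dynamic program selects the best chain under a slope constraint
(`max_slope`, default 3 px/row — the catheter is assumed mostly vertical;
strongly horizontal catheters are out of scope). Chain candidates
contribute their score margin above the floor; lateral movement beyond a
plausible catheter drift (0.3 px/row) is penalized so that short, isolated
response islands — the rim of a bolus is the canonical offender — cannot
drag the line. Evidence-free gaps up to `gap_max` are bridged linearly and
the line is extended to the full frame height with the end slopes, because
the tall triple template cannot anchor near the border while sensors still
sit there.

**Temporal error correction.** The accepted lines of the previous three
frames are kept; if the current line deviates too far from their per-row
average, or extraction failed outright, the history average replaces it,
and the window slides. "Too far" is the largest 25-row moving average of
the per-row column deviation exceeding `dev_thresh_px` (default 25 px):
the characteristic failure is a *localized* excursion — a stretch of line
captured by the near-vertical tangent of a bolus rim — which a whole-line
mean would dilute below any usable threshold, while a windowed mean
exposes it and is still insensitive to single-row jitter; a frame-wide
displacement trips the same test. This is deliberately a whole-line rule
operating at the line stage only; sensor positions are *not* smoothed
across frames.

**Stage 2 — sensor localization.** A second heatmap from two
*single-sensor* templates is sampled along the accepted line at 1-px arc
steps. Profile peaks (score at least `peak_floor`, default 0.25) are
selected under a minimum mutual separation of 0.6 sensor spacings — the
selection maximizes total peak score under that constraint
(weighted-interval dynamic programming), which is provably at least as good
as score-descending suppression and matches an exhaustive-search oracle in
the tests. Peaks are then snapped to a regular grid: the local spacing is
the median inter-peak gap clipped to ±20% of the nominal spacing, interior
grid slots without a peak receive an **inferred** sensor at the
interpolated arc position (this is how occluded sensors are recovered), and
slots beyond the outermost peaks are only kept while the profile lends weak
support (`extend_floor`, default 0.15). Sensors are numbered consecutively
from the visible catheter end — index 1 at the top, or 36 at the bottom
counting backward — which is a dataset-level configuration, not something
the detector guesses: the anchor sensor is the only reference for the
numbering.

## Preprocessing

Frames pass through a fixed recipe: automatic cropping of uniform
gray/black borders (a margin row/column is uniform when its intensity
range is within `border_tol`, default 2 units on the 8-bit scale), Gaussian
blur (`blur_sigma`, default 1.5 px), then CLAHE (clip limit 2, 8×8 tiles).
The order is fixed — denoise first, then local contrast enhancement — and
all parameters are config-overridable since the optimal values are
acquisition-dependent. Constant images are passed through unchanged
because histogram equalization is undefined at zero dynamic range.

## The fusion step

Frames and physiology share a time origin; the sample projected on a frame
is the nearest one (`round(t × 50 Hz)`) — at 50 Hz versus at most 15 fps
the synchronization error is below 10 ms, so no temporal interpolation is
applied. Pressures color a ribbon along the catheter through a monotone
blue→green→yellow→red ramp (default display range −10..150 mmHg, clamped,
never dropped); values between sensors are linearly interpolated in arc
length so the ribbon is continuous, and the color at each sensor center is
exactly the mapped sensor value. Impedance (default 50..2000 Ω, log-scaled
because impedance spans orders of magnitude) is drawn at a lateral offset,
spanning the midpoints of each channel's sensor pair: channel *k* spans
sensors (2 + 2k, 4 + 2k), the reading under which 15 span-two intervals
exactly tile sensors 4–34. Inferred sensors are rendered exactly like
detected ones — that is the point of inferring them.

## The phantom

The generator emulates the acquisition geometry: 1024×1024 frames at
8–15 fps (the package defaults to 512×512 with geometry scaled
proportionally, which keeps test runs fast; full scale is one argument
away), ~38 px sensor spacing and 27×12 px sensors at full scale, around 25
visible sensors per frame at the default size, sequences of 40–180 frames.
The catheter is a low-order smooth bend — a half-period harmonic plus a
mild full-period one, phases drawn once per dataset seed — whose lateral
excursion is bounded by `curve_amplitude_px` and whose local inclination
stays under about 20°, matching the near-vertical courses seen clinically;
a slow sinusoidal whole-curve drift (4 px amplitude, 20-frame period)
bounds frame-to-frame displacement near 1.3 px. Sensors are dark,
soft-edged bars oriented along the local tangent at arc-length multiples
of the spacing. The optional bolus is a radiopaque blob whose hard core
saturates the image — a sensor wholly inside it is flagged `occluded` in
the ground truth (a rim sensor is still partly visible and is not). The
four named noise levels add zero-mean Gaussian noise with σ = 0, 10, 25,
50 on the 8-bit scale; the levels are named rather than physical because
low-dose X-ray noise is acquisition-specific. Physiology is a propagating
peristaltic wave: per-channel Gaussian pressure pulses whose peak times
increase strictly from channel 1 to 36, and impedance drops co-propagating
at each channel's sensor-pair midpoint.

What the phantom does *not* model: beam hardening, scatter, anatomy,
motion blur, or real bolus shapes. Passing tests on the phantom therefore
demonstrates the pipeline's geometric and algorithmic correctness — line
tracking, numbering, occlusion inference, fusion, metrics — not clinical
detection rates; the published clinical figures were measured on patient
data this package does not ship.

## Evaluation methodology

Detections (inferred ones included — they are scored like any other) are
matched one-to-one to ground truth within a radius: 5 px ("exact"), 10 px
("good"), 30 px ("acceptable"). Matching processes candidate pairs in
increasing-distance order and then completes the pairing to maximum
cardinality with augmenting paths, so the TP count equals the optimal
bipartite matching — verified against a brute-force oracle on small
instances. Precision/recall/F1 are aggregated per sequence and then
averaged across sequences with their standard deviation, the per-patient
reporting convention. The noise study re-runs the full pipeline per noise
level on noise added *after* rendering, emulating noise added to acquired
images. Per-sensor-index distance distributions localize where along the
catheter errors concentrate.

## Numerical choices and degenerate inputs

* NCC windows with near-zero variance score 0; anchors where a template
  does not fit carry the sentinel −1. Templates have odd dimensions so the
  anchor is a pixel.
* All bank templates are rank-1 patterns (an outer product of 1-D bar
  profiles), so matching uses a separable NCC (two 1-D correlations plus
  summed-area tables) in compiled code; it agrees with the generic
  pixel-template NCC to 1e-6 and is what makes full-sequence runs cheap.
* `gap_max` defaults to 12 sensor spacings in `detect_config()`: a bolus
  can blank several spacings of line evidence *plus* the rows where the
  tall triple template cannot anchor, and the bridge must cover all of it.
* Peak plateaus collapse to their center sample; `detect_peaks` with fewer
  than 3 supporting peaks marks the frame's numbering low-confidence but
  still emits sensors.
* Coordinates are 1-based (row, col) as everywhere in R. The one 0-based
  quantity is `sync_sample_index()`, which returns elapsed samples since
  the shared time origin.
* Problem sizes used by the test-suite benchmarks: five 512×512 sequences
  of 40 frames for the clean study, one 20-frame sequence per noise level,
  and one 20-frame bolus sequence; unit tests use a compact 256×256
  geometry.

## Known limitations

* Strongly horizontal or self-crossing catheters are out of scope (the
  row-wise extraction assumes one catheter column per row).
* Numbering depends on the configured visible end; a frame where the
  anchor-end sensor itself is invisible can shift all indices by one —
  positions remain correct, labels may not.
* No sub-pixel refinement of sensor centers, and no temporal smoothing of
  sensor positions (only the line is corrected temporally).
* The phantom's realism limits are listed above; clinical performance
  claims require clinical data.

## A worked run

```{r, eval = FALSE}
spec <- phantom_spec(seed = 1)                  # 512x512, 40 frames
ds <- generate_dataset(spec)
res <- detect_sequence(ds$frames, detect_config(spec))
report <- evaluate_detections(res$detections, ds$truth)
tidy(report)
autoplot(report)

st <- noise_study(phantom_spec(seed = 1, n_frames = 20))
autoplot(st)
```
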
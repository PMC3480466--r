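---
title: "Posture-based sleep monitoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture-based sleep monitoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnacc)
```

## The measurement model

A static accelerometer axis reads the projection of the gravity vector
(1 g = 9.81 m/s²) onto that axis, plus the dynamic acceleration of body
movement, plus sensor noise. With a triaxial sensor on the sternum and a
single antero-posterior axis on the right thigh, posture is encoded in the
gravity projections:

* upright (standing/walking): gravity loads the sternum **vertical** axis
  (|reading| ≈ 1 g), the thigh axis is roughly horizontal (≈ 0 g);
* sitting: the torso stays upright but the thigh rotates, so the thigh
  axis loads heavily (≈ 1 g);
* lying: the vertical axis unloads (≈ 0 g) and gravity moves into the
  sternum antero-posterior / medio-lateral plane. The direction of that
  planar projection is the torso's rotation about the longitudinal body
  axis — the *sleeping posture*: 0° ventral, +90° right side, 180°
  dorsal, −90° left side.

`somnacc` never band-pass filters. Gravity and movement are separated in
the time domain: over 5-s windows the per-channel **median** is robust to
movement transients and estimates gravity, while the **activity**

$$ a = \frac{1}{n}\sum_{i=1}^{n} \left\| x_i - m \right\|_2 $$

(the mean magnitude of the median-subtracted four-channel sample vectors)
quantifies movement. The activity is computed on median-subtracted values:
on raw values a resting sensor would read ≈ 1 g of "activity", which is
incompatible with the ~0.004 g average nightly activity that real supine
recordings show. Activity is offset-invariant (adding a constant to a
channel shifts its median identically) and scales linearly with dynamic
amplitude; both are property-tested.

## Tunable parameters

All decision constants live in a single `default_thresholds()` object:

| parameter | default | unit | role |
|---|---|---|---|
| `vertical_g` | 0.66 | g | lying split: `|median_v| <` threshold |
| `thigh_g` | 0.5 | g | sitting split: `|median_thigh| >` threshold |
| `angle_change_deg` | 30 | ° | adaptive segmentation boundary |
| `supine_min_s` | 50 | s | minimal lying run for a supine episode (ten windows) |
| `sleep_activity_g` | 0.15 | g | stillness threshold for sleep |
| `still_min_min` | 3 | min | sustained quiet defining sleep onset |
| `long_posture_min` | 15 | min | "long posture" duration |
| `night_start`/`night_end` | 20:00 / 10:00 | clock | analysis window (spans midnight) |
| `max_rise_min` | 30 | min | a longer non-lying gap ends the in-bed bout |
| `vertical_sign` | 0 | — | 0 = magnitude rule; ±1 pins a signed axis convention |

The 0.66 g constant corresponds to a torso tilt of ≈ 49° from upright
(cos⁻¹ 0.66); the often-quoted "40°" description corresponds to ≈ 0.77 g
and is **not** the operative constant — the printed decision value 0.66 g
is. Both split constants can be refit from labeled calibration data with
`fit_thresholds()` (exhaustive midpoint search per split, 10-fold
cross-validated, ties broken toward the widest inter-point gap).

All activity/duration comparisons are strict (`<` for stillness and lying,
`>` for sitting), so boundary values fall to the wake/upright side; the
boundary behaviour is pinned by tests.

## The adaptive segmentation, and one deliberate design deviation

Within a supine episode, each 5-s window yields one rotation angle
(`atan2` of the planar gravity medians; windows with planar magnitude
≤ 0.2 g are flagged ill-conditioned and carry the previous valid angle
forward). The segmenter maintains the **running circular mean of the
current segment** and closes the segment when the incoming window deviates
from it by more than 30°. Two consequences:

* slow wobble around a fixed category border (e.g. oscillating 40° ± 20°
  across the 45° ventral/right line) stays **one** segment, whereas a
  fixed-threshold labeler would flip labels dozens of times;
* the detector is invariant under rigid rotation of the whole trace
  (sensor mounting twist), property-tested for shifts < 15°.

A stated alternative was to cap the mean at the *last 5 s* of history.
At one angle per 5-s window that cap leaves a single-sample memory, and a
40° turn whose 5-s transition window lands half-way (two consecutive
≈ 20° steps) would be missed entirely — no 40°-or-larger turn spanning a
transition window is then detectable, which defeats the turn-count
indices. The segment-anchored mean was chosen instead; `mean_window_s`
survives as the warm-up/stub granularity. Relatedly, a large (> 60°) turn
makes its own transition window deviate > 30° from *both* flanking
postures, producing a one-window stub segment; stubs no longer than one
window are merged into the following segment so that one physical turn
yields exactly one boundary (`min_segment_s = 0` disables this). The
streaming implementation is verified window-for-window against an offline
brute-force re-implementation of the same rule on hundreds of random
traces.

Category boundaries are half-open (ventral |angle| < 45°, right
[45°, 135°), left (−135°, −45°], dorsal beyond ±135°) so the four labels
exactly partition the circle; the published dorsal range "−135° to +135°"
overlaps every other category and was read as its complement, the only
partition-consistent interpretation.

## Index definitions and open choices

* **Supine episodes / in-bed span.** Lying runs ≥ 50 s are episodes; the
  span runs from the first to the last episode of the principal bout.
  Interior sitting/standing is interruption, not supine time; lying runs
  shorter than 50 s inside the span still count toward *time supine*
  (span minus sitting/standing), but are not segmented. Episodes separated
  by more than `max_rise_min` of non-lying time are split into bouts and
  the bout with the most lying time is analyzed — this operationalizes
  "getting up for the day" without clock heuristics.
* **Sleep efficiency.** The numerator is supine time minus turning time
  (one window per segment boundary plus adjacent contiguous active lying
  windows). The denominator is genuinely ambiguous in the literature:
  relative to the in-bed span or to time supine. Both are computed;
  `sleep_efficiency` (primary) uses the span — a published mean of 0.70
  implies a denominator that exceeds quiet supine time — and
  `sleep_efficiency_supine` carries the variant.
* **Rates.** Every per-hour rate divides by time supine; when time supine
  is zero the rates are `NA`, never 0.
* **Still-position latency** is a *proxy* for sleep-onset latency: time
  from supine onset to the first ≥ 3 min of sustained stillness. When no
  such run exists the latency equals the supine duration and is flagged
  (`sleep_onset_found = FALSE`).
* The 0.15 g stillness constant is treated as fixed; the original
  averaging unit behind it is unstated.

## What the synthetic generator emulates — and what it does not

`simulate_night()` renders a scripted night: gravity projections per
scheduled posture, constant-rate (slerp) 5-s transitions, Gaussian sensor
noise, a 0.25 g oscillatory "restless" component during the latency
period, and Poisson-timed 0.4 g movement bursts on whole windows during
quiet sleep. Defaults were fixed once from the published scales: noise SD
0.002 g puts quiet-window activity near 0.004 g; random nights draw noise
up to 0.05 g; burst and latency amplitudes sit clearly above the 0.15 g
threshold, quiet windows clearly below it. Random scenarios place turns
≥ 5 min apart on different quarter-turn categories (≥ 60° turns), draw
posture durations of 5–40 min excluding exactly 15 min (so the
">15 min" count cannot flip on a one-window boundary shift), and keep
rises away from turns, the latency tail and the 60-min first-hour
boundary. Ground-truth indices are computed *analytically* from the
scenario (plus the realized burst windows), not by running the pipeline.

The generator does **not** emulate: respiration/tremor/ECG artifacts,
gradual sensor drift or re-mounting shifts, non-lying sleep, co-sleepers,
or the soft tissue dynamics of real turns. A green recovery test
therefore establishes that the pipeline implements its own definitions
exactly and degrades gracefully under Gaussian noise up to 0.05 g — not
that it reproduces any population statistic of real nights.

## Numerical choices

* Windows tile the recording (step = window) by default; the trailing
  partial window is dropped, never padded (padding would bias medians).
  Window count is `floor((N − window)/step) + 1`.
* Circular means use unit-vector sums; a resultant below 1e-12 (antipodal
  cancellation) is an error rather than an arbitrary answer. Angles are
  reported in (−180°, 180°] with circular differences in the same range.
* Even-length window medians average the two central order statistics
  (matching R's `median`); the compiled kernel is tested against R
  per-sample computation at 1e-12.
* Timestamps follow the grid `start_time + i/rate` with half-open
  `[start, end)` windows; storage is plain CSV with `#`-metadata headers,
  values in g (an explicit `units=ms2` header converts on read — readers
  never rescale silently). EDF input is not available in this build.
* All randomness (calibration fold shuffles, simulations) flows through a
  single seed and restores the caller's RNG state.

## Known limitations

Posture and stillness are necessary, not sufficient, evidence of sleep:
a motionless reader is indistinguishable from a sleeper, sleep stages are
out of reach, and bed cannot be told from couch. Walking and standing are
deliberately not distinguished. Calibration quality bounds classification
quality: the tree's two constants assume sensors mounted as described,
and a grossly tilted mounting violates the magnitude rule's geometry even
though small twists are absorbed by the adaptive segmentation.
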
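---
title: "Evaluating detection reliability in multi-camera drone surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating detection reliability in multi-camera drone surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droneval)
```

## The evaluation model

The pipeline scores how reliably an automated detector reproduces manually
annotated ground truth in frame-synchronised video from several camera
treatments flown on one drone. The unit of analysis is a *flight x
treatment* pair; its primary data are three integers obtained by matching
boxes frame by frame:

* **TP** — model boxes assigned one-to-one to a ground-truth box with
  intersection-over-union (IoU) at or above a threshold (default 0.5);
* **FN** — ground-truth boxes left unassigned;
* **FP** — model boxes left unassigned, under one of two conventions
  discussed below.

From the counts, `compute_metrics()` reports percentages
`precision = 100 TP/(TP+FP)`, `recall = 100 TP/(TP+FN)` and
`f1 = 100 TP/(TP+0.5(FP+FN))`. F1 is always computed from the counts, never
from rounded precision and recall: the two routes disagree in the last
printed decimal for several rows of the reference table, and the counts are
the primary data. Treatment-level summaries are unweighted means over
flights (sd with the n−1 denominator); per-flight metrics with a zero
denominator are reported as `NA` and excluded from means rather than forced
to 0 or 100.

Key assumptions inherited from the field procedure:

* Ground truth is the smallest axis-aligned rectangle enclosing the animal;
  every individual is tracked and boxed separately, so one-to-one matching
  is the correct counting rule even for overlapping animals.
* Evaluation is frame-wise only. No track-level credit is given or needed;
  identity is used solely to validate the ground truth.
* All streams are on a common frame timeline before matching (below), and
  both streams are restricted to the same frame range and to the central
  region of the frame, where lens vignetting and the filters' angular phase
  shift are negligible.

## Matching rules and their edge cases

**Assignment.** Candidate pairs are those with IoU ≥ threshold. The default
`"greedy"` mode sorts candidates by descending IoU (ties broken by ground-
truth index, then model index — results are identical across platforms and
runs) and accepts pairs whose endpoints are unused. The `"optimal"` mode
computes the exact maximum-cardinality one-to-one assignment, breaking
cardinality ties by maximum total IoU, with a bitmask dynamic program over
the smaller side of the frame (exact up to 25 boxes on that side; a frame
with more raises an error rather than silently approximating). Greedy can
in principle be one match short of optimal; the test suite verifies
equality on an enumerated grid of small configurations and `TP(greedy) ≤
TP(optimal)` everywhere.

**False positives.** The reference analysis *defines* an FP as a model box
that "did not overlap" any ground-truth box. Read literally, a model box
with overlap 0 < IoU < 0.5 is neither a TP nor an FP. `fp_mode =
"no_overlap"` (default) implements that literal reading and reports such
boxes as `discarded`; `fp_mode = "strict"` is the usual COCO-style
convention where every unmatched model box is an FP. The literal reading
inflates precision, which is why both are implemented and the choice is
explicit in every report manifest. Both conventions satisfy
`TP + FN = #ground truth`; only strict mode satisfies `TP + FP = #model`.

**Degenerate inputs.** Empty frames, empty streams and disjoint clip ranges
are all defined results (zero counts, empty sets), not errors. A genuine
contract violation — mismatched frame ranges, boxes outside the frame,
negative extents — raises a classed validation error.

## Synchronisation

Cameras are frame-locked at 30 fps but may start a few frames apart. Short-
lived events visible to all sensors (surfacing moments) anchor the streams:
for each camera the offset is the median over anchors of the per-event
frame difference to the reference camera, rounded half away from zero. The
median tolerates a single misidentified event; the per-event residuals
(difference minus offset) expose it. Verification passes when the largest
offset is within tolerance (default 1 frame, the agreement the three-camera
rig was verified to hold) *and* all residuals are zero. Correction
(shifting each stream by its estimated offset) is explicit and optional in
the pipeline config, since the original analysis only verified agreement;
sub-frame offsets are out of scope because acquisition is frame-locked.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `iou_threshold` | 0.5 | – | operating point used by the reference analysis; chosen off the IoU histogram, between its two modes |
| `fp_mode` | `"no_overlap"` | – | the literal published FP definition (see above) |
| `central_fraction` | 0.8 | – | the source analysis keeps "the middle area of the frame" without quantifying it; 0.8 per dimension removes the outer 10% band on every side |
| `max_extension` | 60 | frames | annotators keep boxing "for a number of frames" after an animal dives; 60 frames = 2 s at 30 fps |
| sync `tolerance` | 1 | frames | the rig's verified agreement |
| `bin_width` | 0.02 | IoU | fine enough to localise the ~0.74 mode without empty-bin noise at typical match counts |
| `prominence_floor` | 0.25 | – | a local maximum must reach a quarter of the tallest bin to count as a peak, suppressing counting noise |

Neither `central_fraction` nor `max_extension` has a published numeric
value; both are package defaults, exposed and recorded in every manifest.

## What the simulator emulates — and what it does not

`simulate_flight()` generates the statistical structure the evaluation
assumes, not images:

* **Dive cycles.** Depth is 0 for `surface_duration` frames, then half a
  sine up to `max_depth` over `dive_duration` frames — continuous, zero at
  every surfacing, giving clean surfacing anchors and the repeated
  surface-and-dive pattern that makes dolphins useful for this comparison.
* **Availability.** A box at depth *d* is detected with probability
  `plogis((d50 − d)/slope) · light_fraction^γ`. The logistic is the
  standard smooth two-parameter availability curve; `d50` (metres) is the
  depth of 50% detectability and `slope` its scale. `light_fraction`
  carries the filter physics: 1 for unfiltered RGB, 0.12 for a 25 nm
  bandpass on a broadband sensor (an order-of-magnitude in-band fraction,
  not a measured value), and 0.06 for bandpass + polariser, since a
  polariser passes roughly half the light. γ = 0.5 softens the penalty
  (detectors degrade sublinearly with signal). The default preset orders
  `d50` 4 / 2.5 / 1.5 m so RGB > green > green+polariser, the ordinal
  finding being reproduced; the specific depths are illustrative and only
  ordinal claims are tested against them.
* **Localisation noise.** Detected boxes get independent Gaussian jitter on
  each corner. The preset sd (3.943 px for a 60×25 px animal) was
  calibrated once by `calibrate_jitter_sd()` so the *mode* of the IoU
  distribution between true and jittered boxes sits at 0.74, where the
  reference IoU distributions peak. The IoU distribution is left-skewed
  (bounded by 1), so calibrating the mean instead would push the histogram
  peak to ~0.79; the mode is the statistic the observation is about. The
  calibration seed, draw count and result are frozen in the preset file.
* **Grouped animals.** When two truly overlapping boxes are both detected,
  they are merged into one union box with probability `merge_prob`. A
  merged box overlaps each ground-truth box at IoU ≈ 0.35 for animals one
  body-length apart, which is what produces the secondary low-IoU histogram
  mode reported for flights with closely swimming dolphins. The
  `overlap_preset()` uses `merge_prob = 0.25` so that this mode stays
  *secondary*, as observed; at much higher values it would dominate.
* **Clutter.** Poisson false positives per frame (default preset 0.01/frame,
  matching the near-zero FP columns of most reference flights), uniform
  over the *full* frame so the central-region filter has work to do.
* **Sub-seeds.** Each treatment's noise stream uses a fixed offset from the
  master seed: treatments are conditionally independent given the shared
  truth, like three physically separate sensors, and every run is
  bit-reproducible. Detection uniforms and jitter draws are laid out so
  that raising `d50` under a fixed seed only ever adds detections, making
  recall provably monotone in `d50` (a property test).

Not emulated: pixel content, water optics, glare, vignetting's spatial
profile, detector confidence structure (confidences are uniform on
[0.5, 1]), and animal size change with depth. A green test on synthetic
data therefore establishes that the *pipeline arithmetic and its
invariants* are correct under the stated statistical structure — not that
any real sensor ranking holds; the real ranking enters only through the
packaged reference counts.

## Numerical and design choices

* Frame indices are 0-based; ranges are inclusive at both ends (published
  per-flight frame totals are simple counts).
* Coordinates are continuous throughout, so interpolation never rounds;
  per-coordinate linear interpolation is the simplest scheme consistent
  with the short gaps it fills, and convexity guarantees interpolated boxes
  satisfy the box invariants whenever the endpoints do.
* Display rounding is one decimal, half away from zero (the reference
  table's apparent convention); unrounded values are retained internally
  and used for all aggregation.
* The published table's own F1 cells disagree with their counts in five
  places (last-decimal level except one 0.8 discrepancy); the package
  treats the counts as primary, flags the disagreements in
  `check_reference_counts()`, and makes no claim about the published "±"
  dispersion values, which match neither the sd nor the standard error of
  the per-flight F1s.
* Configs and presets are JSON (`jsonlite`); no YAML parser is assumed.

## Limitations

* The optimal matcher is exact only up to 25 boxes on the smaller side of a
  frame — far beyond any dolphin group here, but not suitable for dense
  detection benchmarks.
* `fit_detectability()` assumes `light_fraction = 1`; with a light penalty
  the plateau below 1 is absorbed into the logistic parameters and `d50` is
  biased.
* The sync estimator needs every anchor to include the reference camera and
  at least two cameras; it estimates integer offsets only.
* Confidence scores are carried but unused: no PR curves or average
  precision, since the evaluation is a single operating point by design.
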
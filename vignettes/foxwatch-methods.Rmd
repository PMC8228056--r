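---
title: "From bounding boxes to activity budgets: the foxwatch methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bounding boxes to activity budgets: the foxwatch methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxwatch)
```

## The problem

A single captive animal — the motivating case is a silver fox in a
318 cm × 140 cm cage with an elevated platform — is filmed around the clock
by two fixed cameras. An object detector reduces every video frame to at
most one bounding box: the normalized center coordinates `(cx, cy)`, the
box width and height, and a detection confidence; frames where the animal
is hidden (hut, blind spot) yield nothing. foxwatch takes it from there:
it turns these per-frame detections into movement time series, merges the
two cameras, classifies every second into an activity level, and
summarizes residence locations and activity budgets. Everything upstream
of the detections — video decoding, network training, inference — is out
of scope on purpose; the package also provides the standard
detector-evaluation metrics so a trained detector can be audited with the
same annotation files it was trained on.

## The movement signal

The activity signal is the displacement of the bounding-box center between
consecutive frames,

$$ m_{f,f+1} = \sqrt{(x_{f+1}-x_f)^2 + (y_{f+1}-y_f)^2}, $$

in normalized image units (so the largest conceivable value is
$\sqrt{2}$). Three aggregation stages follow:

1. **Per second** (`per_second_series()`): the mean of the non-missing
   frame-pair norms whose leading frame falls in that second. At 5 frames
   per second this produces 3600 measurements per hour.
2. **Camera fusion** (`fuse_series()`): per second, take the one camera
   that saw the animal, or the *larger* of the two values when both did —
   a camera that catches only part of a movement underestimates it, so
   disagreement is resolved upward. Only when both cameras missed the
   animal is the fused second missing.
3. **Sliding window** (`sliding_mean()`): a trailing mean over the 30
   seconds ending at (and including) the current second, stepped every
   second.

Missing values never enter a mean as zeros: a stationary animal and an
unobserved animal must remain distinguishable, which is the entire point
of carrying the `out` state through the pipeline.

Two compositional choices here were genuinely open and are worth
recording. First, window alignment: nothing in the problem dictates
trailing, centered, or leading windows. foxwatch uses trailing windows
inclusive of the current second, the only alignment under which a window
of one step is exactly the identity on a per-second series — a property
the test suite relies on. Second, the normalization of the windowed mean:
summing $F-1$ frame-pair norms and dividing by the number of *frames*
$F$ would bias the mean low by a factor $(F-1)/F$; foxwatch always
divides by the number of non-missing pairs actually summed.

### Coverage accounting

A window is reported missing when fewer than `min_coverage` (default 0.5)
of its positions hold an observed value: a window more than half
unobserved is better reported as `out` than extrapolated. The coverage
denominator counts only window positions that overlap the series' time
range, so the opening 29 seconds of a recording — where the trailing
window pokes out before the first sample — are not spuriously flagged as
`out`. "Unobserved" means the detector lost the animal, not "before the
recording began".

## Activity levels and threshold calibration

Every second receives one of four labels: `inactive` (box essentially
still — lying, sitting, standing), `active` (in-place movement —
scratching, stretching, turning), `high_active` (locomotion — the box
changes location), or `out` (not detected). Classification is a two-cut
decision tree on the windowed mean norm; a value exactly on a boundary
classifies upward (the strictness choice is arbitrary and documented
rather than load-bearing).

The two cuts are calibrated from reference segments — stretches of footage
whose level is known — each summarized by the **maximum** of its windowed
norm. If the summaries of adjacent levels separate, any value in the gap
is a valid threshold; foxwatch takes the midpoint, which maximizes the
margin to both sides symmetrically. Overlap is a hard calibration error
naming the offending values: silently picking a threshold inside an
overlapping range would manufacture a classifier that cannot be trusted.

`reference_segments()` automates segment extraction when ground truth is
available (simulated data, or manually scored footage): it uses contiguous
single-level runs of at least 60 s and skips the first 30 s of each run so
the trailing window no longer mixes in the previous behavior.

Durations (`activity_durations()`) are integer seconds at the 1 Hz label
resolution and always sum to the observation length; the binned overview
(`activity_overview()`, default 30-min bins) is additive under re-binning,
so hourly and half-hourly views of the same day agree by construction. No
smoothing of short label flickers is applied — with well-separated
thresholds and a 30-s window the label sequence is already smooth, and any
additional smoothing would silently move seconds between levels.

## Residence mapping

`residence_trace()` collects the detected box centers in time order;
`occupancy_grid()` bins them on a uniform grid over the unit square
(default 32 × 18, roughly the 16:9 image aspect) with half-open cells and
a closed top/right edge, so each point is counted exactly once. The
normalized density is the empirical likelihood of residence; no kernel
smoothing is applied — the raw histogram is the definition, and a
rendering can smooth for display if desired. Merging a $2n \times 2n$ grid
2×2 reproduces the $n \times n$ grid exactly, which the tests verify.

## Detector evaluation

The metrics are the interpolated-AP family: detections are ranked by
confidence; a detection is a true positive when its best-IoU unmatched
ground-truth box in the same image and class reaches 0.5. Matching is
greedy **one-to-one** in rank order, so a duplicate detection of an
already-claimed object is a false positive — without this, precision is
meaningless for detectors that fire twice on one animal. IoU clips boxes
to the unit square before computing areas. Precision/recall accumulate
down the ranking; AP averages the interpolated precision
$p_\text{interp}(r) = \max_{\hat r \ge r} p(\hat r)$ over the 11-point
recall grid $\{0, 0.1, \dots, 1\}$, and mAP averages AP over the classes
present in the ground truth (with one class, mAP = AP). `average_iou` is
the mean IoU over true-positive matches; recall against zero ground-truth
boxes is an error rather than a silent zero, because an empty label set
is almost always a mishap. The whole chain is verified in the test suite
against an independent plain-loop reimplementation on hundreds of random
micro-instances.

## Annotation tooling

The YOLO/LabelImg dialect (one `.txt` per image; lines
`<class> <cx> <cy> <w> <h>`, normalized to `(0,1]`) is parsed strictly by
default — a coordinate of 0, or 1.2, names its line number and fails —
with an opt-in lenient mode that clips, for real-world label files.
The stratified splitter preserves stratum proportions (day/night scenes)
with a largest-remainder allocation: total training size
$\lfloor f N \rfloor$, per-stratum floors of $f N_s$, remaining seats to
the largest fractional remainders. This is the simplest rule that
reproduces an 80% split of 7363 images stratified 4467/2896 as exactly
5890 training and 1473 test images, and its randomization is confined to
*membership within* strata, under a caller-supplied seed.

## The cage simulator

There is no public detection data for this setting, so the package ships a
generator with the statistical structure the pipeline assumes, used by
the tests and usable for power analyses:

* **Behavior**: a semi-Markov process over the three levels. Dwell times
  are exponential beyond a 10 s minimum (means 240 s inactive, 90 s
  active, 120 s high-active — resting bouts dominate a captive canid's
  day, interruptions are shorter). Per-frame speeds are drawn from
  disjoint ranges: 0–0.002 (essentially stationary), 0.06–0.12, and
  0.3–0.6 normalized units per second. The supports are deliberately
  non-overlapping — threshold calibration is only well-posed when the
  reference behaviors separate, and the generator's contract is to
  produce data *from* the model the classifier assumes.
* **Movement**: during active/high-active bouts a correlated random walk
  (heading noise 0.25 rad/frame) with reflecting cage walls, heading for
  the platform with probability 0.3 per bout; during inactive bouts a
  wobble tethered within 5 mm-scale distance of a fixed rest position — a
  lying animal must not diffuse across the cage, however long the bout.
* **Sensing**: each camera sees a configurable rectangle (defaults: left
  65% and right 65% of the cage, overlapping in the middle); outside it,
  the frame has no detection. Detected centers carry Gaussian jitter
  (sd 0.002 — at 318 cm cage width about 6 mm, a plausible localization
  error) and Beta(30, 2)-distributed confidences. With these defaults the
  windowed norm of an inactive animal (≈0.004, dominated by jitter) sits
  an order of magnitude below an active one (≈0.02), mirroring the margin
  a real calibration needs.
* **Comparison emulators**: an interval motion detector (10 s cadence,
  360 readings/hour, blind to everything outside its coverage rectangle
  and to sub-threshold path lengths) and manual spot checks (every
  15 min, ±30 s watched, the modal label extrapolated to the whole
  interval — 4 readings/hour, faithfully over- or under-representing
  mixed intervals).

What the simulator does **not** emulate: appearance (no images are
rendered, so detector failure modes like unusual postures or lighting do
not occur — missingness is purely geometric), camera tampering, multiple
animals, and identity switches. Passing tests therefore demonstrate that
the *post-detector* computation is correct under its stated model, not
that any particular detector is accurate on real footage.

## Numerical and accounting choices

* Equality in camera fusion is exact; any difference is a mismatch
  resolved to the larger value. Fusion is commutative, idempotent, and
  dominant, and can only increase coverage.
* Confidence ties in detection ranking break by image id, then input
  order — determinism over elegance.
* Degenerate inputs fail loudly: zero-area boxes, empty item lists,
  recall without ground truth, non-separable calibration segments,
  misaligned camera clocks (above 0.5 s after snapping to seconds).
* All randomness funnels through explicit integer seeds; a pipeline run
  with a fixed seed is byte-identical, and the run log records the
  package version, a config digest and per-stage counts.

## Problem sizes

The test suite works at deliberately small scales: simulated recordings
of 10–60 minutes at 5 fps (3 000–18 000 frames), 200 random
detector-evaluation micro-instances of at most 6 boxes, 20 simulated
half-hours for the fusion dominance checks, and 10 seeded scripted
half-hours for duration recovery (recovered within 5% per level; the
residual error is window smearing at state transitions, about 10 s per
transition, which no threshold classifier on a 30-s window can avoid).
These sizes keep a full check fast while leaving every statistical
property comfortably measurable.

## A worked half hour

```{r worked, eval = FALSE}
script <- data.frame(level = c("high_active", "active", "inactive"),
                     duration_s = c(550, 550, 700))
res <- run_pipeline(list(mode = "simulate", out_dir = tempfile(), seed = 7,
                         sim = list(duration_s = 1800, state_script = script)))
res$thresholds
res$durations
```

On this scripted half hour the calibrated thresholds land near 0.012 and
0.056 and the recovered durations come out within about 15 s of the
scripted 700/550/550 split, with no `out` time — both cameras together
cover the whole cage.

## Known limitations

Physical units are out of reach without camera calibration: all speeds
and distances are fractions of the image. The two cameras are assumed
clock-synchronized (an alignment helper snaps sub-second skew). The
threshold classifier is as good as its reference segments; behaviors
whose windowed speeds overlap (e.g., slow pacing vs vigorous in-place
activity) cannot be separated by any threshold on this one statistic.
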
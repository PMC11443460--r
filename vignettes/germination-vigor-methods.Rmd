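---
title: "Methods: box-regression losses, detection evaluation and germination-vigor phenotyping"
author: "germkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: box-regression losses, detection evaluation and germination-vigor phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germkit)
```

`germkit` quantifies seed germination vigor under salt stress from detected
bounding boxes in time-lapse tray imagery, and provides every computational
stage around the detector: the IoU family of box-regression losses, a
convergence harness, the coordinate-attention forward pass, detection
evaluation, dataset tooling, and a synthetic generator plus classical
reference detector that close the pipeline without any trained network.
This vignette records the models, the parameter choices and the numerical
decisions, in the spirit of a methods section.

## The loss family

All boxes are axis-aligned, in continuous pixel coordinates (origin
top-left, y downward), stored in center form `(cx, cy, w, h)` with
`w, h > 0`. For a prediction `(ω, h)` and a truth `(ω^gt, h^gt)`:

* `IoU` is intersection area over union area;
* `GIoU = IoU − |C \ (A ∪ B)| / |C|` with `C` the smallest enclosing box;
* `DIoU loss = 1 − IoU + ρ²/c²`, with `ρ²` the squared center distance and
  `c²` the squared diagonal of `C`;
* `CIoU loss = 1 − IoU + ρ²/c² + αv`, where
  `v = (4/π²)(arctan(ω^gt/h^gt) − arctan(ω/h))²` measures aspect-ratio
  disagreement;
* `EIoU loss = 1 − IoU + ρ²/c² + (h − h^gt)²/c_h² + (ω − ω^gt)²/c_ω²`
  splits the aspect penalty into separate, directly-optimisable edge terms;
* `ECIoU loss = CIoU loss + (h − h^gt)²/c_h² + (ω − ω^gt)²/c_ω²` is the
  combination: the aspect-ratio coupling of CIoU plus the separated edge
  penalties of EIoU, computed as a single sum.

Two definitional points were genuinely open and are resolved as follows.
The trade-off weight `α` is taken from the original CIoU formulation,
`α = v / ((1 − IoU) + v)` with `α := 0` when `v = 0` and an ε = 1e-9 guard
against division by zero. And ECIoU is implemented as the printed sum
above, not as a two-phase schedule that first optimises CIoU and then
EIoU; narrative descriptions of "first the aspect ratio converges, then
each edge is tuned" describe the optimisation dynamics that the sum itself
produces (the aspect term dominates early, the edge terms dominate the
endgame), not a branch in the loss.

Invariants enforced by tests: every loss is 0 exactly at identity and
positive elsewhere; all six are translation invariant; IoU, `v` and
`ρ²/c²` are scale invariant; `ECIoU ≥ CIoU` always (the added terms are
nonnegative); GIoU loss lies in [0, 2]. IoU itself is validated against a
pixel-rasterisation oracle on random integer boxes (agreement ≤ 1e-3 over
200 pairs).

## The regression harness

`fitBox()` treats each loss as an objective over the moving box,
parameterised as `(cx, cy, log w, log h)` so sizes stay positive, with
central-difference gradients (step 1e-4). Plain fixed-step gradient
descent is unusable here for two reasons discovered during design: the
surface is roughly two orders of magnitude flatter in the pixel-scale
center coordinates than in the log sizes (the penalty terms are normalised
by the enclosing box, so center curvature scales as 1/c²), and the losses
are only piecewise smooth — when a box edge aligns exactly with the
target's, the enclosing-box terms kink, and both raw gradients and
per-coordinate sign moves stall there (GIoU is particularly prone, since
its only other signal near the optimum is 1 − IoU).

The fitter therefore uses sign-based per-parameter resilient steps (grow
1.2× while the gradient sign holds, halve on a flip; capped at 50 px for
centers and 0.7 log-units for sizes so a size cannot run away), a monotone
safeguard (a move that would increase the loss is never accepted, so the
recorded trace is non-increasing), and a kink fallback: a coordinate-
descent sweep over the four box edges (each a coupled center/size change)
plus center-preserving size moves, each with halve-then-double line search.
The size moves also rescue degenerate states in which a box has collapsed
or ballooned until its finite-difference gradient vanishes. Defaults:
initial step 0.05, iteration budget 2000, convergence tolerance 1e-3 on
the loss. The run is deterministic given its inputs; a non-finite
objective ends the run as non-converged rather than an error.

Qualitative properties asserted by the tests: from disjoint boxes the
plain IoU loss has zero gradient everywhere and never converges, while
GIoU/DIoU/CIoU/EIoU/ECIoU all do; from random overlapping starts all five
enclosing-box losses converge on at least 95 % of 100 seeded scenarios,
and converged fits match the target within 0.5 px per coordinate. No
quantitative convergence-speed comparison between CIoU and ECIoU is
claimed: iteration counts under this optimiser are not comparable to SGD
steps in a detector.

## Coordinate attention

`coordinateAttention()` implements the forward pass only, on `(C, H, W)`
arrays with injected weights: mean-pool along width (→ C×H) and height
(→ C×W), concatenate along the spatial axis, apply the shared `C → C/r`
reduction and a ReLU (the deterministic choice among the nonlinearities
used by such blocks), split, expand per path, logistic-squash into
attention maps `a_h` and `a_w` in [0, 1], and gate:
`out[c,i,j] = x[c,i,j]·a_h[c,i]·a_w[c,j]`. Batch normalisation is omitted
(inference-style identity) because the block is never trained here. The
default reduction ratio is r = 32, overridable; tests use small channel
counts with r dividing C. With all-zero weights both maps are exactly 0.5,
so the output is 0.25·x — a convenient analytic fixture. Gating bounds
(`|out| ≤ |x|`) and permutation equivariance of the two pooling paths are
property-tested.

## Detection evaluation

`nms()` suppresses greedily per class and frame at IoU 0.7 (the reference
training configuration); confidence ties are broken by input order (stable
sort), making the procedure deterministic. `matchAndScore()` matches each
detection, in decreasing confidence, to its best-IoU unmatched same-class
truth in the same frame at threshold 0.5 (the mAP50 convention); matching
never crosses frames or labels. Precision and recall are defined as 0 when
their denominators are 0. AP integrates the all-point-interpolated PR
curve: the precision envelope `max precision at recall ≥ r` against the
recall steps — the modern VOC/YOLO convention; the test oracle enumerates
the cumulative PR sequence with explicit loops and must agree to 1e-9 on
random instances of up to 6 boxes. Classes absent from the ground truth
carry `NA` AP and are excluded from the mAP mean, the usual convention, so
a frame set with no short roots does not dilute mAP50.

## Phenotyping

Germination is equated with reaching the `L_root` class — radicle at least
half the seed length — so `S_root` detections contribute to neither the
germinated count nor the root-length statistics. Per acquisition time the
pipeline counts L-root detections, capped at the number of seeds on the
tray (duplicate detections cannot create seeds), and enforces monotonicity
with a running maximum: germination is irreversible, so a dip in the count
is detector flicker, not biology. First-time germinations `G_t` come from
differencing the repaired cumulative series — the standard
germination-index convention of "newly germinated at t", with `D_t` the
elapsed time in hours; the index `Σ G_t/D_t` is reported unitless. Root
length is the detection-box diagonal `√(w² + h²)` scaled by the mm/px
calibration; mean root length is cross-sectional per frame (root identity
is never tracked across frames) and 0 mm by convention when nothing has
germinated.

## The synthetic generator

The generator emulates the reference experimental design: 9×9 = 81 seeds
per tray; NaCl at 0 (control), 30, 60, 90, 120, 150 mmol/L; three
replicate trays per concentration (18 trays, 1458 seeds); one frame per
tray every 0.5 h for 48 h (1728 images); 26 °C. Germination probability
per concentration defaults to 0.85 / 0.92 / 0.75 / 0.55 / 0.30 / 0.10,
linearly interpolated, and 0 at or above 160 mmol/L — a profile shaped to
the qualitative dose response (mild promotion at 30 mmol/L, monotone
inhibition above, no germination at ≥160); no per-concentration rates are
published for the real experiment, so these are generator defaults, not
claims. Radicle emergence is Normal(26 h, 4 h), matching "around 24 h"
emergence with spread, truncated to times at which the half-seed-length
standard is still reachable within the 48 h window given the
concentration's growth rate — `p_germ` is thereby the probability of
germinating *within the observation window*, which keeps the detector-side
recovery comparable to the Bernoulli parameter. Elongation is linear at
0.40 mm/h in the control, 0.44 mm/h at 30 mmol/L, declining to 0.18 mm/h
at 150 mmol/L. The nominal seed is 8 × 3.5 mm, so the germination standard
is a 4 mm radicle.

Rendering: 972×972 px frames at 0.25 mm/px (108 px cells), seed ellipses
at cell centers (gray level 0.85 on background 0.10), radicles as gently
curved strokes (sagitta 5 % of length, half-width 1.5 px, level 0.55)
growing from the seed tip toward a cell corner; Gaussian pixel noise
(sd 0.02) is seeded per frame. Radicles are clipped at their cell boundary
with a summary warning. Ground-truth boxes enclose the seed ellipse and
the radicle centerline with a 1 px margin; roots are annotated once at
least 1 mm is rendered. The 1 px margin is deliberate: it keeps the box
diagonal within 15 % of the rendered chord for measurable (≥ 6 mm) roots,
so the box-diagonal length proxy stays honest, while still covering the
stroke core for IoU matching. What the renderer does *not* emulate:
photo-realistic texture, lighting gradients, seed-shape variation,
touching seeds, condensation artifacts — so a detector that is perfect
here can still fail on real imagery, and passing tests validate the
*pipeline math*, not real-world detection difficulty.

The reference detector is classical and deterministic: threshold halfway
between background and radicle level; morphological opening with a disc
sized to ~70 % of the seed minor axis separates seed bodies from
protruding radicles; radicle pixels are the foreground outside a small
dilation of the bodies; connected components become detections. Root
length is measured as the component's extent along its principal axis with
a fixed geometric compensation for the stroke radius and the pixels hidden
under the body mask, and the S/L classification applies the half-seed
standard to that measured length. Confidence is the component's mean
intensity contrast, clipped to [0, 1]. Root boxes are padded by 1 px for
the masked margin at the seed boundary — the value, like the opening
radius, was calibrated on noiseless rendered frames against the annotation
convention above.

## Problem sizes and numerical choices in the tests

The closed-loop recovery test runs all 6 concentrations × 3 trays × 81
seeds with frames every 4 h (12 per tray, 216 frames in total) — a
sampling of the 0.5 h schedule chosen to keep the suite comfortably fast
while leaving the germination-index ranking unchanged (ground truth and
detector are compared on the same grid). Recovery is asserted within the
binomial 95 % sampling error of 243 seeds per concentration, under fixed
seeds. Detector quality (mAP50 ≥ 0.9 pooled over noiseless frames spanning
12–48 h at two concentrations) is an artifact property of this generator +
detector pair, not a claim about any trained model. Oracle suites use 200
random box pairs (IoU), 60 random instances of ≤ 6 boxes (AP), and 100
random overlapping scenarios (regression), all seeded.

## Known limitations

* The regression harness characterises the loss *geometry*; it says
  nothing about stochastic-gradient behavior inside a real detector.
* Root lengths from detector boxes inherit the stroke/mask padding, so
  synthetic mean-root-length estimates carry a ~1 mm upward bias relative
  to the true chord; classification uses the compensated principal-axis
  measurement instead.
* The index and rate are only as monotone as the running-maximum repair;
  a detector with sustained false L-root detections would bias both
  upward, capped at the tray's seed count.
* At high salt concentrations germinating seeds are, by construction of
  the truncated emergence-time distribution, early-emerging seeds; the
  marginal emergence-time distribution at those concentrations is
  therefore left-shifted relative to the untruncated normal.
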
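---
title: "Methods: posture tracking and sensorimotor reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture tracking and sensorimotor reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensetrackr)
```

## Overview

`sensetrackr` tracks the posture of a single animal — a crawling
*Drosophila* larva is the motivating case, but any compact dark-on-light
or light-on-dark body works — in grayscale frame sequences of a
two-dimensional arena, and reconstructs the sensory stimulus experienced
at specific body loci in parametric stimulus landscapes. The pipeline has
an "online" stage (what a tracker does while frames stream from a
camera) and an "offline" stage (shape analysis and sensorimotor
reconstruction), tied together by `run_pipeline()`.

The stages are:

1. **Background reconstruction** (`reconstruct_background()`): the animal
   is detected in the first frame as the largest salient object, a box is
   cropped around it, and the box interior is patched from the first
   later frame whose animal box is disjoint from it. Static clutter
   (dirt, droplets, shadows) stays in the background and cancels on
   subtraction.
2. **Segmentation and tracking** (`track_stream()`): per frame,
   background subtraction, thresholding, largest-8-connected-object
   retention, and a bounding-box crop (margin of half the object's
   major-axis length). The next frame is searched in the previous box
   dilated by the margin, with a whole-frame fallback. Tracking stops at
   the frame budget or when the object touches the frame border.
3. **Posture analysis** (`analyze_posture()`): hole filling, boundary
   tracing, contour smoothing, contour curvature, head/tail candidate
   tips, Zhang–Suen thinning to a midline skeleton, endpoint checks,
   skeleton ordering, and morphometrics (area, perimeter, skeleton
   length, centroid, midpoint).
4. **Identity** (`label_trajectory()`): head vs tail is seeded from two
   configured points (replacing interactive clicks) and propagated by the
   distance rule — the head in the current frame is the candidate closest
   to the previous head. The rule uses position only, so it tolerates
   pauses and backward crawling; it requires sampling faster than the
   motion speed in body-length units. Ambiguous frames (blob-like
   postures, head jumps above half a body length, distance ties) are
   flagged; corrections are a replayable table (`resolve_flags()`).
5. **Calibration** (`fit_scale()`, `to_arena_frame()`): a single scalar
   mm-per-pixel factor from landmark pairs, plus frames per second.
6. **Sensorimotor records and events** (`build_records()`,
   `detect_events()`, `merge_trials()`): stimulus at the head, its time
   derivative, bearing to the local gradient, skeleton-resolved stimulus
   differences, contour light exposure, and run/turn/cast labels.

An experiment planner (`plan_experiment()`) relates organism size λ,
field-of-view length L, sampling interval τ, experiment duration T,
frame resolution and speed: posture resolution is P/(L/λ) pixels per
body length (51.2 px at P = 1024 and L/λ = 20), time-to-edge is the
distance in body lengths over the speed in body lengths per second, and
storage is frames × crop pixels × bytes per pixel.

## Stimulus landscapes

Three analytic field shapes cover the assay modalities, each with an
exact gradient:

* linear (thermotaxis): $v(p) = v_0 + g\,(p - p_0)\cdot\hat u$, constant
  gradient $g\hat u$ in units/mm — e.g. a 0.1 °C/mm thermal gradient, in
  which a 4 mm body aligned with the gradient spans 0.4 °C tip to tip;
* radial (chemotaxis): $v(p) = A\,e^{-|p - s|/\lambda_d}$ around a source
  $s$; the gradient points toward the source with magnitude
  $A e^{-r/\lambda_d}/\lambda_d$;
* sideways light (phototaxis): $v(p) = I_0\,e^{-d(p)/\lambda_d}$ with
  $d$ the distance from the source line, plus an optional lit/shadow
  half-plane boundary used to compute the percentage of the body contour
  (and of each body side) exposed to light.

The exponential forms for odor and light are conventions — the real
profiles depend on the apparatus — and are config-replaceable; a
`landscape_grid()` bilinear interpolator accepts measured maps. Measured
physical transport (diffusion, conduction) is out of scope.

## The synthetic generator

`simulate_crawl()` renders a worm-like body — a constant-halfwidth
capsule around a curved midline — crawling over a noisy background with
optional static clutter discs, and returns exact per-frame ground truth
(midline, head, tail, centroid, heading, body mask). Defaults emulate a
third-instar larva on agarose: body length 4 mm, halfwidth 0.25 mm,
speed 0.15 body lengths/s, 7 Hz sampling, 0.1 mm/px, 8-bit intensities,
i.i.d. Gaussian pixel noise clipped to [0, 255]. All randomness is
controlled by a single seed and sequences are bit-reproducible.

Design choices worth noting:

* **The body tips coincide with the midline endpoints.** The capsule is
  drawn around the midline inset by one halfwidth at each end. The
  ground-truth head is therefore the visible tip of the body — the same
  point that contour-curvature maxima estimate — and the tip-to-tip
  length equals the body length. The analytic mask area of a straight
  body is $2(L - 2w)w + \pi w^2$.
* **Kinematics are deliberately simple**: instantaneous heading changes
  at turns, and head casts as a smooth sinusoidal swing of the anterior
  third of the midline (about the one-third arc point) over a fixed 1 s
  window, with forward progression paused. Ground truth stays analytic;
  peristalsis, body-width modulation and gradual turning are *not*
  emulated. Passing tests therefore demonstrate correctness of the
  image-processing and reconstruction machinery on capsule-shaped
  bodies, not robustness to every real-world body shape or deformation.
* Rendering is hard-masked (no anti-aliasing), so noise-free
  segmentation oracles are exact.

## Numerical and algorithmic choices

* **Thresholding.** `suggest_threshold()` maximizes between-class
  variance (Otsu). That criterion degenerates when the animal occupies a
  tiny fraction of the frame — it splits the background noise instead of
  separating the animal — so the tracking loop defaults to a robust
  contrast-midpoint rule: halfway between the median intensity (the
  background) and the extreme intensity on the animal side. Both are
  config-overridable, mirroring the interactive threshold adjustment of
  camera-side trackers.
* **Connectivity** is 8-connected everywhere (thin diagonal bodies stay
  connected); component labeling is implemented in-package because the
  available library labeling is 4-connected. Equal-size component ties
  break toward the first pixel in row-major order.
* **Thinning** is Zhang–Suen, vectorized over the mask; holes are filled
  first so segmentation noise cannot change topology. Thinning variants
  differ by a pixel or two at line ends (Zhang–Suen erodes one more end
  pixel than lookup-table thinning); the test suite pins behavior to an
  independent brute-force implementation of the same rules.
* **Skeleton ordering and extension.** The medial axis of a capsule ends
  one halfwidth short of each tip, so the ordered skeleton is extended to
  the curvature-derived tip points; the ordered path is then smoothed
  (moving average, window 5, endpoints fixed) because the raw thinned
  path staircases and inflates arc length by 10–25%. After both steps the
  skeleton length of the default body is within a few percent of truth.
* **Curvature** is estimated from the turning angle between chords to
  points ±w away (w = 5% of contour length, minimum 3), divided by the
  arc between the chord midpoints — the normalization that converges to
  1/r on a circle. Head/tail candidates are the two highest
  positive-curvature local maxima separated by ≥ 25% of the contour,
  required to exceed 1.5× the median absolute curvature so that shapes
  without localized tips (disks, curled bodies) are flagged `blob_like`
  instead of yielding arbitrary points.
* **blob_like** additionally triggers when the head–tail distance is
  under 30% of the skeleton length or the skeleton is under 5 px.
* **Identity ties** (candidates equidistant from the previous head
  within 1 px) resolve by body-axis continuity and set `swap_suspect`.
* **Coordinates** are R's native 1-based (row, col) indices with x =
  column and y = row, origin at the top-left; CSV offsets are written
  0-based for interoperability. Pixel centers map to
  ((col − 0.5), (row − 0.5)) · mm/px.

## Event detection

Heading is the direction of centroid displacement over a centered
3-frame window, falling back to the tail-to-head body axis below
0.05 body lengths/s. Events are labeled per frame, every frame getting
exactly one of run/turn/cast:

* **turn**: |dθ/dt| > 20 °/s (default) for ≥ 2 frames while the centroid
  moves at or above the run-speed gate;
* **cast**: head-bend angle (deviation of the head–midpoint–tail chain
  from straight) > 30° while the centroid speed is below the gate, for
  ≥ 2 frames; casts take precedence over turns;
* **run**: everything else.

Two gates deserve justification. The run-speed gate (default 0.15 body
lengths/s, roughly half a typical crawl speed) separates translation
from stationary head sweeping; it is needed because centroid-derived
heading is ill-defined when the animal barely translates. Second, a
guard window (default 1 s, the canonical cast duration) around each
detected cast is excluded from turn candidacy: a head sweep displaces
the centroid and contaminates the heading estimate for a few frames
after the cast, which would otherwise register as spurious turns. With
both gates, validation on randomized ground-truth trials (4 events per
trial, turns of 60–120° and 60° casts, events ≥ 3 s apart, 0.2 s
sampling) recovers 100% of injected events with no false positives.
Threshold defaults are config-exposed; they are operating points, not
universal constants, and should be re-tuned per organism and frame rate.
Note that at 60° cast amplitude the bend angle exceeds the 30° cast
threshold for only ~0.47 s of the 1 s window, so sampling slower than
~0.23 s cannot satisfy the 2-frame minimum duration — an instance of the
planner's general warning that sampling must outpace the behavior.

## Problem sizes and runtime

The validation suite uses 20 tracked trials of 50 frames (500×500 px,
noise σ = 5, contrast 100, 0.1 body length of motion per frame) for
end-to-end fidelity; 60 randomized curved postures for the shape
invariants; 20 randomized kinematic trials for event recovery; and 100
random points per landscape for gradient checks. These sizes give stable
statistics (≈ 1000 frames per aggregate) while keeping a full run of the
suite under a minute on one core; all quantities are recomputed from
scratch at every run.

## Known limitations

* Single animal only; no multi-animal data association.
* One scalar calibration factor: anisotropic pixels, lens distortion and
  perspective are not corrected.
* Skeleton-by-bisectors (building the midline from the two curvature
  tips along the left/right perimeter) is not implemented; thinning is
  the only skeletonization route, with curvature tips used for the
  endpoints.
* The live-timing stop (sampling interval exceeded by processing time)
  is meaningful only when frames stream from a camera; reading from
  files never triggers it.
* Extra skeleton branches are flagged (`spur`), not exploited to detect
  appendages; automatic swap repair from brightness or motion asymmetry
  is not attempted.
* AVI/MP4 input and HDF5 output are not supported in this build; frame
  directories (PNG/TIFF) and CSV/JSON serializations are.
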
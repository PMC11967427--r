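---
title: "Counting and classifying stained microplastics in flow-cell video: models and methods"
author: "flowmp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and classifying stained microplastics in flow-cell video: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Nile-Red staining makes microplastic particles fluoresce brightly
(excitation 450–490 nm, emission 515–565 nm), so a suspension pumped through
a shallow flow cell under a fluorescence stereomicroscope becomes a video of
bright particles drifting across a dark background. `flowmp` turns such a
video into a particle inventory: every physical particle counted exactly
once, measured (maximum feret diameter, size category), cropped, and
classified as *grain* (compact fragment) or *fiber* (thin elongated thread)
with a confidence score. At the default optics one pixel corresponds to
18 µm, which sets the lower detection limit: a single bright pixel is an
18 µm particle.

The pipeline is: per-frame Canny-style segmentation inside a fixed
*detection window* → cross-frame linking (de-duplication) → morphometry →
crop extraction → CNN classification → CSV/crop reporting. A synthetic
flow-cell simulator with exact ground truth makes every stage testable
without laboratory data.

## Detection: the Canny cascade

Each frame passes through a fixed cascade: 5×5 Gaussian smoothing
(σ = 1.4), Sobel first derivatives giving gradient magnitude and direction,
non-maximum suppression along the quantized gradient direction, and
hysteresis thresholding (pixels at or above the high threshold seed edges;
pixels at or above the low threshold survive only in 8-connected contact
with a seed). Closed contours are then morphologically closed (3×3),
hole-filled, and labeled into 8-connected regions; a region becomes a
`ParticleCandidate` when its area reaches `min_area_px` (default 1 px) and
its centroid lies inside the detection window.

Two numerical choices matter here:

* **Relative high threshold, 0.10 of the frame's maximum gradient.**
  Acquisitions fix staining concentration and exposure rather than
  thresholds, so the threshold adapts to the frame. The faintest resolvable
  particle — a one-pixel-wide fiber at the brightness floor, attenuated by
  the point-spread blur — has roughly a quarter of the gradient of a bright
  saturated grain; a fraction of 0.25 loses such particles whenever a bright
  grain shares the frame, while 0.10 retains them and still sits more than
  3× above defocused non-plastic distractors.
* **Absolute floor `min_gradient = 30`.** On frames containing no particle
  the maximum gradient is background noise, and a purely relative threshold
  would collapse onto it and segment the whole frame. The floor sits above
  the noise-gradient ceiling of 8-bit video with noise sd up to ~4 (about 14
  at sd 2 after smoothing) and far below any stained particle (> 100).
* **Closing before filling.** Uneven staining produces dark particle cores;
  non-maximum suppression occasionally breaks a contour ring by 1–2 px.
  Without closing, a broken ring is not filled and an interior core ring can
  surface as a second, spurious candidate.

## Tracking: count each particle once

A particle is visible in many consecutive frames. Candidates are linked
greedily to the nearest predicted position (previous centroid advanced by
`expected_flow_dx_px`), gated by `max_link_distance_px` (default 12),
lateral movement `max_lateral_dy_px` (6), and frame-to-frame feret ratio
(symmetric, 2). Ties break deterministically (smaller distance, then smaller
x, then y), so the matching is invariant to candidate ordering. Unmatched
candidates start tracks; unmatched tracks age and are finalized after
`max_gap_frames` (2) missed frames — enough to bridge pump pauses. Greedy
matching is adequate at realistic particle densities and is checked against
optimal assignment on constructed cases in the tests.

A track is counted once, when it terminates, at its **representative
candidate** — the largest-area member, i.e. the most in-focus, most fully
stained view; that member supplies the reported size, the crop, and the
counted frame. Counting at termination rather than entry means all frames
are available when the representative is chosen.

Two failure modes are deliberately preserved, measured, and reported rather
than hidden: particles whose masks (or edge rings) touch merge into one
track (undercount), and jumps beyond the link gates split tracks
(overcount). `detection_efficiency()` quantifies both against ground truth.

## Morphometry conventions

* **Feret diameters** are caliper widths over the *pixel-corner point set*
  (each boundary pixel expanded ±0.5 px), so an axis-aligned w×h block
  measures exactly w and h, and a 10×4 rectangle's maximum feret is exactly
  √116. The convention inflates a 20 px disk's maximum feret by ~1.3 px —
  the price of exact axis-aligned extents.
* **Perimeter** is the polygonal length of the traced 8-connected boundary
  chain, not the pixel-edge count, which would inflate P by ~25% and deflate
  circularity correspondingly; very small shapes (chain < 8 points) fall
  back to the pixel-edge outline.
* **Circularity** is 4πA/P²; with the chain convention a rasterized disk
  measures ≈ 0.96 and an elongated 30×2 bar ≈ 0.21. Discretization can push
  values slightly above 1 (bounded by +0.1 for shapes ≥ 10 px across).
* **Size** is the maximum feret rounded to integer pixels
  (`size_px`), and `size_um = size_px × pixel_scale`; nearest-rounding was
  chosen over floor as the less biased convention. Size categories are
  half-open with boundaries going up: small < 6 px, medium [6, 10), large
  [10, 20), extra-large ≥ 20 px — i.e. 108, 180, 360 µm at 18 µm/px.

## The synthetic scene generator

The simulator defines the study conditions for every test:

* **Grain shapes** are star-convex radial-harmonic polygons
  r(θ) = R(1 + Σₖ aₖ cos(kθ + φₖ)), k = 2…6, anisotropically stretched,
  randomly rotated, and rasterized. Harmonic amplitude, stretch and scale
  are adapted by rejection sampling against the package's own
  `shape_stats()` until the measured circularity, aspect ratio and size hit
  their targets (tight tolerances ±0.04 / ±0.15 / ±4% are attempted; the
  documented acceptance tolerances ±0.15 / ±0.5 / ±15% are the fallback).
  Defaults follow natural sediment microplastics: size lognormal
  152.9 ± 94.1 µm (truncated 36–500 µm, right-skewed like real size
  spectra), circularity 0.42 ± 0.20 (truncated 0.2–0.9), aspect
  3.16 ± 1.51 (truncated 1.1–6). At 18 µm/px a mean-size grain is only
  ~8 px across, so rasterization cannot reach circularity below ~0.3 there;
  the resulting population bias (+0.06 on mean circularity) is measured in
  the calibration test and stays inside the ±0.1 recovery band.
* **Fibers** are constant-step strokes whose heading turns by a total of
  `curvature · π/2` (quarter circle at curvature 1) plus mild wiggle,
  stamped `width_px` samples wide along the local perpendicular. The
  quarter-circle cap keeps typical fibers above aspect ratio 4; strongly
  curved strokes would otherwise fold toward compact envelopes and become
  morphologically ambiguous even to a human.
* **Kinematics.** All particles advect along +x at
  `flow_velocity_px_per_frame` (default 8) on "moving" frames of a
  rectangular pulsation profile (period 10 frames, duty 0.6 by default),
  emulating a peristaltic pump with an intermittent actuator; they pause
  otherwise. Because velocities are identical, relative geometry is static:
  a scene is non-touching forever if placed non-touching (the
  `allow_touching = FALSE` placement enforces a margin covering the edge
  rings). Optional lateral jitter re-enables transient touching.
* **Intensity model.** 8-bit single-channel frames: background level 6 plus
  Gaussian noise (sd 2); per-particle brightness uniform in [180, 240]
  times a smooth multiplicative staining-unevenness field
  (1 ± `staining_unevenness`, bilinear upsampling of a 4×4 grid); Gaussian
  PSF blur σ = 0.8 px. Distractors (non-plastic debris) are rendered at
  ≤ 30% of the 180 brightness floor and strongly defocused (σ = 2.5), which
  keeps their gradients ≥ 3× below the default high threshold.
* **Determinism.** A scene config plus seed reproduces bit-identical frames
  and ground truth; the ground-truth log records per-particle class, true
  size (measured on the rendered mask), per-frame centroid, window-entry
  frames, and all touching events.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: optical aberrations and depth-of-field variation
(the PSF is fixed), hydrodynamic rotation/tumbling (shapes are rigid),
autofluorescent organic debris beyond dim distractors, particles stuck to
the cell walls, and correlated shape statistics (size, circularity and
aspect are sampled independently, whereas they are correlated in nature).

## The shape classifier

The rule-based rough split labels a particle *fiber* when aspect ≥ 4, or
aspect ≥ 3 with circularity < 0.2 — deliberately stricter than natural
grain elongation (mean aspect 3.16). The learned classifier is a small CNN
built from scratch (fixed 2×2 average pool to 50×50, then three
convolution blocks 5×5×8, 3×3×16, 3×3×32 each with ReLU and 2×2 max-pool,
then dense 512→64→2 with softmax), trained with mini-batch SGD
(batch 32, learning rate 0.01, momentum 0.9) on per-crop min-max-normalized
100×100 crops.

The training protocol: 250 images per class sampled without replacement,
each augmented with horizontal mirroring and all 90° rotations (8
orientations, 4 000 images total), at most 200 epochs, early stop once the
within-epoch training error falls below 0.005 — but never before 10 epochs,
because the evaluation rule ("correct" requires the right label *and*
≥ 90% confidence) rewards sharp probabilities and the error plateau is
reached before the logits saturate. Class order is fixed (grain = 0,
fiber = 1) and stored in the model file; a reloaded model predicts
bit-identically. Training data come from the simulator with
artificial-fragment shape statistics (compact mill-ground particles,
size 290 ± 130 µm, circularity 0.60 ± 0.15, aspect 2.2 ± 0.8, plus
laundry-like fibers) — the material a classifier of this kind is trained
and evaluated on — with ground-truth labels standing in for the human
relabeling step; real-data workflows can override labels via a relabeling
CSV.

## Evaluation

`confusion_summary()` builds the evaluated-as × true-class matrix and
per-class correct-answer rates under the ≥ 90%-confidence rule, reporting
plain label agreement alongside (the two differ exactly when a correct
label is predicted timidly). `detection_efficiency()` matches counted
records one-to-one (greedy by distance) to ground-truth trajectories at the
counted frame within the link distance; unmatched records are false
positives, never efficiency. `size_histogram()` bins sizes in 50 µm steps
to 500 µm with an open tail. `fov_coverage(11.2, 12)` reports the 93.3%
field-of-view coverage of the reference flow cell.

## Problem sizes and degenerate inputs

The bundled benchmark scenes are 320×240 px, 100–120 frames, 8–9 particles
— small enough that the full suite (including one complete classifier
training at the 250-per-class protocol) runs in minutes on one CPU, while
every contract is exercised at the sizes stated above. Degenerate inputs
are defined, not crashed on: empty frames error; empty scenes, empty
candidate lists and empty record sets flow through as zeros; collinear
contours take a 1 px line-width convention; single-pixel particles get
circularity from the pixel-edge outline.

## Known limitations

Per-frame candidate counts can differ from ground truth on frames where a
true centroid sits within ~1 px of the window edge (sub-pixel disagreement
between true and measured centroid about which side of the boundary it is
on); track-level counts are unaffected. Particles passing within ~4 px of
each other merge at the edge-ring level even without mask contact — the
same undercount mode as true touching. Detected sizes are measured on the
filled edge ring, which sits ~1–2 px outside the true mask, so pipeline
sizes are biased slightly upward relative to generator-mask morphometry.
The classifier sees synthetic shapes only; nothing here validates transfer
to real stained-particle imagery.
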
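---
title: "Models and design of the spermtrack CASA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the spermtrack CASA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermtrack)
```

spermtrack analyses brightfield microscopy video of boar sperm the way a
smartphone hand-held CASA platform does: a static counting chain for total
cell numbers, motion-based detection and identity tracking for the moving
cells, per-track kinematics with WHO-style grading, and focus scoring for
quality control. This vignette records the models, the parameter choices
that matter, and the design decisions that were genuinely open.

## Coordinate and unit conventions

Frames are numeric matrices on the 8-bit 0–255 scale; coordinates are
(row, col), 0-based, origin top-left, and centroids are real-valued. All
image processing works in pixels and frames; physical units enter exactly
once, in the motility module, through a `Calibration` (µm/px and fps). The
defaults, 0.074 µm/px and 29.80 fps, correspond to the phone-microscope
platform (≈38× magnification); the synthetic scenes use a desk-scale
0.5 µm/px at 30 fps. Area thresholds published at the reference pitch are
rescaled by the squared pixel-pitch ratio and floored at 2 px, because a
single-pixel component is never a meaningful object; distances (the
association gate) rescale linearly.

## Static counting

The counting chain is fixed: binarize (Otsu unless a level is given) →
fill holes → morphological opening (disc, radius 1) → remove components
below the impurity-area threshold (70 px at the reference pitch) →
8-connected labelling. Otsu maximizes between-class variance over a
256-bin histogram; when several thresholds tie, the plateau midpoint is
returned — a symmetric, deterministic tie-break (a half-black/half-white
image thresholds at 127/255). Bright-on-dark polarity is the default,
matching flash-illuminated recordings; a flag inverts it. A constant image
has no two classes and raises a "degenerate histogram" error rather than
guessing.

Two ambiguities were resolved as follows: components are 8-connected
(diagonal contact joins), and the impurity-area filter applies after the
opening, on the cleaned mask. Counting is monotonically non-increasing in
the area threshold, which the tests assert.

## Motion detection

Each pixel is a mixture of K Gaussians with weights ω, means µ and scalar
variances (the pipeline is grayscale). A new frame's value is matched to
the first component, in ω/σ-descending order, within λσ; the matched
component is reinforced (ω ← (1−α)ω + α) and pulled toward the value with
learning rate α, unmatched weights decay, and when nothing matches the
weakest component is replaced by a fresh one centred on the value. The
background set is the smallest prefix of the ordering whose cumulative
weight exceeds ξ; foreground pixels are those matching no component or a
non-background one. The "descending order rule" reading of the background
selection is the canonical one — a literal argmin over an inequality is
ill-typed.

Defaults are the standard operating points for this family of models:
K = 3, α = 0.01, λ = 2.5, ξ = 0.7, initial σ = 15 gray levels, and a σ
floor of 4 gray levels as a numerical guard (all config-exposed). Weights
renormalize to 1 after every update and variances never fall below the
floor; both are asserted as properties. Foreground masks get one pass of
small-component removal (40 px at the reference pitch, rescaled, floored
at 2 px) before centroids are extracted.

A consequence worth stating: the model is initialized on frame 0, so
motion-based detection cannot classify the first frame, and objects
present at start leave slowly decaying ghosts. Identity benchmarks that
demand tracking from frame 0 therefore plug the static intensity detector
into the tracker instead (the detector is an explicit argument of
`trackVideo()`); the mixture detector is the default for real recordings,
where stationary debris would otherwise be tracked.

## Tracking

Each identity carries a constant-velocity Kalman filter with state
(row, col, v_row, v_col), dt = 1 frame, position-only measurements, and no
control input. Detection size is stored on the track but not filtered — it
is not dynamical. The predict step is the standard x⁻ = Ax, P⁻ = APAᵀ + Q
(the correction equations K = P⁻Hᵀ(HP⁻Hᵀ+R)⁻¹, x = x⁻ + K(z − Hx⁻),
P = (I−KH)P⁻ are sometimes mislabelled as prediction in the application
literature; they are implemented as the measurement update). Covariances
are re-symmetrized after every step and stay PSD, which the tests check by
eigenvalue.

Association is minimum-total-Euclidean-cost one-to-one assignment solved
by an O(n³) Hungarian implementation (no weighted linear-assignment solver
ships with the R stack used here), with matches beyond a gate demoted to
unmatched. Matched tracks are corrected and extended; unmatched tracks
coast on their prediction and are deleted after more than `maxAge`
consecutive misses; unmatched detections spawn tracks with fresh,
never-reused IDs, initial velocity 0 (no prior motion information).
Defaults: Q = 0.01·I, R = I, P₀ = diag(1, 1, 10, 10), gate = 50 px at the
reference pitch (rescaled), maxAge = 5, minHits = 1.

The tracking rate of an identity is R_t = 100·F_t/F_w. Against ground
truth, F_w is the number of frames the true object is present and F_t the
largest number of those frames covered by a single track within a 5 px
radius, so identity switches cap F_t at the longest correct segment. For
published per-identity tables, F_t and F_w are taken as given inputs — in
the bundled reference table F_w is an independent presence count that is
not derivable from the appear/disappear columns. One row of that table
(id 45, 44/68) prints 64.70 where half-up rounding gives 64.71; the
package rounds half-up and the tests compare at one unit in the last
printed place.

## Motility and grading

Track centroids are converted to µm and, over the elapsed time
T = (n−1)/fps: VCL = L/T with L the polyline segment sum; VSL the net
displacement over T; VAP = S/T with S the length of the average path — a
centered moving average of positions, default window 5 frames (the common
CASA convention; window 1 disables smoothing and makes VAP ≡ VCL).
Endpoints use shrinking centered windows. LIN = 100·VSL/VCL,
STR = 100·VSL/VAP, WOB = 100·VAP/VCL are reported half-up at 2 decimals,
so LIN = STR·WOB/100 holds within rounding; VSL ≤ VCL by the triangle
inequality. Ratios are undefined (NA) when their denominator is 0, as for
a perfectly immotile cell.

Grades follow the WHO four-class scheme — A fast progressive, B slow
progressive, C non-progressive, D immotile — operationalized as cut-offs
on VCL: A ≥ 50, B ≥ 25, C ≥ 6 µm/s, else D. The velocity rule was chosen
because it exactly reproduces the grade column of the bundled reference
parameter table (10/10); WHO manuals define grades via progressive
motility, which that table does not operationalize. All cut-offs are
arguments. Tracks shorter than 15 frames (≈0.5 s at 29.80 fps) are flagged
`insufficient` rather than graded — velocity estimates on tiny tracks are
unstable.

The reference parameter table has internal inconsistencies: two rows have
STR and WOB transposed relative to their definitions and three have LIN
inconsistent with the printed velocities. Only the five self-consistent
rows serve as ratio test vectors; all ten grades are used.

## Sharpness

SDF is the mean absolute difference between each pixel and its left and
lower neighbours over in-bounds pairs, divided by M×N; TDF is the mean
squared Sobel gradient magnitude S = √((Gx∗I)² + (Gy∗I)²) over interior
pixels, divided by M×N. The magnitude form is the Tenengrad convention
(the squared combination is what the measure's definition squares); a
plain-sum variant is available behind a flag. Borders are excluded rather
than padded — padding choices change values, exclusion is reproducible.
Sequence scores are normalized by the series maximum (all-zero series stay
zero). Both measures are zero iff the image is constant, are invariant to
intensity offsets, and do not increase under progressive blur; all three
properties are tested.

## The synthetic generator

`simulateVideo()` renders anti-aliased bright ellipses (head 8 × 4 µm,
oriented along the instantaneous velocity) over a uniform background with
additive Gaussian noise, and records the exact per-frame centroids,
presence flags, counts, and per-object kinematics computed by the motility
module itself on the true centroids — so pipeline recovery is compared
like for like, on the sampled polyline rather than a continuous curve.

The default scene is desk-scale: 512 × 512 px at 0.5 µm/px, 30 fps, 90
frames, 8 progressive (20–45 µm/s, forward zigzag: lateral sinusoid of
amplitude 1.5 µm, period 8 frames), 4 non-progressive (tethered jitter at
2–5 µm/s), 4 immotile cells and 5 single-pixel debris particles. Noise sd
is 3 gray levels, a realistic level for 8-bit flash-illuminated video.
Placement is random with rejection sampling toward a 25 µm minimum
same-frame separation; `wellSeparatedScene()` instead lays objects on
parallel lanes with moderate speeds so identities stay separated for the
whole clip, and `crowdedScene()` doubles the noise and relaxes separation.
One RNG stream per run, seeded from the config: the same seed reproduces
frames and truth bit for bit.

These scenes establish correctness of the algorithms, not field
performance: real recordings have flagella, uneven illumination, focus
drift, cell collisions and adhesion, and debris of arbitrary shape, none
of which the generator emulates. Passing the synthetic benchmarks
(counting error < 5 %, full-length tracking on separated scenes, VCL/VSL
recovery within 2 % noise-free and 10 % at default noise) shows the chain
measures what it defines; published recognition and tracking rates from
real videos are reproduced only at the level of their printed summary
tables, which ship with the package as reference data.

Problem sizes in the test-suite were chosen for quick, repeatable runs:
unit tests use 96–160 px scenes of 25–40 frames, and the end-to-end
benchmarks use the full 512 px default scenes.

## Known limitations

* No video decoding: inputs are numbered PNG/TIFF frame directories.
* Grayscale only; no shadow handling or colour background models.
* No appearance-based re-identification: after a long occlusion or merge,
  an identity resumes as a new track.
* ALH and BCF are not computed (not defined in the source platform).
* The mixture detector needs a burn-in and cannot see frame 0; counting
  and first-frame identity work use the static detector.
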
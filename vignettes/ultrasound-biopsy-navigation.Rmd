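---
title: "Tracked freehand ultrasound navigation: models, calibration and accuracy evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracked freehand ultrasound navigation: models, calibration and accuracy evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sononav)
```

## The navigation problem

Needle biopsies of small soft-tissue masses in the head and neck region are
difficult to navigate: conventional navigation systems register preoperative
CT/MRI to bony landmarks, and soft tissue far from bone shifts intraoperatively,
invalidating that registration. A tracked freehand ultrasound workflow avoids
the problem by registering the target *intraoperatively*: the lesion is imaged
in a 2-D B-mode frame, segmented, and its center mapped into the fixed 3-D
frame of an optical tracking camera (the *world* frame, mm). A tracked biopsy
needle is then guided to that world point by acoustic feedback, so the
operator never has to look away from the patient and has both hands free.

`sononav` implements this workflow as testable software: rigid-transform
algebra, probe and needle-tip calibration, lesion segmentation, target
registration, the three-tier alignment classifier with its tone mapping, a
phantom simulator with analytic ground truth, and the surgical-accuracy
analysis.

## Coordinate frames and the registration chain

Four frames are involved, all in millimetres:

* **world** — the tracking camera's fixed frame;
* **sono** — the tracking tool rigidly mounted on the ultrasound probe;
* **image** — the metric 2-D image plane (z = 0 by construction; pixels are
  0-based, origin top-left, columns lateral, rows axial);
* **needle** / **tip** — the needle's tracking tool and its calibrated tip.

A pixel centroid $(c, r)$ with spacings $(s_x, s_y)$ mm/px embeds as
$(c\,s_x,\; r\,s_y,\; 0)$ in the image frame, and the lesion's world position
is

$$
\mathbf{m}^{world} \;=\; {}^{world}T_{sono}\; {}^{sono}T_{image}\;
\mathbf{p}^{image},
$$

where ${}^{world}T_{sono}$ is the tracked probe pose at capture time and
${}^{sono}T_{image}$ is the probe calibration. The needle tip is likewise

$$
{}^{world}T_{tip} = {}^{world}T_{needle}\,{}^{needle}T_{tip}.
$$

Transforms are stored as `rigid_transform` objects that carry frame labels;
`compose()` refuses to chain mismatched frames, which catches the most common
bookkeeping error in tracking code at the call site. The convention is
column vectors, parent = M · child, quaternions in (w, x, y, z) order.
Rotations are re-orthonormalized by polar decomposition (nearest rotation in
the Frobenius sense) whenever the orthonormality error exceeds 1e-9, so long
composition chains cannot drift.

## Calibration

**Probe calibration** (`calibrate_probe()`) estimates the pixel spacings and
${}^{sono}T_{image}$ from captures of fiducials with known world coordinates.
Each world fiducial is first mapped into the sono frame through the inverse
probe pose at its capture. Because a rigid map preserves distances, the
squared sono-frame distance between two fiducials equals
$s_x^2\,\Delta c^2 + s_y^2\,\Delta r^2$ — linear in $(s_x^2, s_y^2)$ — so the
anisotropic spacings come from a least-squares fit over all pairs. The rigid
part is then the closed-form absolute-orientation (SVD/Kabsch) solution
between the metric pixel points and the sono-frame points, with the
determinant correction that keeps the rotation proper for planar point sets.
The residual RMS is the fiducial registration error (FRE). At least three
non-collinear fiducials are required; on noiseless synthetic input the
parameters are recovered to machine precision, and under Gaussian fiducial
noise the error shrinks with $\sigma$ as expected (tested over
$\sigma \in \{1, 0.1, 0.01\}$ mm at n = 100).

**Tip (pivot) calibration** (`pivot_calibrate_needle()`) models the tip as a
pure translation $\mathbf{p}$ in the needle-tool frame — a point target needs
no tip orientation — and solves the stacked linear system
$R_i \mathbf{p} + \mathbf{t}_i = \mathbf{w}$ over all pivot poses for
$\mathbf{p}$ and the fixed world pivot $\mathbf{w}$. Observability requires
rotational diversity; the smallest singular value of the design matrix must
exceed 1e-6 or the fit is refused. The needle direction is taken from the
tool-frame shaft axis, (0, 0, 1) by default and configurable.

## Segmentation

The original system localized the lesion with a pretrained deep network; the
network weights are external, so `detect_lesion()` provides a classical
detector behind the identical interface (binary mask, sub-pixel area
centroid, equivalent diameter), letting a learned backend drop in without API
change, and `load_mask_as_result()` accepts externally produced masks
directly. The detector smooths with a Gaussian (σ = 2 px), thresholds dark
regions at 0.5 × the image median (a hypoechoic lesion is darker than
speckled background), filters connected components by area (50–5000 px²) and
circularity (4πA/P² ≥ 0.6), and keeps the highest-contrast component.

One numerical subtlety: the contour of the *smoothed* thresholded mask sits
where the blur's coverage fraction equals the threshold fraction, which
biases the measured area. The detector therefore uses the smoothed mask only
for detection and takes its final mask from the unsmoothed image (the
raw-threshold component with maximal overlap), which makes the centroid of a
symmetric noiseless lesion exact and the equivalent diameter unbiased.

## Alignment classification and acoustic feedback

With a registered target sphere (center $\mathbf{m}$, radius $r$) and the
needle as a ray from tip $\mathbf{p}$ along unit direction $\mathbf{d}$, the
classifier computes the perpendicular distance from the extended needle line
to the center,

$$
\ell = \lVert (\mathbf{m}-\mathbf{p}) - ((\mathbf{m}-\mathbf{p})\cdot
\mathbf{d})\,\mathbf{d} \rVert ,
$$

and returns **2** (optimal insertion angle — the line pierces the sphere)
when $\ell \le r$ and the target lies ahead of the tip, **1** (approaching)
when $r < \ell \le k\,r$ ahead, and **0** (miss) otherwise. Squared forms are
used internally; roots are taken only for reporting. Design choices where the
workflow description leaves room:

* *Ray, not line, semantics*: an intersection behind the tip is a miss —
  pointing away from the patient cannot be a hit.
* *Near band*: the "approaching" tier has no stated threshold; it is the
  metric band $k r$ with `near_factor` k = 2 by default, configurable.
* *Tie-breaks*: boundaries are inclusive (tangent at $r$ is a hit, at $kr$
  is tier 1) — deterministic and testable.

The tone mapping is fixed: 0 → 200 Hz, 1 → 350 Hz, 2 → 440 Hz.
`run_session()` replays a tracked needle stream at the navigation update rate
(20 Hz default), evaluating the most recent pose at or before each tick, one
tone event per tick with markers at tier transitions. The insertion depth
reported to the operator is the along-axis distance from the tip to the
closest approach to the center; when the line pierces the sphere the distance
to the proximal surface, $\text{depth} - \sqrt{r^2 - \ell^2}$, is reported as
well (the workflow does not pin down which surface the displayed depth refers
to, so both are exposed).

## The phantom simulator

`build_eval_phantom()` reproduces the accuracy phantom: a hollow sphere of
16 mm inner diameter with a concentric 8 mm spherical lesion and two surface
notches 19 mm apart on a line through the center; their midpoint is the
"true" reference. `render_bmode()` renders the frame a calibrated probe pose
would see — pixels whose world point falls inside the lesion sphere take the
lesion intensity — with unit-mean multiplicative log-normal speckle
(σ = 0.3 by default). Tracking noise is isotropic Gaussian on translations
with σ = 0.25 mm, the tracker's quoted intrinsic error; rotational noise is
off by default because the quoted figure is a single translation-scale
scalar. Sphere membership is tested with an inclusive 1e-9 relative
tolerance: with the default geometry (4 mm radius at 0.1 mm/px, an exact
40 px disc) many pixel lattice points lie exactly on the boundary, and
round-off from the pose chain must not flip them asymmetrically.

What the simulator deliberately does **not** emulate: attenuation, shadowing
and other echo physics, the shell wall and water bath, needle bending, and
probe-image latency. Passing tests therefore demonstrate that the geometric
chain, calibration and analysis are correct and that the pipeline tolerates
tracker-scale noise — not that the detector would segment clinical B-mode
images, which is the trained network's job.

All stochastic operations are reproducible from (seed, parameters) alone.

## Accuracy analysis and rounding conventions

`evaluate_table()` reproduces the accuracy study: per-trial euclidean
deviations from the marker-midpoint reference, the mean measured position E,
the maximum surgical deviation, and the count of trials within the lesion
radius (4 mm). Three reporting conventions matter and are implemented
explicitly:

* **Reference precision.** Tracked positions are recorded at 0.01 mm, so the
  marker midpoint is rounded to 2 decimals before deviations are taken
  (`reference_decimals = 2`; `NULL` gives the exact midpoint). The packaged
  ten-trial table's deviation column is reproduced to 4 decimals only under
  this convention — e.g. trial 1 yields 3.0182 mm against the recorded
  reference but 3.0156 mm against the exact midpoint.
* **Rounding mode.** Half-away-from-zero, not banker's rounding: mean
  components (54.836, 91.073, −1006.425) report as (54.8, 91.1, −1006.4).
* **Maximum surgical deviation.** Defined operationally as the distance from
  the 1-decimal-rounded mean E to the reference, which gives 2.5287 mm on the
  packaged table; the unrounded mean gives ≈ 2.49 mm and is available via
  `decimals = NULL`. The quantity is a deviation of the *mean* position —
  the conventional naming ("maximum" vs "average") is ambiguous in the
  source material, and the package simply documents what it computes.

```{r evaluate}
markers <- eval_phantom_markers()
report <- evaluate_table(eval_phantom_trials(), markers$a, markers$b,
                         hit_radius = 4)
report
```

## Problem sizes and performance

The test suite and the acceptance script use the study's own scales: the
ten-trial packaged table; 128×128 rendered frames; 100 simulated trials at
tracking σ = 0.25 mm for the stochastic band; 1000 random configurations for
the line–sphere oracle (sampled at 4001 points per ray, skipping
near-tangent configurations that point sampling cannot resolve); 50 pivot
poses and 10 fiducials for calibration recovery; and 10 000 pose samples for
the noise-calibration check. The full suite runs in well under a minute on
one CPU.

## Known limitations

* The classical detector assumes a single dominant hypoechoic blob; it is a
  stand-in for the trained network on real anatomy, not a replacement.
* The sphere model ignores pixel-spacing anisotropy beyond using the mean
  spacing for the radius.
* No temporal (latency) calibration between image stream and tracker, no
  speed-of-sound correction, and no statistical inference on the accuracy
  numbers — the analysis reports the study's descriptive quantities only.
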
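---
title: "Vessel-based registration of tracked ultrasound to a centre-line model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-based registration methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselreg)
```

## The problem

During laparoscopic liver surgery the preoperative CT model must be
aligned to the patient so that tumours and vessels can be projected into
the surgeon's view. Surface-based alignment is hard through a trocar;
the liver's vessel tree, however, is clearly visible in intraoperative
B-mode ultrasound as dark (hypoechoic) tubes. `vesselreg` implements a
*locally rigid*, vessel-based registration: vessel centre points are
segmented from a tracked 2D ultrasound sweep, reconstructed into a 3D
point cloud \(P\), and a preoperative vessel centre-line graph \(G\) is
rigidly registered to \(P\). A rigid model is accepted to be valid only
near the region that was scanned; error is expected to grow with
distance from it, which the evaluation module quantifies.

The operating-room inputs (tracked probe, calibrated scanner, CT
segmentation) are replaced for development and testing by a synthetic
tube-phantom simulator, so every stage of the chain runs and is tested
offline.

## Per-frame segmentation

Each frame is pre-blurred once with a Gaussian (`blur_sigma`, default
2 px) and two feature images are computed from the denoised frame.

**Vesselness.** The multi-scale Hessian line filter: with eigenvalues
\(|\lambda_1| \le |\lambda_2|\) of the scale-normalised Hessian
(Gaussian smoothing at \(\sigma\), central second differences,
\(\times\sigma^2\)),

\[
v_0 = \begin{cases}
0 & \lambda_2 < 0\\[2pt]
e^{-R_B^2 / 2\beta^2}\left(1 - e^{-S^2/2c^2}\right) & \text{otherwise,}
\end{cases}
\qquad R_B = \lambda_1/\lambda_2,\quad S = \sqrt{\lambda_1^2 + \lambda_2^2},
\]

with \(\beta = 1\) and \(c = 10\). Zeroing the \(\lambda_2 < 0\) branch
makes the filter respond to dark tubes on a bright background, which is
how vessels appear in B-mode. The final image takes, per pixel, the
maximum over the scale set, recording the winning scale.

*Scale set.* The default is `c(2, 3, 4.5, 6)` px — far below the
vessel radius. This is deliberate. The boundary of the thresholded
response region of a dark tube sits where \(\lambda_2\) changes sign;
for a tube of diameter \(d\) that boundary is displaced outward from
the true wall by roughly \(\sigma^2/d\) px (curvature of the smoothed
edge). Scales of order \(d/2\) — the classical choice for *detection* —
therefore inflate the contour by many pixels and make contour-derived
diameters useless, while small scales keep the thresholded region
faithful to the wall and still localise the centre line. Detection
robustness at small \(\sigma\) is restored by the shared pre-blur and
by the second feature image, which carries the width information
explicitly.

**Dip image.** Along each beam line (image columns, linear probe), for
a centre row \(x\) and candidate width \(v\), three window means are
taken over the inclusive intervals \(a=[x+v/2, x+v]\),
\(b=[x-v, x-v/2]\), \(c=[x-v/2, x+v/2]\) (half-widths `floor(v/2)`;
windows crossing the column border are skipped — partial windows would
bias the means). If \(c < a\) and \(c < b\), every pixel in
\([x-v/2, x+v/2]\) receives the candidate value
\(\min(a-c,\, b-c)\), and a pixel's final value is the maximum over all
\((x, v)\) covering it. Widths iterate over \([v_{\min}, v_{\max}]\)
(default 40–100 px, i.e. 3–9 mm hepatic calibre at 0.1 mm/px) with a
stride (default 4 px) that trades width resolution for speed; the test
oracles use stride 1. A coarse-to-fine variant
(`dip_image_pyramid`) runs the scan on a block-averaged image first and
rescans at full resolution only the columns whose coarse response
reaches a quarter of the coarse maximum — a factor-2 safety margin
under the half-of-maximum seed threshold used downstream.

**Seeds, prior, contours, ellipses.** Candidate seeds are pixels
passing both thresholds: vesselness \(\ge T_e\) and dip \(\ge\) half of
the dip-image maximum. 8-connected components of the thresholded
vesselness image that contain a seed and whose median raw intensity
lies in the lumen prior (default `[0, 80]` of 255) are vessels; the
median is used because contour bleed drags a mean. Their outer boundary
polygons are extracted (holes ignored) and a direct least-squares
ellipse is fitted to each contour. A fit is accepted when the
short-axis diameter \(2b\) lies in \([v_{\min}, v_{\max}]\) and the
axis ratio \(b/a\) exceeds 0.5 — a smaller ratio means the vessel was
cut at under \(\sim 30^\circ\) to its axis, where the centre estimate
is unreliable. The short-axis rule is checked first so the recorded
rejection reason is deterministic. The vessel centre is the fitted
ellipse centre (not the contour centroid).

*Calibrating \(T_e\).* The method fixes \(T_e\) once per B-mode
configuration. For the synthetic imaging conditions shipped with the
package it was calibrated on rendered 6.5 mm tube frames so that the
fitted short-axis diameter reproduces the ground truth (mean 6.53 mm,
SD 0.006 mm at speckle level 8), and frozen at `T_e = 0.12`. At the
default small scales the recovered diameter is insensitive to \(T_e\)
across 0.05–0.3; the value mainly clears the speckle response floor.

## Reconstruction

Pixel centres are 0-based `(column, row)`; the in-plane position is
`(column * scale_x, row * scale_y, 0)` mm with the x-axis along columns
— a convention the package fixes since tracking stacks differ. Each
centre is mapped by the probe calibration (image plane to sensor) and
the frame's tracking pose (sensor to tracker) into world coordinates.
Frames take the tracked pose nearest in time, without interpolation;
interpolation is an extension point.

## Registration

**Initialisation.** One manually identified landmark (typically a
bifurcation) with two branch directions on each side defines the
initial alignment: the rotation is the orthogonal Procrustes solution
aligning the orthonormal frame built from \((u, v)\) — \(e_1 = u\),
\(e_2\) the normalised component of \(v\) orthogonal to \(u\),
\(e_3 = e_1 \times e_2\) — to the corresponding frame in the cloud; the
landmark pair fixes the translation. Direction pairs subtending
\(\le 5^\circ\) are rejected as degenerate.

**ICP.** The refinement minimises point-to-*line* distances: points are
mapped into model space, matched to the exact nearest point on the
polyline segments (projections clamped to segment ends, ties broken to
the lowest edge/segment id for determinism), and updated with the
closed-form SVD rigid fit. The loop stops when the RMS residual changes
by less than `rms_change_tol` (default \(10^{-4}\) mm) or after
`max_iterations` (default 100); an optional gate excludes
correspondences beyond `max_correspondence_distance`. A point-to-point
mode against a densely resampled centre line is provided purely as a
cross-check; both modes agree to within 0.1 mm RMS on the test suite.
Both directions of the result are reported (`g_from_p`, `p_from_g`,
exact inverses) so navigation (CT into patient) and residual
computation are unambiguous. No deformation model is fitted — the
design hypothesis is that a rigid alignment within a small region of
interest suffices, and the evaluation quantifies where it stops
sufficing.

Closest-point queries use a vectorised linear scan over all segments.
At this problem scale (hundreds of segments, thousands of points) the
scan is exact and far from the runtime budget, so no spatial index is
layered on top of it; exactness and tie behaviour stay trivially
auditable.

## Evaluation

Target registration error at landmark pairs identified in both spaces
is computed in P-space (world): \(\mathrm{TRE}_i = |T\,g_i - p_i|\)
with \(T\) mapping model to world. `stratify_errors` reports, relative
to a reference point (the landmark that drove the local registration),
the fraction of landmarks within a radius whose error stays below a
threshold, plus mean error per 5 mm distance bin for
error-versus-distance curves; 5 mm is a readability choice.
`navigation_error` is numerically identical to `compute_tre` but tags
the report as coming from a held-out sweep, where the number compounds
registration, tracking and probe-pressure errors.

## The synthetic phantom

The simulator emulates what the operating room provides:

* tubes as capsule sweeps of polyline centre lines (diameters in the
  3–9 mm range; presets: a straight 6.5 mm tube, a Y-branch, a
  multi-tube phantom with one bifurcation, and a liver-like tree with
  8 degree-3 bifurcations spanning ~100 mm);
* B-mode appearance as a two-level image — hypoechoic lumen (default
  30) on speckled background (default 120) — with multiplicative
  Gaussian speckle on the background and additive Gaussian in the
  lumen (`speckle_sigma`, default 8 grey levels), plus optional
  column-aligned shadow bands below a tube, consistent with the
  column beam model;
* freehand sweeps as linearly/geodesically interpolated pose paths with
  per-frame Gaussian jitter (default 0.3 mm / 0.3°) standing in for
  jerky freehand motion;
* ground truth: exact per-frame plane/centre-line intersections in both
  pixel and world coordinates, and a known rigid misalignment,
  optionally composed with a smooth deformation (a sum of four random
  cosine modes, wavelengths at or above `smooth_scale`, total peak
  amplitude `smooth_amplitude`) emulating the shape change between
  insufflated and non-insufflated anatomy.

All randomness flows from explicit seeds; identical specifications
yield identical bytes. What the simulator does **not** model: acoustic
physics (attenuation, refraction, anisotropic speckle texture),
respiration and cardiac pulsation, probe-pressure deformation, tracker
field distortion, and calibration error. Passing tests on the phantom
therefore demonstrate the correctness and self-consistency of the
algorithmic chain under controlled noise — not clinical performance on
tissue.

## Problem sizes and numerical choices

The shipped experiments use 160-frame sweeps at 640×480 px and 0.1
mm/px for diameter recovery, a 200-frame sweep of the multi-tube
phantom for registration residuals, 100 trials for ICP
parameter-recovery statistics and 20 seeds for the deformation
error-growth trend; these sizes give stable statistics at desk scale.
Other choices worth recording:

* Gaussian kernels are truncated at \(3\sigma\) with mirror (reflect)
  boundary handling;
* dip windows are inclusive integer intervals with half-width
  `floor(v/2)` — documented so the brute-force oracle matches exactly;
* the ellipse fit solves the direct least-squares conic with the
  ellipse-specific normalisation and converts to geometric form via the
  eigen-decomposition of the quadratic form; fewer than 5 points or a
  collinear contour yield an explicit degenerate-fit flag;
* the degenerate pyramid (`pyramid_levels = 1`) is bit-identical to the
  full scan; an all-zero dip image produces an empty seed mask rather
  than an all-true one;
* rotations are validated to be proper (orthonormal, det +1, both to
  1e-9) at construction, so reflections cannot leak into results.

## Known limitations

* The segmentation assumes dark lumens on brighter tissue; contrast
  inversions (e.g. highly echogenic thrombus) are out of scope.
* Beam lines are modelled as image columns (linear probe); curvilinear
  geometry is not supported.
* The landmark correspondence is supplied manually (or, on synthetic
  data, from ground truth); automatic correspondence detection is not
  attempted.
* Timing is logged but not guaranteed; the package aims at
  reproducibility, not real-time operation.
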
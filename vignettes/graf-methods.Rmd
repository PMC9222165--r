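---
title: "Automated Graf hip measurement: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated Graf hip measurement: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grafhip)
```

## The clinical problem

Graf's method is the standardized ultrasound technique for screening
developmental dysplasia of the hip (DDH) in infants. On a coronal
"standard plane" — a section showing a straight, near-vertical ilium, the
lower limb of the os ilium, and the labrum — the sonographer draws three
lines: the **baseline** (tangent along the ilium echo), the **bony roof
line** (from the lower limb point tangent to the bony roof), and the
**cartilage roof line** (from the bony rim point through the labrum
center). The angle α between baseline and bony roof line grades bony
coverage; β between baseline and cartilage roof line grades cartilaginous
coverage. A hip with α ≥ 60° is type I (mature); smaller α indicates
an immature or dysplastic configuration, represented here by the binary
type II class.

`grafhip` implements the measurement side of a fully automated pipeline:
given per-structure bounding boxes from *any* detector (the package ships
a heuristic one and an oracle for synthetic data; a neural detector plugs
in as a `function(image, frame_index)`), it validates the detections,
scores how "standard" each video frame is, and measures α, β on the best
frame.

## Coordinate convention

Images are integer matrices with the origin at the top-left pixel.
Pixel coordinates are 0-based `(column, row)` pairs: the **column**
index increases with depth (to the right, toward the far field) and the
**row** index increases caudally (downward), so a well-aligned ilium runs
vertically down the image. Boxes are half-open,
`[x_min, x_max) × [y_min, y_max)`. Frame indices, in contrast, are
1-based, as is idiomatic in R.

## Standard-plane scoring

A frame's score is

$$S = \lambda_1 S_{\text{lower limb}} + \lambda_2 S_{\text{labrum}}
    + \lambda_3 S_{\text{bony rim}} + \lambda_4 S_{\text{ilium}},$$

where the first three terms are detector confidences and the ilium term
is a composite shape score

$$S_{\text{ilium}} = \lambda_5 S_{\text{conf}} + \lambda_6 S_{\text{hw}}
                   + \lambda_7 S_{\text{angle}}, \qquad
  S_{\text{angle}} = 1 - |\theta| / 10 .$$

* `l1 = 3, l2 = l3 = 1`: the lower limb is weighted three-fold because no
  Graf diagnosis may be made without it, its deep location makes it the
  structure most sensitive to penetration depth, and it anchors the α
  measurement.
* `l4 = 1`: no published value exists for the ilium's frame-level weight;
  the package defaults to symmetry with the labrum/bony-rim terms, on the
  argument that the ilium's special role is already captured *inside*
  its composite score. It is configurable in `graf_weights()`.
* `l5 = 0.2, l6 = 0.3, l7 = 0.5`: confidence mostly reflects visibility;
  the height–width ratio `S_hw` of the ilium box and the moment-based
  tilt θ carry the straightness/verticality information, hence their
  larger weights.
* `S_angle` is deliberately **not clamped** below zero — an ilium tilted
  beyond 10° actively penalizes the frame — and `S_hw` is not normalized,
  because scores are only ever compared *within* one video.

θ comes from the second-order image moments of the expanded ilium box
(margin 0.1 per side; the expansion guarantees the whole ilium is inside
the region even for a tight detector box). With raw moments
$M_{pq} = \sum_i \sum_j i^p j^q V(i,j)$ (columns $i$, rows $j$, 0-based),
centroid $(x_c, y_c) = (M_{10}/M_{00}, M_{01}/M_{00})$ and central terms
$a, b, c$, the principal axis is $\tfrac12 \operatorname{atan2}(2b, a-c)$.
The returned θ is the deviation of the major axis from the image
vertical, in (−90°, 90°], positive when the top of the axis leans deep.
The two-argument arctangent resolves the quadrant ambiguity of the
half-angle form; exactly isotropic regions (a = c, b = 0 within 1e-12)
return 0 by convention. Frames whose detections violate the clinical
layout rules score 0 and can never be selected in dynamic mode.

```{r}
f <- render_frame(phantom_spec(noise_sigma = 0))
fs <- frame_score(f$image, f$true_boxes)
c(S = fs$s, theta = fs$s_ilium$theta, shw = fs$s_ilium$shw)
```

## Layout validation

The layout rules R1–R4 in `check_relative_positions()` are this
package's concretization of "the relative positions are checked": the
lower limb must be deeper and more caudal than the ilium (R1), the bony
rim caudal to the ilium's cranial edge and superficial to the lower limb
(R2), the labrum superficial to the bony rim (R3), and all box centers
inside the image (R4). Absent structures are skipped rather than failed,
so a partial detection set can still be valid. In static mode a
violation only warns (the plane was vouched for by whoever supplied it);
in dynamic mode it zeroes the frame score.

## Angle measurement

Inside each (0.1-expanded) box the structure is segmented by
maximum-entropy thresholding: the threshold maximizes the summed Shannon
entropies of the normalized background (≤ t) and foreground (> t)
histograms, searched exhaustively over all 255 splits with both classes
non-empty, smallest t on ties. Only the largest 8-connected foreground
component is kept, which suppresses speckle islands. Landmarks are then
computed from mask geometry:

* **lower limb point** — centroid of the lower-limb mask;
* **labrum center** — centroid of the labrum mask;
* **bony rim point** — most superficial (minimum-column) mask pixel,
  most cranial on ties;
* **bony roof point** — the tangent point from the lower limb point to
  the contour formed by the caudal half of the ilium mask together with
  the bony rim mask: the contour point such that the whole contour lies
  on the deep side of the pivot→point line (collinear ties go to the
  farthest point).

Centroids and tangent constructions were chosen over gradient-based
operators because they are robust on small masks, parameter-free, and
exactly testable against brute-force oracles; each sits behind a small
function so alternative strategies can replace them.

The baseline is fitted, not assumed: the superficial edge pixel of every
mask row is collected, a total-least-squares line is fitted (eigenvector
of the 2×2 covariance), and the line is translated perpendicular toward
the superficial side until all edge points lie on or deep to it — a true
tangent of the uppermost ilium. At least 5 edge rows are required.

α and β are acute angles between undirected lines,
`arccos(|d1 · d2|) ∈ [0°, 90°]`. This is adequate for the type I/II
range implemented here; decentered hips with β > 90° would need a
directed convention and are out of scope, as are Graf types D/III/IV.
The type boundary is inclusive: α = 60° is type I.

## The synthetic phantom

`render_frame()` draws a bright ilium band (width 8 px), a diamond bony
rim, and disc lower limb/labrum on a dark background (background 20,
default contrast 200, additive Gaussian noise, default σ = 3). The
construction works backwards from the requested angles: the baseline and
bony roof line meet at the band's caudal tip with exactly `alpha_true`
between them; the lower limb disc sits on the roof line; the rim diamond
is tucked just deep of the roof line (1.5 px clearance) so the tangent
from the lower limb point touches the band tip *on* the true roof line;
the cartilage roof line leaves the diamond's superficial vertex at
exactly `beta_true` from the baseline and carries the labrum disc. The
rim is a diamond rather than a disc so its minimum-column landmark is a
sharp, unambiguous vertex. Recomputing the angles from the stored
landmarks therefore reproduces the requested values to machine
precision, and the measurement error of the full pipeline on phantoms
(≈ 1° mean absolute error) is attributable to rasterization and
segmentation alone.

```{r}
f <- render_frame(phantom_spec(alpha_true = 65, beta_true = 55,
                               noise_sigma = 0))
angles_from_landmarks(f$true_landmarks, f$true_baseline)
measure(f$image, f$true_boxes)
```

`render_video()` emulates a probe sweep as a tilt trajectory. A rigidly
rotated phantom would measure the same angles at every tilt, so frame
choice would not matter; real off-plane sections distort the apparent
joint geometry. The generator therefore shifts the *rendered* angles by
`obliquity_gain` (default 0.4° per degree of tilt): each frame's
`true_alpha`/`true_beta` is its apparent, rendered value, while the
video-level `alpha_ref`/`beta_ref` keep the hip's reference angles. The
best frame is the one minimizing |tilt| among frames with all four
structures visible, earliest on ties. The sweep used across the test
suite is 9 frames over [−10°, 10°] with a sub-degree random offset of
the sweep center, which keeps the best frame unique without making the
task trivial.

What the phantom does **not** emulate: speckle statistics (noise is
additive Gaussian only), attenuation and acoustic shadowing, soft-tissue
clutter, probe pressure deformation, and pathological (type D/III/IV)
morphology. Passing phantom tests therefore demonstrates correctness of
the geometry, scoring, and measurement machinery — not clinical-grade
performance on real ultrasound, which depends on the plugged-in
detector.

## Numerical choices and degenerate inputs

* Exhaustive threshold search with strict-improvement comparison gives
  the smallest maximizer deterministically; single-level histograms are
  an error, as are empty masks and all-zero moment regions.
* Box expansion floors minima and ceils maxima, then clips to the image.
* Tangent selection runs in one pass under the precondition that the
  contour spans < 180° as seen from the pivot (always true here: the
  pivot is the lower limb point, deep-caudal of the contour); tests
  verify the O(n²) one-sided property directly.
* `select_standard_frame()` errors with "no usable plane" when every
  frame scores 0, mirroring the clinical rule that no diagnosis is made
  without the required structures.
* ICC is the two-way random-effects, absolute-agreement, single-measures
  form ICC(2,1) — the standard choice for method-vs-rater agreement —
  with the F-based 95% interval (Satterthwaite denominator df); the form
  of the interval matches common references (verified against pingouin's
  ICC(A,1) during development). Zero-variance data define ICC = 1, and
  two constant identical raters define κ = 1.
* Sample (n−1) standard deviations are used throughout, matching the
  Bland–Altman convention; limits of agreement are mean ± 1.96 SD.

## Problem sizes used in the test suite

The suite exercises 256×256 phantoms: an 18-point α × β recovery grid
(noise-free with ground-truth boxes, and σ = 5 with the heuristic
detector), 20 seeded 9-frame sweep videos for selection recovery and the
scoring-vs-confidence-sum comparison, 100-histogram and 100-region
oracle sweeps, and n = 1000 simulations for ICC recovery. These sizes
give stable statistics while keeping the whole suite fast enough to run
routinely.

## Known limitations

Binary type I/II classification only; α and β reported as acute angles;
landmark operationalizations are geometric stand-ins for a sonographer's
judgement; the bundled detector is a deterministic heuristic intended
for phantom-like images, not clinical data.
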
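---
title: "Quantifying the deviation between the epicondylar and flexion-extension axes of the elbow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the deviation between the epicondylar and flexion-extension axes of the elbow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Total-elbow implants and hinged external fixators are aligned on the
medial and lateral epicondyles because they are palpable; the hinge the
joint actually uses is the flexion-extension (F-E) axis of the trochlea.
`elbowaxes` measures, on a triangulated distal-humerus surface, how far the
epicondylar axis deviates from the F-E axis — as per-plane rotational
differences and as translational offsets of the axis exit points from the
epicondyles — and provides a synthetic-specimen generator with exact ground
truth so that every stage is validated by parameter recovery rather than by
eye.

## Axes

Three axes are built per specimen, all as infinite lines (`line3`):

* **Epicondylar axis.** Each epicondyle is the arithmetic mean of three
  manual picks (the clinical palpation gesture); the axis joins the means,
  oriented lateral to medial. Averaging three picks with independent
  picking noise of SD $\sigma$ leaves an epicondyle error of scale
  $\sigma/\sqrt{3}$ per coordinate.
* **Long (intramedullary) axis.** Five slicing planes are placed at
  fractions 0.1–0.9 of the marked diaphysis/metaphysis band, normal to a
  provisional shaft direction; the primary (largest-perimeter) contour of
  each slice is fitted by a planar ellipse
  $P(t) = a\cos(t)\,u + b\sin(t)\,(n \times u) + C$ minimizing the radial
  deviation of the contour points, and the axis is the total-least-squares
  line through the five centers, oriented distal to proximal. Slicing a
  (possibly oblique) elliptical shaft still yields ellipses centered on the
  true axis, which is why the recovered direction is insensitive to the
  provisional direction; one re-slicing pass with the fitted axis (default
  on) removes the residual dependence.
* **True F-E axis.** A circle is fitted to the points picked on the deepest
  part of the trochlear groove by minimizing
  $\sum_i d_i^2,\; d_i^2 = (\rho_i - r)^2 + h_i^2$, where $\rho_i$ and
  $h_i$ are the in-plane and out-of-plane distances from the candidate
  circle plane. The F-E axis is the circle normal through the center,
  oriented into the lateral-to-medial hemisphere.

### Numerical choices in the fits

The circle fit is Gauss-Newton with Levenberg-Marquardt damping adapted by
the gain ratio; the Jacobian uses central differences. Initialization is
the principal plane of the points plus a Kåsa algebraic circle fit within
it. The radius is profiled out in closed form (its optimum given center and
normal is the mean in-plane distance), which removes the center-radius
valley that otherwise slows convergence badly on partial arcs. Stopping:
relative objective decrease below $10^{-14}$, step norm below $10^{-12}$,
three consecutive near-zero-progress steps, or less than $10^{-6}$
relative progress over ten iterations; the iteration budget is 100, and a
budget-capped run is still flagged converged when the model-predicted
remaining decrease is below $10^{-5}$ of the objective (flat-valley
partial-arc fits). Non-convergence is a flag on the result, never an
exception. Signed radial residuals (positive = outside the circle within
its plane) and out-of-plane residuals are reported per point.

The ellipse fit runs in 2D plane coordinates (center, two radii, optional
orientation angle; an axis-aligned mode is available) with the residual
defined as the radial deviation along the ray from the center,
$\rho_i - ab/\sqrt{(b\cos\psi_i)^2 + (a\sin\psi_i)^2}$. Both fits agree
with independent grid-plus-Nelder-Mead oracles to well below $10^{-6}$
relative in the test suite.

The provisional shaft direction joins the centroids of the most distal and
most proximal 10% vertex slabs; the slab axis is anchored on the
trochlear-groove centroid (groove → farthest vertices), because the wide
articular mass can dominate a plain principal-axis heuristic and the
anchored version is invariant to arbitrary rigid motion of the input.

Plane-mesh sections nudge the plane by $10^{-6}$ mm when a vertex lies
exactly in it, so every intersection is a clean edge crossing and results
are deterministic. Line-mesh intersection is Möller-Trumbore over all
triangles with hits merged within $10^{-6}$ mm along the line.

## Anatomical frame and signed conventions

The coronal plane is parallel to both the long and F-E axes (normal
$\propto$ long × F-E, oriented anteriorly); the axial plane transects the
long axis; the sagittal plane completes the orthogonal triad, its normal
being the in-plane (lateral-to-medial) component of the F-E direction. The
three normals are mutually orthogonal by construction and asserted to
$10^{-9}$ on every call.

Per-plane signed differences are right-hand-rule angles measured **from**
the projected F-E axis **to** the projected epicondylar axis about oriented
normals: medial (sagittal → flexion +), distal (axial → varus +), anterior
(coronal → external +), after orienting both axes lateral-to-medial to
remove 180° ambiguity. Plane-to-label mapping: coronal =
external/internal, sagittal = flexion/extension, axial = varus/valgus.
Left-side specimens reverse the rotation sense so mirrored anatomy reports
identical signs; offsets are resolved on the signed directions and are
mirror-invariant automatically.

**The sagittal channel is intrinsically ill-conditioned.** Any orthogonal
frame derived from the long and F-E axes places the F-E direction in the
medial-proximal plane, so its sagittal projection has magnitude
$|\cos\alpha|$ — about 0.1–0.2 for anatomical inclinations $\alpha$ of
77–84°. The flexion difference is therefore an angle between two *small*
projections: a perturbation that moves an axis by $x$° in the axial or
coronal plane perturbs the flexion reading by roughly
$x / |\cos\alpha| \gg x$. The tests assert exact own-channel recovery for
all three channels and sub-0.2° cross-talk between the two
well-conditioned channels (axial, coronal), and treat the flexion channel
as a derived, low-precision quantity. When the sagittal projection of the
F-E axis vanishes entirely ($\alpha = 90°$), the component is
reconstructed from the projected difference vector of the two axes.

## Translational offsets

The F-E axis exits the surface at the most medial (trochlear point) and
most lateral (capitellum point) line-surface intersections. The medial /
lateral offsets are the displacements of these points from the medial /
lateral epicondyle (structural pairing; a warning is issued if the
distance-nearest pairing disagrees), resolved along anterior(+),
medial(+), distal(+) — the distal-proximal component is also labelled
inferior-superior. The absolute offset is the Euclidean norm and the
Pythagorean identity is asserted on every record. For the overall axis
offset the F-E axis is translated (perpendicular to itself) through the
lateral epicondyle; its most medial surface intersection is the medial
humerus intersection point, and its displacement from the medial
epicondyle is resolved the same way. When the translated line crosses the
medial epicondylar mass near-tangentially this point is intrinsically
sensitive to landmark noise — a property of the measurement, not of the
implementation.

## A geometric identity couples the rotational and translational deviations

Both exit points lie on the F-E axis, so with $L$ the exit separation,

$$\mathrm{epi}_{med} - \mathrm{epi}_{lat} \;=\; L\,\widehat{fe} \;+\;
  (o_{lat} - o_{med}),$$

where $o_{med}, o_{lat}$ are the translational offset vectors. The
epicondylar *direction* — hence every per-plane rotational difference — is
completely determined once the six translational components, $L$ and
$\alpha$ are fixed. Two consequences shape the package:

1. The synthetic generator cannot realize an arbitrary triple of per-plane
   rotational offsets together with six prescribed translational
   components. Its `solve` mode pins the two well-conditioned rotational
   offsets (varus, external) exactly by solving $(\alpha, L)$ with a damped
   Newton iteration and reports the realized flexion value in the ground
   truth. At the default construction values the solution is
   $\alpha \approx 76.9°$, $L \approx 59.8$ mm and the realized flexion is
   $+9.34°$.
2. Within the anatomically plausible band ($\alpha, \beta \in
   [70°, 110°]$) the sagittal difference always exceeds the axial one in
   magnitude (the anterior component of the epicondylar direction is fixed
   by the A-P offset asymmetry, and the sagittal projection divides it by
   the smaller denominator), so cohort-mean summaries in which flexion is
   *smaller* than varus cannot be reproduced by any single specimen under
   these definitions. The acceptance suite documents this honestly: the
   flexion construction target is left failing with the realized value
   reported alongside.

## The synthetic specimen

A specimen is a watertight triangle surface built from four closed parts in
a canonical right-side frame (medial = +x, anterior = +y, proximal = +z):
an elliptical shaft (default radii 11 × 9 mm, length 80 mm, optional
symmetric-arc coronal bow), an articular spool — a surface of revolution
about the F-E axis whose profile has a strict minimum at the ground-truth
groove circle (default radius 12 mm), a medial trochlear ridge and a
capitellar bulge, with end caps centered exactly on the axis so the true
exit points are mesh vertices — and two spherical epicondylar protrusions
(default radius 10 mm) whose apices are the epicondyles, placed to realize
the requested translational offsets exactly. Left-side specimens are the
mirror image with flipped winding.

Landmarks: three picks per epicondyle (tangential Gaussian jitter,
re-projected to the protrusion surface), 20 groove points on the
deepest-groove circle over a 220° arc (angular, radial and axial jitter),
and the shaft band as fractions of the mesh extent along the provisional
direction. Zero jitter is the default: the acceptance conditions are exact
landmarks, with jitter available for robustness studies. All randomness is
seeded; the same seed reproduces the mesh and landmarks bit for bit.

Cohorts draw the six translational components, $\alpha$ and $L$ normally
about the defaults (SDs at the cohort values: medial 4.0/3.4/5.3 mm,
lateral 4.1/1.6/5.2 mm, $\alpha$ 3.8°, width 4 mm), truncated at ±3 SD,
with the rotational differences arising as derived quantities of each drawn
geometry — mirroring the fact that on real specimens they are consequences
of the anatomy. Draws violating realizability (an epicondyle inside the
shaft) or the plausibility band on $\alpha, \beta$ are redrawn a bounded
number of times.

What the generator does **not** emulate: cortical thickness and imaging
artifacts, segmentation noise on the articular surface, anatomical
asymmetries of the trochlear groove (the ground-truth groove is exactly
circular), and correlations between offset components that real anatomy
may exhibit. Passing recovery tests therefore demonstrate the correctness
of the measurement chain, not the clinical accuracy of landmark picking on
real bones.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles (spectral
line fit; grid-plus-refinement searches for the circle and ellipse
objectives), checks rigid-motion invariance of every reported quantity
(50 random transforms in the acceptance suite), runs the null specimen
(all reported deviations below 0.05° / 0.1 mm), recovers the cohort-mean
construction, and calibrates the paired t-test (power on the
medial-vs-lateral M-L comparison and size under a matched null over
2 × 2000 simulated 15-specimen cohorts using the mesh-free ground-truth
path). ICCs are verified against ANOVA mean squares from `stats::aov` and
their defining identities (perfect agreement → 1; per-rater additive
shifts → ICC(3,1) = 1, ICC(2,1) < 1). Default mesh density (96 angular
segments) keeps a full specimen analysis under a second; the analysis
scripts use 15-specimen cohorts at that density.

## Limitations

* The flexion/sagittal channel is reported but ill-conditioned by
  construction (see above); treat its values as qualitative.
* The axis-offset record depends on where the translated axis exits the
  medial mass and can be noise-sensitive near tangency.
* Exit points are computed on the raw triangle surface; no articular
  smoothing is applied.
* The t-test pairing (medial vs lateral offsets of the same specimens) is
  a design choice of this package; an unpaired variant is available via
  `t_test(..., paired = FALSE)`.
* No multiple-testing correction is applied (α = 0.05 per comparison).
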
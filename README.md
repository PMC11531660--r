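# elbowaxes

3D morphometric analysis of the distal humerus: how far does the palpable
**epicondylar axis** deviate from the elbow's true **flexion–extension (F-E)
axis**?

The epicondyles are the standard intra-operative landmarks for aligning
total-elbow implants and hinged external fixators, but the hinge the ulna
actually tracks is the axis of the trochlea. This package quantifies the
deviation between the two axes on triangulated distal-humerus surface models
(STL/PLY, mm), both as per-plane **rotational differences** and as
per-direction **translational offsets**, and ships a parametric
synthetic-specimen generator with exact ground truth so the whole chain is
validated by parameter recovery.

## Method

For one specimen with picked landmarks:

* **Epicondylar axis** — each epicondyle is the mean of three manual picks;
  the axis joins the two means (lateral → medial).
* **Long (intramedullary) axis** — five evenly spaced cross-sections of the
  distal diaphysis/metaphysis are cut from the mesh; each contour is fitted
  by a planar ellipse `P(t) = a cos(t) u + b sin(t) (n × u) + C` minimizing
  radial deviation, and the axis `X = X₀ + k v` is the total-least-squares
  line through the five centers `C` (distal → proximal).
* **True F-E axis** — a 3D circle is fitted to 20 points on the deepest part
  of the trochlear groove by Gauss–Newton minimization of the summed squared
  radial deviations `Σᵢ dᵢ²`, `dᵢ² = (ρᵢ − r)² + hᵢ²`; the F-E axis is the
  circle normal through its center.
* **Anatomical frame** — coronal plane parallel to the long and F-E axes,
  sagittal plane perpendicular to the coronal plane and (as nearly as
  orthogonality allows) to the F-E axis, axial plane transecting the long
  axis. α = ∠(long, F-E), β = ∠(long, epicondylar); per-plane signed
  differences (flexion/extension, varus/valgus, external/internal) are
  right-hand-rule angles between the projected axes.
* **Translational offsets** — the F-E axis exits the surface at the
  trochlear point (medial) and capitellum point (lateral); their offsets
  from the medial/lateral epicondyle are resolved along anterior(+),
  medial(+), distal(+). Translating the axis through the lateral epicondyle
  and intersecting the medial humerus gives the overall axis offset.
* **Cohort statistics** — Shapiro–Wilk normality, paired Student's t-tests
  (medial vs lateral offsets), and single-rater ICC(2,1)/ICC(3,1) from
  two-way ANOVA mean squares for observer reliability.

## Worked example

A synthetic specimen constructed at the study-cohort mean offsets
(translational: medial 14.1/−12.3/12.1 mm, lateral 11.4/3.1/9.2 mm in
A-P/M-L/D-P; rotational: varus 2.1°, external 0.5°), analyzed blind by the
full pipeline:

```r
library(elbowaxes)

s   <- generate_specimen(synthetic_spec())
rep <- run_specimen(s$mesh, s$landmarks)

rep$rotation
#> <axis_comparison> alpha 76.93, beta 77.44, |alpha-beta| 0.51 deg
#>   flexion(+)/extension(-): +9.337 deg
#>   varus(+)/valgus(-):      +2.100 deg
#>   external(+)/internal(-): +0.500 deg
rep$medial
#> <offset_record> |d| 22.28 mm; A-P +14.10, M-L -12.30, D-P +12.10 mm
rep$lateral
#> <offset_record> |d| 14.97 mm; A-P +11.40, M-L +3.10, D-P +9.20 mm
```

Every constructed translational component and the varus/external offsets are
recovered exactly. The flexion value is not a free parameter: given the six
translational components, the exit-point separation and the axis
inclination, the identity
`medial_epi − lateral_epi = L·fe + (o_lat − o_med)` fixes the epicondylar
direction, and with it the sagittal-plane difference (+9.34° here). See the
methods vignette (`vignettes/elbow-axis-deviation.Rmd`) for why this makes
jointly prescribing all three rotational means geometrically impossible.

The cohort workflow lives in `analysis/` (run in order from the repository
root): `01_simulate_cohort.R` draws 15 specimens about the cohort means,
`02_fit_axes.R` runs the pipeline on each, `03_deviation_tables.R` writes
the rotational/translational summary tables and medial-vs-lateral paired
t-tests, `04_reliability_icc.R` runs the simulated three-rater reliability
study. On the default seed the cohort reproduces the expected pattern —
medial absolute offset 23.1 ± 4.4 mm vs lateral 16.1 ± 3.4 mm with the
medial–lateral direction strongly significant (p ≈ 1.6e-5) and
inferior–superior not (p ≈ 0.18).

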
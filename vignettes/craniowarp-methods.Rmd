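---
title: "Modelling facial distraction outcomes with variance-weighted RBF warps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling facial distraction outcomes with variance-weighted RBF warps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniowarp)
```

## The problem

Children with syndromic craniosynostosis (Apert, Crouzon) undergo monobloc
or facial bipartition distraction: the forehead, orbits and mid-face are
osteotomised and advanced gradually by an external frame. Predicting the
resulting composite bone-and-skin shape change is hard: faces in these
cohorts vary enormously in size, proportion and asymmetry, and the surgical
signal is of the same order as that variation. `craniowarp` implements a
landmark-driven simulation of these operations: patient datasets (skin and
bone iso-surface meshes with named anatomical landmarks, all in mm) are
aligned in a standardised skull-base frame, normalised for shape–size,
deformed by a cohort-average "surgical warp", and de-normalised back into
the individual's own geometry.

## The deformation model

Every deformation in the pipeline is a vector-valued radial basis function
(RBF) displacement field

$$s(x) \;=\; c_0 + Cx \;+\; \sum_{i=1}^{N} \lambda_i\,\phi(\lVert x - x_i\rVert),$$

with $\phi(r)=r$ (biharmonic; the default) or $\phi(r)=r^3$ (triharmonic),
fitted per displacement component by the symmetric saddle-point system

$$\begin{bmatrix} A - \alpha\,\mathrm{diag}(\sigma^2) & P \\ P^{\mathsf T} & 0
\end{bmatrix}\begin{bmatrix}\lambda \\ c\end{bmatrix} =
\begin{bmatrix} f \\ 0\end{bmatrix},
\qquad A_{ij}=\phi(\lVert x_i-x_j\rVert),\quad P = [\,1\;x\;y\;z\,].$$

The per-centre variances $\sigma_i^2$ (mm²) trade fidelity against
smoothness: a zero-variance centre is matched exactly at any smoothing
constant $\alpha$, while high-variance centres relax towards the smooth
field. Both kernels are conditionally *negative* definite with respect to
the affine constraints, so the smoothing term enters with a minus sign —
this keeps the constrained system definite and is what makes the weighted
residual a non-decreasing function of $\alpha$ (property-tested). Because
the affine part is unpenalised, any affine displacement field (including
every translation) is reproduced exactly for all $\alpha$ and $\sigma^2$.

Implementation notes:

* One dense symmetric factorisation is shared by the three displacement
  components. At the pipeline's scale (≤ a few hundred centres) a direct
  solve is exact and fast; no far-field acceleration is used.
* Duplicate centres (closer than 1e-6 mm) are rejected, as are coplanar
  centre configurations (the affine part would be unidentifiable) and
  systems with reciprocal condition number below 1e-15.
* `alpha` defaults to 1 (the product $\alpha\sigma_i^2$ is the diagonal
  augmentation, so the cohort variances themselves set the scale); it is
  exposed for sensitivity analysis, as is the choice between the
  variance-of-the-mean and raw sample variance estimators.

## The reference frame

Datasets are aligned by internal anatomy unaffected by surgery or disease:
the lateral semicircular canals (2 points each), the glenoid fossae and the
crista galli. A best-fit plane through the six vestibular/glenoid points is
fitted by total least squares; the points are projected onto it; the line
through the two lateral canal points is taken to the x-axis with its
midpoint at the origin; the plane is rotated about x onto the x–y plane; and
a final z-rotation brings the crista galli to the anterior ($+y$) half of
the y–z plane. The guaranteed postconditions are: projected-midpoint at the
origin, plane = x–y, crista galli at $x=0,\ y>0$. The x-alignment of the
canal line is only approximate after the final rotation — the sequence is
applied literally, and re-enforcing the x-axis would disturb the crista
galli condition. Axis polarity is fixed as: $+x$ right, $+y$ anterior,
$+z$ superior; the superior direction is chosen so the centroid of the
remaining bone landmarks lands at $z \ge 0$, with a `flip_z` override.
Pre- and post-operative stages are aligned independently from their own
reference landmarks, which places both in a common frame and makes the
congruence of unoperated regions a measurable residual.

## Cohort models

The surgical warp for a cohort is fitted to the per-landmark mean
pre-operative positions (centres) and mean pre→post change vectors
(targets) over the contributing datasets, with per-landmark variance equal
to the trace of the sample covariance of the contributed change vectors
divided by the contribution count ("variance of the mean" — the fidelity
target is the *averaged* vector; the raw sample variance is available as an
option). Static calvarial/skull-base landmarks contribute near-zero change
vectors and anchor the warp in unoperated anatomy. Models are built
leave-one-out — the patient a warp is applied to never contributes to it,
and this is machine-enforced (`predict_outcome()` refuses a contributing
patient unless explicitly overridden). Arbitrary exclusion lists are
supported: a single contributor is allowed (its variance is zero), matching
cohorts where only a subset of datasets is usable.

The normalisation warp moves an individual's 36 craniometric landmarks
towards the cohort average, weighted by the cohort craniometric variances;
applied to the whole dataset it removes individual size, proportion and
asymmetry. Its reverse is *not* a numerical inversion of the forward field
(a smoothed RBF has no closed-form inverse): it is a fresh zero-smoothing
interpolant from the forward-warped craniometric positions back to the
originals, which makes forward-then-reverse exactly the identity at all 36
centres and very nearly the identity elsewhere. The prediction composes
forward normalisation, surgical warp and reverse normalisation by pointwise
sequential evaluation (not by summing displacement fields), transporting
mesh vertices and landmarks through the identical composite map.

## Evaluation

Predicted surfaces are compared to actual outcomes by signed distance: for
each predicted vertex the triangle-exact closest point on the actual mesh
is found (exhaustive scan in compiled code; ties to the lowest face index),
and the sign is positive when the vertex lies on the outward-normal side
(over-prediction), using barycentric interpolation of angle-weighted vertex
normals at the foot point. If the actual mesh is not consistently oriented
the map downgrades to unsigned with a warning. Summaries (mean, RMS,
median, 5th/95th percentiles) and per-region statistics over the standard
region vocabulary are reported; colour-coded difference meshes use a
diverging blue–green–red scale, green at zero, clipped at user-set limits.

Landmark placement reliability from repeated sittings is summarised per
landmark as the root-mean-square 3D deviation from the mean position (a
single scalar comparable with the 1/2/3 mm accuracy bands; per-axis SDs are
also reported), with half-open bands $[0,1)$, $[1,2)$, $[2,3)$,
$[3,\infty)$ mm.

## The synthetic generator

No clinical CT data are distributable, so the generator produces head-like
skin/bone surface pairs on which every pipeline stage is testable against
ground truth:

* The bone surface is a smoothly deformed superellipsoid-like radial
  surface (facial and chin protrusions, optional mid-face retrusion); the
  skin is the bone offset outward by a spatially varying thickness, thicker
  over the cheeks and thinner over the forehead, so skin and bone landmarks
  are distinct yet nearby and genuinely exercise the joint single-field
  fit.
* Landmark positions are exact analytic functions of the parameters — they
  are never snapped to mesh vertices, mirroring manual placement on
  iso-surfaces.
* Per-patient variation: overall scale, vertical stretch (turricephaly),
  antero-posterior compression (brachycephaly), a smooth unilateral
  asymmetric bulge, and mid-face retrusion depth. Default cohort ranges are
  deliberately modest (scale 0.95–1.05, stretch 0.95–1.10, compression
  0.90–1.05, asymmetry 0–2 mm, retrusion 0–6 mm): wide enough that
  normalisation does real work, narrow enough to represent a single
  surgical cohort.
* The simulated operation is a smooth analytic field: a Gaussian
  advancement (default 15 mm forward plus 4 mm descent, 40 mm falloff)
  centred at the mid-face apex, multiplied by a mask that vanishes at the
  skull-base reference points — anatomically, the distraction moves the
  osteotomised block while the skull base stays fixed, and without the mask
  any smooth forward field would carry the crista galli (which sits only
  ~35 mm behind the apex) by several millimetres. The bipartition variant
  adds para-midline maxillary divergence and orbital medialisation as odd
  functions of $x$. Optional mandibular auto-rotation rotates mandibular
  landmarks about a condylar axis proportionally to the descent.
* Placement noise (default SD 1 mm) is added to the post-operative landmark
  placements only; surfaces are transported noise-free, and the 7
  reference-frame landmarks are placed exactly (they are deep anatomical
  points with the highest placement reliability, and keeping them exact
  separates surgical-model error from frame error in recovery
  experiments).

What the generator does *not* emulate: real CT iso-surface topology (holes,
bone gaps, thin structures), growth between scans, patient-specific
surgical remodelling, or soft-tissue mechanics. Passing the recovery
experiments therefore shows the pipeline recovers a smooth, shared surgical
field under realistic landmark noise and moderate shape variation — not
that it reproduces clinical outcome accuracy, which depends on cohort data
the package cannot ship.

## Numerical choices and problem sizes

* Test and demonstration cohorts use coarse meshes (roughly 100–800
  vertices per surface) and 5–20 patients — the landmark-driven model is
  independent of mesh resolution, so these sizes exercise every code path
  while keeping the full suite to a couple of minutes.
* Parameter-recovery experiment: 10 patients, shared default surgical
  field, 1 mm landmark noise, default shape-variation ranges; the held-out
  mid-face landmark RMS error is about 0.7–0.9 mm, comfortably within the
  2 mm acceptance bound, and drops to solver precision (≈1e-13 mm) when
  noise and variation are switched off.
* Concentric-sphere distance calibration uses ≥5000-face spheres (50 vs
  48 mm), giving +2 mm everywhere.
* Closest-point ties (a query equidistant from several faces) return the
  lowest face index, for determinism. Degenerate (zero-area) faces are
  dropped when meshes are constructed or read.
* Units are millimetres throughout; loaders reject any other declared unit
  rather than converting silently.

## Known limitations

* The forward/reverse normalisation pair is exactly involutive only at the
  craniometric centres; elsewhere the round-trip error is tiny near the
  head (micrometres in the tests) but grows with extrapolation distance.
* The signed-distance sign depends on a consistently oriented actual mesh;
  non-manifold inputs fall back to unsigned.
* The surgical warp models the *common* component of an operation; bespoke
  per-patient steps (nasal grafts, forehead remodelling) are outside the
  model, as are growth effects between scans.
* Mandibular auto-rotation disrupts distance maps in the lower face; the
  package reports it region-wise rather than correcting for it.
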
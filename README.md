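# craniowarp

Landmark-based prediction of post-operative head and face shape after
**monobloc** and **facial bipartition** distraction surgery in children with
syndromic craniosynostosis (Apert, Crouzon).

Surgeons advancing the forehead, orbits and mid-face with an external
distractor currently judge the outcome by eye. `craniowarp` provides a
quantitative simulation of the *typical* operation for audit and planning:
given a cohort of pre/post surgical datasets (skin + bone surface meshes
with named anatomical landmarks, coordinates in mm), it predicts the
post-operative shape of a held-out patient and measures how far a
prediction is from an actual outcome.

## The model

All deformations are vector-valued radial basis function (RBF) displacement
fields

```
s(x) = c0 + C x + Σ_i λ_i φ(|x − x_i|),     φ(r) = r  (or r³)
```

fitted per component by the weighted least-squares saddle-point system
`[A − α·diag(σ²), P; Pᵀ, 0]·[λ; c] = [f; 0]` with `A_ij = φ(|x_i − x_j|)`
and `P = [1 x y z]` at the centres. Per-centre variances σ² relax fidelity
where the cohort disagrees (smoothness wins) while zero-variance centres —
and every affine field — are matched exactly. The pipeline is:

1. **Align** every dataset into a standardised skull-base frame built from
   7 reference landmarks (lateral semicircular canals, glenoid fossae,
   crista galli) — anatomy untouched by surgery or disease.
2. **Normalise** the individual for shape–size: an RBF warp moves its 36
   craniometric landmarks towards the cohort average.
3. **Surgical warp**: an RBF fitted to the cohort-mean pre→post change
   vectors at the cohort-mean landmarks (78 skin + 78 bone + static
   calvarial constraints), built **leave-one-out** and weighted by the
   variance of the averaged vectors.
4. **Reverse the normalisation** (exact interpolant back from the
   forward-warped craniometric positions) to restore the individual's own
   size and shape.
5. **Evaluate**: triangle-exact signed-distance maps against the actual
   outcome (positive = over-prediction), per-region summaries, and
   landmark-placement reliability reports with 1/2/3 mm accuracy bands.

A fully parametric synthetic generator (head-like skin/bone pairs, the
complete landmark schema, a known analytic surgical field with optional
bipartition components and landmark placement noise) makes every stage
testable without clinical data.

## Worked example

```r
library(craniowarp)

# a synthetic 8-patient monobloc cohort with 1 mm landmark placement noise
cohort <- lapply(generate_cohort(n = 8, seed = 42), align_dataset)
stats  <- craniometric_stats(cohort)

# leave-one-out surgical model for patient P001, then predict
model <- surgical_model(cohort, exclude = "P001")
model
#> <surgical_model> monobloc_older: 170 landmarks averaged over 7 datasets
#>   mean |change|: 3.11 mm (max 13.46); variances [5.18e-09, 0.893] mm^2
#>   excluded: P001

norm <- normalisation_model(cohort[["P001"]], stats)
pred <- predict_outcome(cohort[["P001"]], model, norm)
pred
#> <craniowarp_prediction> patient P001 (monobloc_older model, 7 contributors)
#> <surface_mesh> skin/predicted: 830 vertices, 1656 faces
#> <surface_mesh> bone/predicted: 830 vertices, 1656 faces

signed_distance_map(pred$skin, cohort[["P001"]]$skin_post)
#> <signed_distance_map> 830 vertices
#>   mean    rms median     p5    p95
#> -0.045  0.262 -0.019 -0.473  0.331
```

The model averages 7 datasets (never the patient it is applied to — the
leave-one-out guard is enforced in code). The mean change of 3.11 mm over
all 170 landmarks peaks at 13.46 mm at the mid-face apex, the simulated
15 mm advancement after Gaussian falloff. The final map says the predicted
skin surface sits within about ±0.5 mm of the simulated actual outcome for
90% of vertices (negative = predicted inside the actual surface).

`run_pipeline(run_config(...))` orchestrates the whole sequence over a
cohort directory (or a simulated cohort) and writes predicted meshes (PLY),
landmarks (CSV), colour-coded difference maps and provenance JSON. A thin
command-line wrapper with `simulate`, `align`, `build-model`, `build-norm`,
`predict`, `evaluate` and `run` subcommands is at
`inst/cli/craniowarp.R`.

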
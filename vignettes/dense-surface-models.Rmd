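---
title: "Dense surface models for facial dysmorphology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense surface models for facial dysmorphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsmorph)
```

## The problem

Syndromic facial gestalts — the constellation of subtle shape differences a
clinical geneticist recognizes at a glance — can be quantified from 3D
surface scans. `dsmorph` implements the dense-surface-model route: sparse
anatomical landmarks placed once per face are used to induce a *dense*
correspondence (every face represented by the same ordered set of thousands
of surface points), after which face shape becomes a vector and familiar
multivariate statistics apply. The package covers the whole chain:
correspondence, the PCA shape model, per-face signatures against matched
controls, anthropometric distance tests, discrimination between groups in
shape space, and growth regressions, plus a synthetic-cohort generator that
stands in for clinical photographs which cannot be redistributed.

This vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, what the generator does and does
not emulate, and the numerical and design choices taken where the design
was genuinely open.

## Landmark schema

All I/O and statistics are pinned to a fixed, ordered 22-landmark schema
(`landmark_schema()`): glabella, nasion, endo-/exocanthion L+R, palpebrale
superius/inferius L+R, pronasale, subnasale, alare L+R, labiale
superius/inferius, crista philtri L+R, chelion L+R, pogonion, gnathion.
The composition is a convention chosen so that the classic measured
distances (nose width = alare L–R, nose length = nasion–pronasale, philtrum
length = subnasale–labiale superius, mouth width = chelion L–R, face height
= nasion–gnathion) always exist; annotation schemes differ between
laboratories, so both the schema (via the `schema` argument of the readers)
and the measurement pairs (via `pairs` in `measure_face()`) are
configurable. Note that nose length and philtrum length have no universal
landmark definition; the defaults above are stated conventions, not claims.

Coordinates are millimetres in a right-handed frame: +x subject-left,
+y up, +z out of the face. This fixes the semantics of the axial heat-map
channels unambiguously.

## Dense correspondence

Three steps, no manual interaction:

1. **Generalized Procrustes alignment** (`procrustes_align()`) of the
   landmark configurations, iterating rigid (rotation + translation)
   superimposition onto an evolving mean until the mean moves < 1e-8 RMS or
   100 iterations. *No scaling*: size must survive, because the first
   principal component of a mixed-age model is the growth axis and the
   growth regressions read facial size off it. Reflections are never used
   (proper rotations only), so left/right anatomy cannot be silently
   flipped. The GPA mean is then rigidly anchored onto the base-mesh
   landmarks; without this step the common frame would inherit an arbitrary
   orientation from the first configuration, and the corresponded output
   would not be invariant to the pose of the inputs.
2. **Thin-plate-spline warp** (`tps_fit()`/`tps_apply()`) of the base mesh
   onto each subject's aligned landmarks, using the 3D biharmonic kernel
   φ(r) = r plus an affine term. Two properties make this testable: at
   λ = 0 the warp interpolates the landmarks exactly, and affine (hence
   rigid) maps are reproduced exactly for any λ. The default regularization
   λ = 1e-3 × (landmark bounding-box diagonal) trades a few hundredths of a
   millimetre of landmark interpolation error for smoothness under noisy
   landmarks; coincident landmarks make the system singular and are
   reported by row pair.
3. **Closest-point projection** (`project_to_surface()`) of each warped
   vertex onto the subject's triangulated surface — exact point-to-triangle
   distance (not nearest vertex), accelerated by a uniform spatial grid in
   compiled code. Vertices farther than `max_distance` (default 10 mm) from
   the surface keep their warped position and are flagged in a miss mask,
   so the fixed-topology contract (every face has exactly N base-mesh
   points) is never broken; per-face miss fractions are reported and are
   essentially zero on synthetic cohorts.

The base mesh is the synthetic template by default, or the first control
subject (`run_config(base = "first_control")`); the method itself only
requires *a* base with landmarks. The modelled surface is the full face
patch of the template, which has no ears — mirroring the usual practice of
modelling a reduced, ear-free face patch, since ears are rarely captured
reliably.

## The shape model

`dsm()` performs PCA of the mean-centered flattened point matrices via SVD
of the n × 3N data matrix (never forming the 3N × 3N covariance, which for
N ≈ 25,000 would be intractable; a brute-force eigendecomposition serves as
the test oracle at small N). Variances use the n − 1 divisor. Modes are
ordered by decreasing variance; the retained count is the smallest k whose
cumulative variance fraction reaches `variance_target` (default 0.99). The
sign of each mode is fixed (largest-magnitude coefficient positive) so
stored models are byte-reproducible — PCA signs are otherwise arbitrary,
and slope signs in downstream regressions would be meaningless across runs.
For the same reason `pc1_growth_comparison()` flips PC1 to correlate
positively with age before any regression.

Separate models per comparison (per sex, per syndrome pair, per age band)
are built by re-running `dsm()` on subsets; there is no incremental update.
Within cross-validated discrimination the model is *rebuilt on each
training fold* — a deliberately conservative choice that rules out test-set
leakage through the mode basis.

## Signatures, weights, heat maps

`matched_reference()` defines "age/sex-matched": the k = 25 controls of the
same sex nearest in age, expanded to include ties at the cut and to span at
least a ±2-year window. k-nearest matching (rather than a fixed window) is
used because control cohorts at any single age are modest; the realized
window is reported for transparency. The per-point, per-component control
SD is clamped below at `sd_floor` = 0.05 mm: at near-rigid points (e.g.
nasion) the control SD can approach zero and the normalized signature would
blow up; 0.05 mm is well below scanner noise, so the clamp only ever
engages where normalization is meaningless anyway.

`signature()` reports raw (mm) and normalized (SD-unit) displacement per
point, both as x/y/z components and projected on the reference mean's
area-weighted outward vertex normals (outward displacement positive). The
scalar weight sums the squared normalized *axial* components over all
points; the normal component feeds the heat maps only. Whether a published
weight sums axial components, normal components, or raw norms is not
something the definition pins down — the choice is isolated in
`signature_weight()`, and switching to the normal channel is a one-line
change. Heat maps (`heatmap_colors()`) map a channel linearly to
red–green–blue with saturation exactly at ±2 SD by default: green is
coincidence, red inward, blue outward.

## Statistics

* **Anthropometry**: pooled-variance Student's t (Welch behind a flag),
  two-tailed, with the Bonferroni threshold α/m (0.05/4 = 0.0125 for the
  four classic facial distances). Zero-variance degenerate inputs resolve
  to p = 1 (equal means) or p = 0 with a warning (unequal means).
* **Discrimination** (`discriminate()`): stratified k-fold (leave-one-out
  when the smallest group has < 15 members), per-fold DSM rebuild, three
  classifiers on the retained mode scores: closest mean (ties go to the
  first label in sorted order), `MASS::lda`, and a linear SVM
  (`e1071::svm`, C = 1 — the linear kernel is chosen for determinism and
  the small n of rare-syndrome cohorts). LDA is restricted to the leading
  n_train − n_groups − 1 modes because it is singular when the retained
  mode count (≈ n − 2 at the 99% target) approaches the training count;
  accuracies are reported overall and macro-averaged per class, since
  control groups are typically much larger than syndrome groups.
  `axis_projection()` places faces along inter-group-mean axes (group A at
  −|B−A|/2, B at +|B−A|/2) for simultaneous multi-syndrome comparison.
* **Growth** (`compare_regressions()`): per-group OLS of a marker (PC1,
  signature weight, or any measurement) on age, then the sequential
  procedure familiar from common regression-comparison software: F-test of
  equal slopes (interaction vs. common-slope model); only if slopes do not
  differ at 0.05 is the intercept tested under a common slope. The decision
  trace records which branch applied. Exact-fit degeneracies (zero residual
  sums of squares) are resolved explicitly: no slope difference gives
  F = 0, p = 1; a perfect separation gives p = 0.

## The synthetic cohort generator

`make_template()` builds a smooth face-like surface: an elliptical dome
(70 × 95 × 55 mm semi-axes) with Gaussian relief for the nasal ridge and
tip, alae, lips, chin boss, brow ridges and orbital hollows, exactly
bilaterally symmetric, with all 22 landmarks on template vertices and named
region masks (nose, philtrum, lips, chin, brow, cheeks, forehead). The
nominal template nose width is 30 mm (realized up to grid snapping).

`sample_subject()` composes, in order: group effect fields → individual
variation → vertex noise → growth scale → rigid pose. Each piece emulates
one feature of real study data, with defaults chosen once as study-like
conditions:

* **Effect fields** (`effect_field()`): Gaussian-bump displacements
  (amplitude × exp(−d²/2r²)) anchored at landmarks or region centroids,
  along a fixed direction or the local surface normal. The stock syndrome
  set (`syndrome_effect_fields()`, 1.5 mm default amplitude, radii
  8–10 mm) encodes the studied gestalt: wider nose (lateral alar fields),
  prominent/upturned nasal tip, longer philtrum, fuller lips, prominent
  chin — stronger in males (×1.2) than females (×0.8), mirroring the
  reported sex asymmetry of the phenotype. An optional age ramp
  (amplitude × min(1, age/a₀), off by default) emulates features that
  develop late, such as chin pointing.
* **Growth**: isotropic scale s(age) = s₀ + s₁·age; controls (0.80, 0.012)
  give ≈ 30% linear growth across ages 2–22, patients (0.82, 0.015) are
  larger and grow faster, emulating macrosomia.
* **Individual variation**: random loadings (SD 1.5 mm) on five smooth
  Gaussian-bump displacement fields at random surface anchors (radii
  15–35 mm). This matters: with iid vertex noise alone the PCA modes would
  be noise and PC1 would not track age.
* **Noise and pose**: iid vertex noise (SD 0.2 mm, sensor-like) and a
  random rigid pose (≤ 10°, ≤ 20 mm) that the correspondence stage must
  remove.

Everything is deterministic given the config seed, and every cohort exports
ground truth (injected fields, mode loadings, growth coefficients) so that
parameter-recovery tests are possible — the generator, not unavailable
clinical data, is the package's acceptance surface.

What the generator does **not** emulate: texture and photorealism, capture
artifacts (holes, spikes, failed eye surfaces), hair, asymmetry, nonlinear
or sex-specific growth curves, and ear anatomy. Passing tests therefore
demonstrate that the *algorithms* recover known structure under controlled
conditions; they do not certify performance on clinical scans, whose
landmark placement error and surface artifacts are additional noise
sources outside this model.

## Validation design and problem sizes

The test suite checks each stage against an independent oracle: rigid
alignment against `vegan::procrustes`, TPS against its closed-form affine
reproduction, surface projection against an exhaustive point-to-triangle
scan, PCA against explicit covariance eigendecomposition, the signature
weight against a brute-force accumulation loop, and the regression F-tests
against explicit design-matrix least squares. Property-style checks cover
round-trips, rigid invariance of the corresponded output (< 1e-3 mm RMSD),
determinism under fixed seeds, and statistical calibration (null
false-positive rates of the t- and F-tests at their nominal levels over
2000 replicates).

Simulation-based checks run at deliberately chosen scales: templates of
600–800 vertices and groups of 14–40 subjects for recovery, discrimination
and power suites, and a single full-scale 60-subject, ~5000-vertex cohort
for the variance-coverage check that `scripts/acceptance.R` also
recomputes. The discrimination sweeps (amplitudes 0–5 mm) use two groups
that are identical — same growth model, narrow 9–11-year age band — except
for the injected effect, so that the contrast being classified is the
effect itself rather than incidental growth differences; the chance-level
check averages leave-one-out accuracy over 20 generator seeds.

## Known limitations

* Correspondence quality is bounded by the landmarks: TPS + closest-point
  is faithful to the landmark-driven DSM construction, but regions far from
  any landmark (forehead, cheeks) are constrained only by smoothness of the
  warp.
* Signatures assume the matched control set is large enough for a stable
  per-point SD; below ~10 matched controls the SD estimate is noisy and
  weights between cohorts of different control density are not directly
  comparable.
* The sequential slope/intercept procedure cannot test intercepts when
  slopes differ — by construction, not oversight.
* Facial asymmetry is not modelled or measured anywhere; the signature
  machinery compares a face to a control mean, not to its own mirror.
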
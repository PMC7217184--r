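# dsmorph — dense surface models for 3D facial morphometry

`dsmorph` implements the dense-surface-model (DSM) approach to quantitative
facial dysmorphology: given 3D face surfaces annotated with 22 sparse
anatomical landmarks, it induces a dense point correspondence across a
cohort, extracts principal-component shape modes, and characterizes each
face against age- and sex-matched controls by normalized *signatures*,
scalar dysmorphism scores and red–green–blue heat maps. It is aimed at
researchers studying syndromic facial gestalts (the motivating application
is Cantú syndrome, an ABCC9/KCNJ8 channelopathy with a characteristic
facial phenotype) who need a reproducible, fully scriptable shape-analysis
pipeline rather than interactive tooling.

Because clinical 3D photographs cannot be shared, the package ships a
deterministic synthetic face-cohort generator that emulates the statistical
structure of such a study — localized group displacement fields with
sex-specific magnitudes, a linear growth model, smooth individual
variation, sensor noise and arbitrary rigid pose — so that every method can
be exercised and validated end-to-end on data with known ground truth.

## The model

For a cohort of surfaces with a shared landmark schema, correspondence is
induced with no manual interaction:

1. **Generalized Procrustes alignment** of the 22-point landmark
   configurations, rotation + translation only (size is deliberately kept,
   since facial growth must survive into the model); the common frame is
   anchored to the base mesh.
2. **Thin-plate-spline warping** (biharmonic kernel φ(r) = r, affine part,
   regularization λ) of a base mesh onto each subject's aligned landmarks.
3. **Closest-point projection** of the warped vertices onto the subject's
   surface (exact point-to-triangle distance, grid-accelerated in C++).

Every face then has the same N points in the same order, and the DSM is the
PCA of the flattened point matrices: mean face x̄ plus orthonormal modes
φ₁, φ₂, … with variances λ₁ ≥ λ₂ ≥ …, retaining the smallest k modes whose
cumulative variance fraction reaches 99%. In a mixed-age cohort PC1 tracks
facial growth and correlates strongly with age.

The **signature** of a face is its per-point displacement from the mean of
the k nearest age-matched, same-sex controls, normalized by the per-point
control SD; the **signature weight**

&nbsp;&nbsp;&nbsp;&nbsp;w = √( Σᵢ Σ_{c∈{x,y,z}} (dᵢ𝚌 / σᵢ𝚌)² )

is a scalar dysmorphism estimate. Heat maps color the surface-normal
component on a −2…+2 SD scale (red = inward, green = coincident,
blue = outward, saturating beyond ±2 SD). Group differences are tested by
landmark anthropometry (pooled Student's t with Bonferroni correction,
0.05/4 = 0.0125 for the four classic measures), by multi-fold
discrimination in mode-score space (closest mean, LDA, linear SVM; the DSM
is rebuilt per fold), and by F-tests comparing regression slopes and
intercepts of PC1 or signature weight against age between groups.

## Worked example

```r
library(dsmorph)

cfg    <- study_config(n_control = 30, n_cs = 14, resolution = 1500, seed = 42)
cohort <- generate_cohort(cfg)        # synthetic faces + landmarks + truth
cc     <- correspond_cohort(cohort)   # GPA + TPS + closest-point projection
model  <- dsm(cc)                     # the dense surface model
model
#> Dense surface model
#>   44 training faces x 1547 surface points
#>   43 modes; 4 retained covering 99.09% of shape variance (target 99%)

w <- cohort_signature_weights(cc, k = 12)
aggregate(weight ~ group, w, function(v) round(mean(v), 1))
#>     group weight
#> 1 control   63.7
#> 2      CS  119.1

meas <- cohort_measurements(cc)
compare_measurements(meas, "CS", "control", sex = "male")
#>       measurement mean_a mean_b    t        p significant
#> 1      nose_width   35.4   28.1 6.23 4.41e-06        TRUE
#> 2     nose_length   38.2   33.6 3.44 2.57e-03        TRUE
#> 3 philtrum_length   16.8   14.8 3.38 2.98e-03        TRUE
#> 4     mouth_width   54.5   49.4 2.68 1.42e-02       FALSE
#> 5     face_height  106.3   96.6 2.60 1.70e-02       FALSE

pc1_growth_comparison(cc, "control", "CS")
#> Regression comparison:
#>   control    slope 29.48, intercept -458.7 (n = 30)
#>   CS         slope 36.7, intercept -376.1 (n = 14)
#>   slope test:     F = 73.6, p = 1.321e-10
#>   slopes differ significantly (p = 1.321e-10); intercept test not applicable
```

The numbers read as a miniature of a real study: retained modes cover just
over the 99% variance target; synthetic patients carry roughly twice the
mean dysmorphism score of held-out controls; the injected nose-widening and
philtrum-lengthening fields reach significance at the Bonferroni threshold
(0.01) while mouth width does not; and the patient group's faster
configured growth shows up as a significantly steeper PC1-vs-age slope.
`signature()` + `heatmap_colors()` + `write_heatmap_mesh()` export
per-vertex colored PLY heat maps of any face or group mean, and
`run_pipeline(run_config(...))` drives all stages from a manifest into a
single run directory with config snapshot and logs.

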
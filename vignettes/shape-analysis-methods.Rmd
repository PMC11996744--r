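---
title: "Methods: Jacobian shape descriptors, super-vertex reduction, and permutation inference"
author: "ercshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Jacobian shape descriptors, super-vertex reduction, and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical and numerical choices behind
`ercshape`: the model and its assumptions, the parameters that matter, what
the synthetic-data generator emulates (and what it does not), and the known
limitations.  It states no empirical result that the package's tests do not
themselves compute.

## The analysis model

The pipeline consumes a *corresponded cohort*: a template triangle mesh and,
for each subject, one 3-D position per template vertex, produced upstream by
a diffeomorphic surface registration.  Per vertex, three deformation
descriptors are defined:

* surface Jacobian `J_s`: one-ring (attached-face) area after the
  deformation divided by the one-ring area on the template.  We use the full
  incident-face-area sum rather than a one-third barycentric area: any
  consistent vertex-area convention cancels in the ratio, so the simpler
  literal convention is used on both sides.
* Jacobian determinant `J_d`: the volume-change factor of the ambient map.
  Two input paths are supported: an evaluable deformation field (synthetic
  path — analytic gradient when available, otherwise a central finite
  difference), or per-vertex determinants supplied in a CSV (real-data path,
  matching registration pipelines that report a determinant per vertex).
  How a volumetric determinant is best interpolated onto surface vertices is
  registration-specific, so the package deliberately accepts either.
* normal Jacobian `J_n = J_d / J_s`: stretch normal to the surface.  This is
  not cortical thickness: it is a local scale factor, and a thickness change
  need not imply a normal-Jacobian change or vice versa.

The analysed quantities are `log J_s` and `log J_n` (logs taken once, at the
end); positive means expansion.  For each cluster `c` of template vertices
the nested models

$$H_0: \mathrm{jac} = c_i\,\mathrm{ICV} + c_a\,\mathrm{Age} + c_s\,\mathrm{Sex} + c_0$$
$$H_A: \mathrm{jac} = c_V\,\mathrm{Vest} + c_i\,\mathrm{ICV} + c_a\,\mathrm{Age} + c_s\,\mathrm{Sex} + c_0$$

are fitted by ordinary least squares, where `jac` is the cluster
super-vertex value of the chosen log-descriptor.  Size is handled
statistically (ICV as a covariate), so the rigid alignment step deliberately
excludes scaling, and reflections are excluded by constraining the Kabsch
rotation to determinant +1.  Left and right structures are always analysed
separately, never pooled.

## Covariate preparation

The vestibular variables follow fixed clinical rules: for cVEMP and oVEMP
the continuous measure is the higher amplitude from either ear with a
present response and the categorical measure codes bilaterally absent (0)
versus any present response (1); for VOR the continuous measure is the mean
gain of the two eyes and the categorical measure codes impaired (mean gain
strictly below 0.8) versus unimpaired.  Ear-side specificity is lost by
construction (best-ear rule).  Missing data are handled per variable by
complete-case analysis, with the dropped count reported, so different
variables legitimately analyse different `n`.  Continuous variables are
standardised to unit SD by default so `c_V` reads as change per 1 SD;
because the reported effect is on a log scale, `100(e^{c_V}-1)` is emitted
alongside the raw coefficient as the percent change (reporting both avoids
the ambiguity of a bare "% change" column).

## Super-vertex reduction

With N ≈ 400 vertices, vertex-wise testing would multiply hypotheses beyond
the power of a modest cohort.  Vertices are therefore partitioned into `k`
clusters (default 6, with 7 exposed in the configuration) by spectral
clustering of the surface geometry alone: the affinity graph has the mesh
edges weighted `exp(-d^2/\sigma^2)` with `d` the edge length and `σ` the
median edge length — a standard, scale-adaptive choice that respects mesh
topology (geodesic-distance or coordinate kernels would be defensible
alternatives; the choice is isolated behind `mesh_affinity()`).  The
embedding uses the `k` smallest eigenvectors of the symmetric normalized
Laplacian with row normalisation, followed by seeded k-means with 50
restarts.  Determinism under a fixed seed takes precedence over k-means
local-optimum quality; an empty cluster triggers a seed bump (at most 10)
before erroring.

Each cluster is reduced to the *maximum* of the descriptor over its vertices
("super-vertex").  The max is applied to both log-descriptors; since the log
is monotone, max-then-log equals log-then-max.  The max emphasises the
strongest local signal and is the reduction the pipeline is built around;
mean/median reducers exist only as a sensitivity escape hatch.

## Permutation inference

The family statistic is `T = max_c SSE_{H0}(c) / max_c SSE_{HA}(c)` — the
ratio of the maximum squared error under the null to the maximum under the
alternate.  The alternative grammatical reading, `max_c` of the per-cluster
ratios, is implemented behind `statistic = "max_of_ratios"` and exercised in
tests; `ratio_of_maxima` is the default.  For nested least squares both
variants satisfy `T >= 1`.

Each permutation replicate permutes the vestibular column across subjects
with responses and nuisance covariates fixed; a Freedman–Lane-style option
permutes the null-model residuals of the vestibular column instead (for
this statistic the two coincide algebraically, since `Vest` enters only
through its null-residualised component, but the option is kept explicit).
The p-value uses the add-one convention `(1 + \#\{T_b \ge T\})/(B+1)`: it can
never be exactly zero, recovers the "fraction of replicates greater than
the observed statistic" as `B` grows, and counts ties conservatively.
Replicate refits use the exact rank-one update for adding a single regressor
to a fixed null model (residualise the permuted column, subtract the squared
scaled covariance from the null SSE), which is algebraically identical to a
full refit — the test suite verifies this against naive whole-model refits.

Because `T` is a single family statistic, per-cluster localisation needs a
convention: cluster `c` receives the single-step max-statistic adjusted
p-value — the fraction of permuted family statistics at least as large as
the cluster's own SSE ratio — and clusters passing the family-wise level are
reported with their dominant parcellation subregions (overlap fractions
below 0.10 are suppressed from the rendered report but kept in the JSON).

## The synthetic cohort

No real cohort ships with the package, so a generator provides statistically
faithful stand-ins:

* **Covariates.**  Age 76.99 (SD 8.64) years, intracranial volume 1231.1
  (118.38), 28% female, best-ear cVEMP amplitude 1.32 (0.68) µV with 56.31%
  either-ear presence, best-ear oVEMP amplitude 14.74 (9.63) µV with 62%
  presence, two-eye mean VOR gain 0.98 (0.15), for 103 subjects by default.
  Amplitudes and gains are plain (untruncated) Gaussians so sample moments
  are unbiased; physiological non-negativity is knowingly sacrificed.
  Per-ear amplitudes are correlated pairs (ρ = 0.7 — a fixed, documented
  convention) calibrated in closed form so the *max over ears* has exactly
  the configured mean and SD; per-eye gains are correlated at 0.9 and
  calibrated so the *two-eye mean* has exactly the configured moments.
  Presence is a subject-level either-ear Bernoulli with the configured
  marginal (given presence, both ears with probability 0.7, else one ear at
  random).  Amplitude magnitude and detectability are simulated
  independently — a simplification; in real cohorts absent responses
  correlate with low amplitudes.
* **Template.**  A closed ellipsoid (semi-axes 12 × 6 × 4 mm, an
  entorhinal-like elongation) triangulated as a UV sphere with poles on the
  long axis, about 400 vertices (within 5% of the request), axial
  resolution favoured (~3× the azimuthal) so each of the nine contiguous
  longitudinal label bands — named for the Krimer subregions, seven grouped
  ERC and two TEC — owns vertices whose entire one-ring stays in one band.
  The true high-field atlas geometry cannot be redistributed; this synthetic
  atlas preserves the label-transfer and reporting logic exactly.  Label
  transfer itself is rigid alignment (ICP-style, at most 20 iterations) plus
  nearest-neighbour assignment with ties broken toward the lower parcel id —
  a documented fidelity reduction relative to a diffeomorphic
  template-to-atlas mapping.
* **Deformations.**  Per subject, each region `r` receives a log-scale
  `u_r = b_r + \beta_r^\top x + \varepsilon_r` (covariate channels:
  standardized vestibular variable, age, ICV; sex as 0/1), with
  `ε_r ~ N(0, 0.02²)` per region — per-region rather than per-vertex noise
  is what makes the closed-form truth below exact.  The map is radial about
  the template centroid, `x ↦ c + e^{u(x)}(x − c)`, with `u` constant inside
  each band and smoothstep-blended over a zone a quarter of the inter-level
  gap wide, placed strictly between mesh levels so no vertex ever sits in a
  transition.  Consequently every vertex whose one-ring stays in one band
  undergoes exact local uniform scaling: `J_s = e^{2u_r}`, `J_d = e^{3u_r}`,
  `J_n = e^{u_r}` — the recovery oracle.  The field carries its analytic
  gradient `e^u (I + u'(s)\,(x-c)\,e^\top)` and determinant
  `e^{3u}(1 + u'(s)\,s)`, so the finite-difference determinant path can be
  cross-checked against closed forms.

### What passing tests do and do not show

The generator produces smooth, noiseless-registration, perfectly
corresponded meshes with piecewise-constant regional effects.  Passing
calibration on it shows the *statistical machinery* is correct (the
permutation test attains its nominal family-wise level; fits match
independent oracles); it does not certify robustness to segmentation error,
registration error, or spatially smooth effect gradients, none of which are
simulated.

A known and deliberate consequence of the construction: at a region
boundary, one band rescales while its neighbour does not, so the faces
straddling the boundary shear; the one-ring area at band-edge vertices then
responds nonlinearly (and partly even-signed) to the planted effect.
Combined with clusters (k = 6) being larger than regions (9), the
cluster-maximum super-vertex is *not* an unbiased estimator of the
per-vertex effect `2β` for a one-region planted effect: the package's
recovery study (200 simulations, β = ln 1.1, region ERC-Pr, n = 100)
recovers the effect's sign in well over 90% of runs but attenuates its
magnitude severely.  This mirrors a real limitation of max-reduction over
geometry-only clusters — a strong signal region can be split across
clusters or pooled with silent vertices — and is asserted honestly in the
test suite rather than hidden.  Detection (family-wise rejection) remains
well powered, as the planted-effect pipeline test shows.

## Numerical choices and degenerate inputs

* Rigid alignment: Kabsch via SVD with the determinant sign corrected;
  fewer than 3 points or a collinear cloud is a degenerate-geometry error.
  Whether a rigid step should include isotropic scaling is left as a
  config extension point; the default excludes it because ICV handles size.
* Mean shape: one pass of alignment to the first cohort member, then the
  per-vertex arithmetic mean — no iterative Procrustes re-referencing, for
  determinism and simplicity.
* Finite differences: central, default step `10^{-3}` × bounding-box
  diagonal; error decreases as `step²` (verified against a closed-form
  radial field).
* Mesh validation: in-range indices, no degenerate faces, no isolated
  vertices, consistent orientation via directed half-edge uniqueness, and
  strictly positive areas; open patches are allowed, and their boundary
  vertices are flagged for exclusion from statistics.
* ASCII-only mesh I/O (PLY, OFF, legacy VTK POLYDATA) with 17-significant-
  digit output: exact round-trips, byte-stable regeneration, diffable
  fixtures.  Binary dialects are rejected with a clear error.
* Ties: nearest-neighbour label transfer breaks exact distance ties toward
  the lower parcel id; permutation p-values count ties against rejection.
* All randomness flows from one master seed, split deterministically per
  stage (cluster seeding, permutation draws, per-subject noise), so any run
  is reproducible from its echoed configuration alone.

## Problem sizes used in the shipped studies

The packaged calibration studies use the study-scale defaults: 500 null
cohorts of n = 100 subjects on the ~400-vertex template with k = 6 and 200
permutations for the family-wise error check, 200 simulated cohorts for the
recovery study, and 100,000 subjects for the generator-moment checks.

## Limitations

* The pipeline starts at corresponded meshes; segmentation, surface
  reconstruction, and diffeomorphic registration are upstream and out of
  scope, as is any re-implementation of LDDMM.
* Cluster-level inference cannot localise below cluster size, and the
  maximum reduction biases effect-size estimates (see above); reported
  coefficients should be read as detection-weighted summaries, not unbiased
  per-vertex effects.
* The normal Jacobian is not thickness; claims about atrophy inside the
  structure are outside what surface descriptors measure.
* The synthetic atlas bands are a topological stand-in for the real
  subregion geometry; region-overlap reports on synthetic data validate the
  plumbing, not anatomical localisation.
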
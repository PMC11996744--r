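Package: ercshape
Title: Vertex-Wise Surface Shape Analysis of the Entorhinal Cortex with
    Permutation-Based Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating subject-level physiological covariates to
    local expansion and contraction of a cortical surface. Works on
    corresponded triangle meshes (one template plus per-subject vertex
    positions sharing the template topology): computes per-vertex Jacobian
    shape descriptors (surface, determinant, and normal Jacobians and their
    logs), reduces vertices to spectral-clustering super-vertices, fits
    nested least-squares models with nuisance covariates (intracranial
    volume, age, sex), and controls the family-wise error rate with a
    permutation test on a max-SSE-ratio statistic. Includes covariate
    preparation rules for vestibular measures (cVEMP, oVEMP, VOR gain), a
    Krimer-style nine-subregion parcellation with nearest-neighbour label
    transfer, ASCII mesh I/O (PLY, OFF, legacy VTK), and a fully synthetic
    cohort generator with analytic ground-truth Jacobians for calibration
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
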
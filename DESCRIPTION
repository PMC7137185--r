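Package: ivimtools
Title: Intravoxel Incoherent Motion Analysis of Diffusion-Weighted MRI
    for Nodal Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise quantitative analysis of diffusion-weighted MR
    volumes of primary cervical tumours: two-point apparent diffusion
    coefficient (ADC) mapping, segmented (two-step) biexponential
    intravoxel incoherent motion (IVIM) fitting with quality-control
    exclusion of incorrectly fitted voxels, diffusion tumour volumetry
    and histogram summaries over tumour volumes of interest,
    rank-based group-comparison statistics across nodal-involvement
    strata (Kruskal-Wallis, Nemenyi post-hoc, Fisher exact,
    interobserver intraclass correlation), and a stepwise-forward
    logistic classifier of pelvic lymph-node involvement with ROC and
    accuracy-comparison utilities. Includes synthetic phantom and
    cohort generators with Rician noise so the whole pipeline runs
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
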
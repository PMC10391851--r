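Package: cervifem
Title: Voxel Finite-Element Comparison of Anterior Cervical Fusion Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale static linear-elasticity finite-element simulator for
    comparing three anterior cervical surgical constructs (ACDF, ACCF and a
    modified ACDF with partial vertebral osteotomy) on an idealized C4-C6
    functional spinal unit. Generates labeled voxel geometry with layered
    vertebral bodies, discs and instrumentation, assembles trilinear
    hexahedral stiffness, solves the constrained system by sparse Cholesky
    factorization, recovers element Von Mises stress, and runs the full
    surgery x bone-quality x axial-load factorial with monitored-point
    summaries and nonparametric group comparisons, including an exact
    permutation Kruskal-Wallis test for small samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
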
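Package: shearscope
Title: Shear-Stress Modeling and Confocal Morphometry for Kidney Tubule Chips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microfluidic culture of proximal tubule epithelium under
    defined wall shear stress and for quantifying the resulting tissue phenotype
    from confocal image stacks. Computes laminar-flow wall shear stress in
    shallow rectangular and elliptical-plan channel slides (parallel-plate
    closed form, exact rectangular-duct Fourier series, lubrication plan
    profiles, and a finite-difference cross-check solver), and inverts a target
    shear stress to a volumetric flow rate. Simulates multi-channel confocal
    z-stacks of epithelial monolayers with known per-cell ground truth, and
    measures them with marker-controlled segmentation (cell area, circularity),
    ciliated-cell fraction, orthogonal-view tissue and basement-membrane
    thickness, cilium length, and normalized 3D marker coverage, averaged five
    fields of view per chip. Chip-level metrics are compared between groups
    with a normality-gated choice of Welch t-test or exact rank-sum test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
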
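Package: wormscreen
Title: Whole-Organism High-Content Screening Toolkit for Balanced C. elegans Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale re-implementation of a combined workflow for RNAi
    screens in balanced lethal C. elegans mutants: large-particle flow
    cytometer (COPAS/Profiler) axial-profile gating that sorts body-GFP
    homozygotes away from pharyngeal-GFP balancer heterozygotes; whole-well
    brightfield/GFP image segmentation with green-head identification,
    dilation-based local background subtraction and per-worm measurements;
    the downstream screen-statistics pipeline (worm and well filters, plate
    quality control, negative-control normalization, ANOVA plus Dunnett
    many-to-one testing, fold-change hit calling) together with RNAi
    library-layout arithmetic; and luciferase molt-timing binarization at
    75% of a moving average. Every stage is exercised on seeded synthetic
    phantoms (well images, flow profiles, screen tables, luminescence
    traces) generated in-package with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    multcomp,
    jsonlite,
    yaml,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
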
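Package: crtkit
Title: Discovery of CRISPRa-Targetable Regulatory Elements for
    Haploinsufficient Disease Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end computational pipeline for nominating
    cis-regulation-therapy targets for haploinsufficient
    neurodevelopmental-disorder genes: Poisson observed/expected
    prioritization of risk genes from trio de novo variant counts,
    harmonization of multi-source enhancer-gene predictions into
    non-redundant candidate cis-regulatory elements, design and
    negative-binomial activity calling of massively parallel reporter
    assay (MPRA) tiles with empirical false-discovery calibration
    against scrambled controls, CRISPRa guide RNA enumeration and
    iterative selection, and hit calling in multiplex single-cell
    CRISPRa screens with a conditional randomization test calibrated on
    non-targeting controls. A synthetic-data module generates every
    input format the pipeline consumes, with planted ground truth, so
    all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
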
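Package: perigranule
Title: Perinuclear Condensate Segmentation, Morphometry and Small RNA
    Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for perinuclear germ-granule biology in the
    C. elegans germline. Implements hierarchical K-means (HKM) histogram
    thresholding and multi-level object extraction for fluorescence
    condensate segmentation, per-granule morphometry (mean intensity, area,
    circularity, nucleus-boundary distance) with germline-level summaries
    and normality-gated group comparisons, reads-per-million small RNA
    quantification with exact log-space hypergeometric gene-set
    enrichment/depletion tests, law-of-mass-action (quadratic isotherm)
    dissociation-constant fitting for thermophoresis titrations, and
    iBAQ-based immunoprecipitation mass-spectrometry enrichment scoring.
    A synthetic-data module generates images, count matrices, titrations and
    proteomics matrices with known ground truth so the whole pipeline is
    testable without raw-data downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
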
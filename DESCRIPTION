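Package: chromcross
Title: Cross-Talk Classification of Chromatin Marks at Meiotic Reader Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to classify histone-methylation-reader (ZCWPW1) binding
    sites by the fate of H3K9 acetylation and chromatin accessibility across
    wild-type and knockout mouse testes. Implements a windowed Poisson
    fold-enrichment peak caller with genome-wide or local background,
    fold-change signal tracks, binned signal matrices around peak centers,
    interval-overlap classification rules (marked/lost/retained acetylation,
    open/lost/retained accessibility, promoter annotation), spectral-count
    filtering of RIME interactor tables with IgG exclusion, and a seeded
    synthetic-data generator with ground-truth labels for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
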
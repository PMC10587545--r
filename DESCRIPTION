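Package: scnaScan
Title: Window-Based Poisson Hotspot Detection for Recurrent Somatic Copy
    Number Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects recurrence hotspots of somatic copy number alteration
    (SCNA) breakpoints across a cancer cohort. Segments are classified by
    width, the genome is tiled into fixed-size windows, per-window per-sample
    overlap counts are modelled as Poisson and the rate parameter lambda is
    estimated by maximum likelihood; windows in the top tail of lambda are
    called hotspots, annotated with overlapping genes and filtered for
    hyper-polymorphic gene families. Downstream stages provide local
    hypergeometric term enrichment, SCNA-burden association tests and
    Kaplan-Meier survival stratification. A seeded synthetic-cohort
    generator with a planted-truth table supports end-to-end testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'association.R'
    'enrichment.R'
    'genome.R'
    'hotspotSet-class.R'
    'windowCounts-class.R'
    'hotspot.R'
    'pipeline.R'
    'scnaScan-package.R'
    'seg-io.R'
    'simulate.R'
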
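Package: hmcfrag
Title: Cell-Free DNA 5hmC Peak and Fragmentation Profiling for Liquid-Biopsy
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated analysis pipeline for cell-free DNA (cfDNA)
    5-hydroxymethylcytosine (5hmC) enrichment sequencing. Builds fixed-width
    consensus peak sets from per-sample peak summits, quantifies peak signal
    as FPKM, identifies differentially hydroxymethylated loci, extracts
    DELFI-style fragmentation-profile features (GC-corrected short/long
    fragment coverage in megabase windows, short-to-long ratio profiles),
    trains stability-selection elastic-net classifiers with weighted
    diagnosis scores, and integrates peak-based and fragmentation-based
    models. Includes a synthetic-cohort generator that emulates the
    mono-nucleosomal cfDNA fragment-length distribution, GC-dependent
    coverage bias, and group-differential 5hmC signal, so the full pipeline
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    glmnet,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
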
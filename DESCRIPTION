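Package: pomecourse
Title: Developmental Time-Course Transcriptomics and Variant Effect
    Annotation for Pome Fruit Cultivar Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for multi-cultivar fruit-development
    RNA-seq panels: RPKM expression quantification with a
    stages-expressed presence filter, Spearman-correlation sample
    dendrograms, short time-series model-profile clustering with
    permutation significance (STEM-style), maturity-to-senescence
    up/down contrasts with a Welch group test, a twelve-category
    transcript-aware SNP effectiveness classifier (upstream/downstream,
    splice boundary, intron, start/stop codon, synonymous,
    nonsynonymous, premature stop, genome N), hypergeometric gene-set
    enrichment, and soft-thresholded co-expression networks with
    topological overlap. Includes a synthetic-data generator that
    plants genomes, gene models, variants of every effect class, and
    count matrices with known expression structure, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
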
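Package: lsiscan
Title: Lineage-Specific Insertion Discovery from Multiple Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls insertions specific to a focal lineage (by default,
    human against five non-human primates) from MAF multiple-alignment
    blocks using an explicit-gap evidence rule, removes short and
    polymorphic calls to obtain the set fixed in the focal population,
    and characterizes that set against gene models, RepeatMasker-style
    repeat annotations, regulatory evidence (DNase and TF-ChIP
    intervals, GREAT-style basal-plus-extension regulatory domains with
    a region binomial enrichment test), selective-sweep statistics
    (CLR, Fu's F, iHS) and codon site-model likelihood-ratio tests with
    Bonferroni correction. A planted-truth synthetic-data generator
    emulates every input so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
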
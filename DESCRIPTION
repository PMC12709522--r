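Package: methylmark
Title: Forensic Tissue Identification from Bisulfite Amplicon Methylation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of tissue-specific differentially methylated regions from
    multi-tissue per-position methylation tables via an informativeness score with
    logistic penalization of major exceptions, and a targeted bisulfite-amplicon
    read-level diagnostic: per-read primer/identity/CpG-coverage filtering,
    methylation-pattern calling, decision-tree evaluation, threshold-based sample
    classification with multi-assay consensus, and read-resampling detection
    sensitivity. Includes a seeded synthetic-data generator for methylome
    compendia and bisulfite amplicon reads with conversion noise, sequencing
    error, tissue mixtures, and environmental degradation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    rpart,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
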
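Package: irdetect
Title: Detection of Differential Intron Retention from RNA-Seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differential intron retention (IR) events between a
    treatment and a control RNA-seq condition from spliced alignments and a
    gene annotation. Implements a rank-based caller that scores each intron
    from intron/exon read-count ratios, intron/junction ratios and intron
    coverage between conditions, together with a machine-learning classifier
    trained on vote-derived labels over a 17-feature representation, plus an
    information-gain feature ranking and a seeded synthetic-alignment
    generator so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    digest,
    jsonlite,
    optparse,
    rpart,
    randomForest,
    pROC,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
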
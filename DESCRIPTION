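Package: oriscan
Title: Sequence-Based Prediction and Repertoire Analysis of DNA Replication Origins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts mammalian DNA replication origins from genome sequence
    alone using a paired-window G-rich hyper-motif scan refined by machine
    learning (greedy logistic-regression feature selection and a
    lasso-regularised linear support vector machine, both scored by
    length-weighted balanced accuracy), and analyses origin repertoires
    mapped by short nascent strand sequencing: background-subtracted
    TMM-scaled activities, decile classification into core and stochastic
    origins, summit and orientation calling, clustering, base-composition
    and pre-RC distance profiles, shuffle-based overlap enrichment, and
    origin density across topologically associating domains. A seeded
    synthetic-genome generator with planted origin cassettes provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    edgeR,
    methods,
    graphics,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
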
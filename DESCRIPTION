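Package: methylseg
Title: Cell-Type-Specific CpG Methylation Susceptibility Modeling with
    k-mer Mixture Logistic Regression and Segment Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models cell-type-specific DNA methylation susceptibility of
    promoter amplicons at three resolutions: individual CpG sites, DNA
    segments, and whole promoter regions. The core is a k-mer mixture
    logistic regression whose features are occurrence counts of a small
    set of selected k-mers, combined with a random binary segment-merging
    hill-climbing search over boundary-variable configurations that
    minimizes a size-weighted squared prediction error. Includes Welch
    t-test and consensus random-forest k-mer selection, ten-fold
    cross-validated AUC evaluation, a synthetic bisulfite-style data
    generator with planted k-mer effects for end-to-end validation, and
    readers and writers for FASTA, tabular methylation summaries, BED6
    segment output and JSON model serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    randomForest,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
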
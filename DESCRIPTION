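Package: stemIndex
Title: Transcriptomic Stemness Index Training, Scoring and Aging Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a one-class logistic regression (OCLR) stemness signature from
    pluripotent-labeled bulk expression profiles, scores arbitrary bulk RNA-seq
    samples on a 0-1 stemness scale by rank correlation against the signature
    weight vector, and runs the downstream aging-association battery: per-tissue
    Pearson correlations of stemness with age under Benjamini-Hochberg FDR
    control, covariate-adjusted linear models (sex, Hardy death code, tissue
    region), same-subject cross-tissue correlation matrices, and gene-set based
    proliferation and senescence associations. Ships a synthetic bulk RNA-seq
    cohort simulator with known ground truth so the full pipeline is verifiable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
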
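Package: zibench16S
Title: Benchmarking Zero-Imputation and Normalization Pipelines for 16S rRNA-Gene Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for preprocessing of sparse 16S
    rRNA-gene (OTU/ASV) count tables. Provides a two-step count simulator
    with known ground truth (gamma-distributed biological variability
    followed by multivariate-hypergeometric sequencing loss), five
    library-size normalization methods (TSS, CSS, TMM, median-of-ratios,
    GMPR), five zero-imputation strategies (local least squares, Bayesian
    square-root and multiplicative zero replacement for compositions, and
    dropout-model and consensus-clustering imputers), a combinator that
    enumerates the 35 normalization/imputation pipelines, and an evaluation
    suite measuring sparsity recovery, technical-zero classification,
    abundance-profile error (SMAPE, Aitchison distance), alpha and beta
    diversity preservation, and differential-abundance concordance against
    the simulated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    pracma,
    yaml,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
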
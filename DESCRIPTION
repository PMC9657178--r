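Package: degconsensus
Title: Consensus Differential Expression Analysis for Two-Condition RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies differentially expressed genes (DEGs) from a
    two-condition RNA-seq count table by running up to four statistically
    distinct testing engines -- a negative-binomial exact test with TMM
    normalization, a negative-binomial Wald test with median-of-ratios
    size factors, a nonparametric noise-distribution test, and an
    empirical-Bayes beta-negative-binomial mixture -- and intersecting
    their DEG calls into a consensus table with direction-consistency
    marking, Venn partition counts, and confusion-matrix evaluation
    against a gold standard. Includes a seeded negative-binomial count
    simulator with known truth so the whole pipeline is testable at desk
    scale, and a command-line interface with run, simulate and evaluate
    subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    DESeq2
Config/testthat/edition: 3
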
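Package: csdsomics
Title: Multi-Omics Analysis of Chronic Social Defeat Stress Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing chronic social defeat stress (CSDS)
    experiments across behavioural, transcriptomic, miRNA and proteomic
    read-outs: social interaction phenotyping with susceptible/resilient
    classification, empirical-Bayes moderated-t differential expression,
    preranked gene set enrichment with permutation-based FDR,
    hypergeometric overrepresentation, signed-regulon activation scores,
    and cross-strain/cross-omics convergence rules. A synthetic-data
    generator emulates the statistical structure of such studies
    (negative-binomial counts with library-size and batch variation,
    log-normal protein ratios, strain-opposite planted gene-set effects)
    so every stage can be exercised end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
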
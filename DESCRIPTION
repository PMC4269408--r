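Package: qgrm
Title: Genomic Relationships, Genomic Inbreeding and GBLUP/GREML from SNP
    Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs genomic additive and dominance relationship and
    correlation matrices from biallelic SNP genotypes under a unified
    quantitative-genetics parameterization (across-SNP and within-SNP
    standardizations, expected and sample SNP variances), computes pedigree
    relationships by the tabular method, derives genomic inbreeding
    coefficients (diagonal-based, allele-frequency-weighted diagonal, and
    parental genomic coancestry/correlation), and fits additive plus
    dominance mixed models by GBLUP and REML (EM and average-information
    algorithms) with SNP-effect back-solving.  Includes a gene-dropping
    simulator of pedigrees, unlinked SNP genotypes and phenotypes with known
    variance components, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
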
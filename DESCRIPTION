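Package: haplohm
Title: Haplotype and Regional Heritability Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Regional heritability mapping of quantitative traits with
    SNP-based (RHM) and haplotype-based (HHM) regional genomic relationship
    matrices. Analysis windows are haplotype blocks delimited by
    recombination hotspots taken from a reference genetic map.  A
    two-variance-component mixed model (regional plus whole-genome
    relationship matrix) is fitted by average-information REML with
    likelihood-ratio tests for the regional component.  Includes a
    forward-in-time population simulator and phenotype generators for four
    regional genetic architectures, readers and writers for phased VCF,
    genetic-map, phenotype and GCTA-style GRM files, and a command-line
    interface for genome scans and replicate studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
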
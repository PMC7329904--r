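Package: pleioscan
Title: Two-Stage Genome-Wide Pleiotropy Scanning for Bone Mineral Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for a two-stage genome-wide pleiotropy scan linking
    established non-bone GWAS loci to bone mineral density (BMD). The
    pipeline curates a GWAS-catalog-style association table with rule-based
    exclusions, expands candidates with perfect linkage-disequilibrium (LD)
    proxies computed from a genotype reference panel, screens candidates
    against femoral-neck and lumbar-spine BMD summary statistics with the
    Simes/Benjamini-Hochberg false-discovery-rate step-up procedure, prunes
    the discoveries to an independent set (r^2 < 0.2), and replicates them
    in an individual-level cohort using a heel-ultrasound-derived BMD
    Z-score adjusted for ancestry principal components, after outlier QC
    and KING-robust kinship-based removal of related samples. A synthetic
    study generator with planted pleiotropic effects, LD block structure
    and related sample pairs supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
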
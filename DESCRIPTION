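Package: SnpHapPower
Title: SNP- and Haplotype-Based GWAS Power Comparison in Multigenerational Pedigrees
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and association toolkit for comparing single-SNP
    mixed-model genome-wide association scans with haplotype-cluster score
    tests in closed multigenerational livestock populations. Provides
    pedigree generation and gene-dropping with calibrated linkage
    disequilibrium, genotype quality control (minor allele frequency, call
    rate, exact Hardy-Weinberg test), Meuwissen-Luo inbreeding and the
    pedigree numerator relationship matrix, animal-model REML on a spectral
    decomposition, an exact per-marker mixed-model Wald scan, a
    fastPHASE-style ancestral haplotype hidden Markov model with a
    GLASCOW-style score test under a gamma-approximated permutation null,
    and a replicated QTL-detection power study across minor allele
    frequency classes, QTL heritabilities and distance windows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
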
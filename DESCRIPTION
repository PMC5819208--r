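Package: pleioscan
Title: Multi-Trait Pleiotropy Scanning of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint testing of GWAS summary statistics across correlated
    phenotypes with the O'Brien combined-Z statistic, an explicit pleiotropy
    declaration rule, genomic-control diagnostics, VEGAS-style gene-based
    Monte Carlo tests driven by a reference linkage-disequilibrium panel, and
    downstream differential-expression and cis-eQTL linear models. Includes a
    synthetic-data generator emulating correlated ordinal and binary
    neuropathological traits (neuritic plaques, neurofibrillary tangles,
    cerebral amyloid angiopathy) with LD-blocked genotypes and known
    pleiotropic causal variants, so every stage of the pipeline is testable
    end to end with recorded ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
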
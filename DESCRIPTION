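Package: hemimeth
Title: Strand-Resolved Hemi-Methylation Analysis of Bisulfite Sequencing Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies hemi-methylated CpG dyads from
    strand-resolved bisulfite sequencing calls. Implements the Absolute
    Methylation Difference (AMD) statistic at CpG-site and gene (TSS-window)
    level together with its exact binomial-expectation null, a within-dyad
    read-reshuffle permutation test for strand asymmetry, condition
    comparisons of active (TET1-type) versus passive (DNMT1-knockdown-type)
    DNA demethylation, promoter CpG-density/methylation zone classification,
    mimic-group and matched-demethylation gene selections, and a seeded
    simulator of strand-resolved methylomes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, MethylSeq, Software, StatisticalMethod
RoxygenNote: 7.3.3
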
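Package: rarescan
Title: Rare-Variant Burden Testing and Selection Scans for Isolated Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinship-adjusted rare-variant set association testing in the
    SKAT-O family for quantitative traits in related cohorts, together with
    the surrounding whole-genome analysis machinery: condition-based variant
    masking and functional weighting (LoF confidence classes, CADD, Eigen and
    Phred-rank transforms), genetic relatedness estimation with self-kinship
    diagonals and relative pruning, an effective-number-of-conditions
    study-wide significance threshold, gene-level iHS and Hudson F_ST
    selection scans, and resampling-based site-frequency-spectrum comparison
    between cohorts of unequal size. A fully synthetic phased-cohort
    generator (founder-mosaic haplotypes, pedigree relatedness, functional
    annotation layers, polygenic plus rare-burden traits, optional partial
    selective sweeps) exercises every stage without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
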
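Package: snarc
Title: Regional Constraint Scanning and Burden Testing for Small
    Non-Coding RNA Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers pathogenic sub-regions of small non-coding RNA genes
    (snRNAs and similar short loci) from population and rare-disease cohort
    data. Implements a sliding-window scan of observed versus possible
    single-nucleotide variants normalised to the per-gene median, calling of
    depleted (constrained) regions, a random intergenic null with a
    Monte-Carlo Fisher-Pitman permutation test, exact case/control and de
    novo burden statistics with conditional-MLE odds ratios, a recurrent
    de novo variant screen, phenotype-term enrichment, and a synthetic
    cohort simulator that emulates the statistical structure of large
    population and trio datasets so the whole pipeline can be exercised
    and validated without access-controlled data.
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
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
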
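Package: ssrmarkers
Title: Polymorphic Microsatellite Discovery and Primer Design from
    Pooled Multi-Individual Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovers polymorphic microsatellite (SSR) loci directly from a
    paired-end sequencing run of a pooled, untagged multi-individual library
    and designs ranked PCR primer pairs for them.  The pipeline trims
    adapters and low-quality tails, merges read pairs across the repeat,
    keeps restriction-digest fragments, mines perfect and compound SSRs,
    clusters repeat-excised flanking signatures into loci at 90% identity,
    tabulates observed and potential allele counts per locus, and designs
    primers under nearest-neighbor melting-temperature constraints.  A
    seeded library simulator with a ground-truth manifest supports
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
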
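Package: epivef
Title: Epiallele-Resolved Promoter Methylation Analysis for Bisulfite
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting low-level, mosaic promoter hypermethylation
    from ultradeep bisulfite amplicon sequencing. Each sequenced fragment is
    treated as one epiallele (an ordered CpG methylation pattern); the
    hypermethylated variant epiallele frequency (VEF) summarises a sample and
    is compared against tissue-specific cutoffs to call methylation
    positivity. A single SNP inside one amplicon phases epialleles to
    alleles for allele-specific methylation and fold-enrichment analysis.
    Includes a seeded, truth-annotated fragment simulator for mosaic
    monoallelic epimutations, exact binomial confidence intervals and
    Fisher tests for cohort summaries, and ggplot2 displays of ranked
    epiallele beta curves, per-CpG methylation profiles and allelic
    fold-enrichment quadrants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
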
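Package: zsweep
Title: Selection-Signature Scanning on the Avian Z Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects selection signatures between two divergently selected
    populations from SNP chip genotypes, combining three complementary scans:
    sliding-window Weir-Cockerham FST with a Tukey-fence outlier threshold,
    cross-population extended haplotype homozygosity (XPEHH) with chromosome-wide
    standardisation, and EigenGWAS (per-SNP regression of genotype-derived
    eigenvectors with genomic control). Significant markers and windows are
    merged within and across methods into candidate regions, annotated against
    gene and QTL interval tracks, and candidate genes can be screened with a
    two-group microarray differential-expression stage. A seeded synthetic-data
    generator (Balding-Nichols divergence, haplotype sweeps, log-scale
    expression) makes every stage testable without external downloads.
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
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
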
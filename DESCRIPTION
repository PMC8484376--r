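Package: poolcross
Title: Pool-Seq Genome Scans and Backcross Linkage Analysis for Plumage-Pattern Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a fully penetrant Mendelian locus in an
    experimental backcross using pooled whole-genome resequencing. Implements
    per-variant pool Fst with 30 kb windowed Z scores and Bonferroni calls,
    the pooled-heterozygosity (Hp) scan with its fixed Z cutoff for
    identical-by-descent detection across breed pools, informative-SNP
    selection filters, genotype-matrix coding and non-recombining-interval
    detection, segregation-distortion chi-square tests, two-point backcross
    LOD scores, and delta-delta-Ct expression and allelic-imbalance
    statistics. A seeded backcross simulator (pedigree, recombinant gametes
    under the Haldane map function, pooled binomial read sampling, multi-breed
    pools with an optional shared IBD segment) makes every stage testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    tidyr,
    withr,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
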
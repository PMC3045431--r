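Package: poolscreen
Title: Rare-Variant Screening from Pooled-DNA Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for rare single-nucleotide variant discovery from deep
    sequencing of pooled DNA. Parses strand-aware base counts from
    samtools-style text pileups, masks PCR-primer positions, builds
    empirical per-substitution-type sequencing-error distributions and
    calls variants with a dual-strand percentile threshold, scores
    forward/reverse strand balance, and estimates pool minor-allele
    counts. Downstream, provides case-control association on genotype
    count tables (Pearson chi-square, allele- and carrier-based odds
    ratios with Woolf confidence intervals) and DerSimonian-Laird
    random-effects meta-analysis of per-study odds ratios. Includes a
    pooled-amplicon pileup simulator with known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
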
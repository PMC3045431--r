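# Accessors for the bundled published-screen tables: the validated
# variant list, genotype counts and replication-study effects from a
# pooled-DNA deep-sequencing screen of the Nicastrin coding regions in
# Alzheimer's cases and matched controls (311 cases / 360 controls in
# the pools; follow-up genotyping across three European cohorts).

screen_file <- function(name) {
  path <- system.file("extdata", name, package = "poolscreen")
  if (path == "") stop_ps("bundled file %s not found", name)
  path
}

#' Bundled pooled-screen variant table
#'
#' Per-variant pool sequencing results (combined frequency, depth,
#' strand-balance ratio score) for a case pool and a control pool, with
#' the individual-genotyping validation frequencies where carried out.
#' Substitutions absent from a pool carry frequency 0 and an NA score;
#' `passed_cutoff` marks whether the substitution cleared the calling
#' threshold.
#'
#' @return data.frame, one row per (position, substitution).
#' @export
screen_variants_table <- function() {
  utils::read.table(screen_file("screen_variants.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' Bundled genotype-count table for validated variants
#'
#' Individual-genotyping counts (genotyped n, minor-allele homozygotes,
#' heterozygotes) per variant and group for the five validated variants.
#'
#' @return data.frame in the long format expected by [run_assoc()].
#' @export
screen_genotypes_table <- function() {
  utils::read.table(screen_file("screen_genotypes.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}

#' Bundled replication-study effects table
#'
#' Per-cohort odds ratios with 95% confidence intervals for the N417Y
#' variant across the three replication cohorts, as input for
#' [dl_meta()].
#'
#' @return data.frame with `study`, sample sizes, minor-allele
#'   frequencies, `or`, `ci_lo`, `ci_hi`.
#' @export
screen_studies_table <- function() {
  utils::read.table(screen_file("screen_studies.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}
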
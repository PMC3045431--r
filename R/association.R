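# Case-control association on validated variants: 2x2 tables on either
# an allele or a carrier basis, Pearson chi-square (no continuity
# correction), odds ratios with Woolf confidence intervals, and the
# pooled-vs-individual-genotyping frequency validation.

#' Genotype counts for one group
#'
#' @param group group label (e.g. "case").
#' @param n genotyped individuals.
#' @param hom_minor individuals homozygous for the minor allele.
#' @param het heterozygous individuals.
#' @return object of class `genotype_counts`.
#' @export
genotype_counts <- function(group, n, hom_minor, het) {
  stopifnot(n >= 0, hom_minor >= 0, het >= 0)
  if (hom_minor + het > n)
    stop_ps("hom_minor + het must not exceed n")
  structure(list(group = group, n = as.integer(n),
                 hom_minor = as.integer(hom_minor), het = as.integer(het)),
            class = "genotype_counts")
}

#' Minor-allele frequency from genotype counts
#'
#' `(2 * hom_minor + het) / (2n)`.
#'
#' @param gc a [genotype_counts()].
#' @return frequency in `[0, 1]`.
#' @export
maf_from_genotypes <- function(gc) {
  (2 * gc$hom_minor + gc$het) / (2 * gc$n)
}

#' Reconstruct a minor-allele count from a printed frequency
#'
#' `round(freq * 2n)`, ties away from zero. Under the all-heterozygote
#' assumption appropriate for rare variants the carrier count equals
#' this allele count.
#'
#' @param freq minor-allele frequency in `[0, 1]`.
#' @param n_individuals genotyped individuals.
#' @return reconstructed allele count.
#' @export
allele_counts_from_frequency <- function(freq, n_individuals) {
  stopifnot(all(freq >= 0 & freq <= 1))
  round_half_away(freq * 2 * n_individuals)
}

new_contingency <- function(a, b, c, d, basis) {
  if (any(c(a, b, c, d) < 0)) stop_ps("contingency cells must be non-negative")
  structure(list(a = a, b = b, c = c, d = d, basis = basis),
            class = "contingency_table")
}

#' Allele-based 2x2 table from case and control genotype counts
#'
#' Minor alleles `= 2 * hom_minor + het`; row totals are `2n`
#' chromosomes per group. Cells: (case-minor, case-major,
#' control-minor, control-major).
#'
#' @param case,control [genotype_counts()] objects.
#' @return a `contingency_table` with `basis = "allele"`.
#' @export
allele_table <- function(case, control) {
  a <- 2L * case$hom_minor + case$het
  c_ <- 2L * control$hom_minor + control$het
  new_contingency(a, 2L * case$n - a, c_, 2L * control$n - c_, "allele")
}

#' Carrier-based 2x2 table from case and control genotype counts
#'
#' Carriers (at least one minor allele) vs non-carriers; row totals are
#' `n` individuals per group.
#'
#' @inheritParams allele_table
#' @return a `contingency_table` with `basis = "carrier"`.
#' @export
carrier_table <- function(case, control) {
  a <- case$hom_minor + case$het
  c_ <- control$hom_minor + control$het
  new_contingency(a, case$n - a, c_, control$n - c_, "carrier")
}

#' Carrier-based 2x2 table from reconstructed allele counts
#'
#' For rare variants reported only as frequencies: reconstructs the
#' minor-allele count per group via [allele_counts_from_frequency()],
#' treats every carrier as heterozygous, and builds the carrier table.
#'
#' @param freq_case,freq_control printed minor-allele frequencies.
#' @param n_case,n_control genotyped individuals per group.
#' @return a `contingency_table` with `basis = "carrier"`.
#' @export
carrier_table_from_frequencies <- function(freq_case, n_case,
                                           freq_control, n_control) {
  a <- allele_counts_from_frequency(freq_case, n_case)
  c_ <- allele_counts_from_frequency(freq_control, n_control)
  new_contingency(a, n_case - a, c_, n_control - c_, "carrier")
}

#' Pearson chi-square test on a 2x2 table
#'
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with no continuity
#' correction; p from the upper tail of the 1-df chi-square law. A zero
#' margin leaves the statistic undefined (NA, with a warning).
#'
#' @param tab a `contingency_table`.
#' @return list with `statistic`, `p`, `df = 1`.
#' @export
pearson_chi2 <- function(tab) {
  a <- tab$a; b <- tab$b; c_ <- tab$c; d <- tab$d
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    warning("zero margin: chi-square statistic undefined")
    return(list(statistic = NA_real_, p = NA_real_, df = 1L))
  }
  stat <- n * (a * d - b * c_)^2 / prod(margins)
  list(statistic = stat, p = stats::pchisq(stat, 1L, lower.tail = FALSE),
       df = 1L)
}

#' Odds ratio of a 2x2 table
#'
#' `ad / (bc)`. A zero cell is an error unless `haldane = TRUE`, which
#' adds 0.5 to every cell (Haldane-Anscombe correction).
#'
#' @param tab a `contingency_table`.
#' @param haldane apply the +0.5 correction when any cell is zero.
#' @return the odds ratio.
#' @export
odds_ratio <- function(tab, haldane = FALSE) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0)) {
    if (!haldane)
      stop_ps("zero cell in 2x2 table; set haldane = TRUE for the +0.5 fallback")
    cells <- cells + 0.5
  }
  cells[1] * cells[4] / (cells[2] * cells[3])
}

#' Woolf confidence interval for the odds ratio
#'
#' Normal approximation on the log scale:
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, with `z = 1.96` at
#' the default 95% level.
#'
#' @inheritParams odds_ratio
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`.
#' @export
woolf_ci <- function(tab, level = 0.95, haldane = FALSE) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0)) {
    if (!haldane)
      stop_ps("zero cell in 2x2 table; set haldane = TRUE for the +0.5 fallback")
    cells <- cells + 0.5
  }
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  c(lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}

#' Association summary for one variant on both bases
#'
#' @inheritParams allele_table
#' @param haldane passed through to [odds_ratio()]/[woolf_ci()].
#' @return data.frame with one row per basis (allele, carrier): OR, CI,
#'   chi-square, p.
#' @export
associate <- function(case, control, haldane = FALSE) {
  do.call(rbind, lapply(list(allele_table(case, control),
                             carrier_table(case, control)), function(tab) {
    chi <- suppressWarnings(pearson_chi2(tab))
    or <- tryCatch(odds_ratio(tab, haldane), error = function(e) NA_real_)
    ci <- tryCatch(woolf_ci(tab, haldane = haldane),
                   error = function(e) c(lo = NA_real_, hi = NA_real_))
    data.frame(basis = tab$basis, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               or = or, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               chi2 = chi$statistic, p = chi$p, stringsAsFactors = FALSE)
  }))
}

#' Pooled-sequencing vs individual-genotyping frequency correlation
#'
#' Pearson product-moment correlation between pool combined frequencies
#' and individual-genotyping frequencies, restricted to variants whose
#' strand-balance ratio score is at or below the cutoff ("not present"
#' sequencing entries enter as frequency 0). Validates the accuracy of
#' pool allele-frequency estimation.
#'
#' @param pooled_freq combined pool frequencies.
#' @param genotyped_freq matched individual-genotyping frequencies.
#' @param fr_score strand-balance scores of the pooled calls.
#' @param score_cutoff keep variants with `fr_score <= score_cutoff`
#'   (default 1).
#' @return Pearson r, or NA when either filtered vector is constant.
#' @export
validation_correlation <- function(pooled_freq, genotyped_freq, fr_score,
                                   score_cutoff = 1) {
  stopifnot(length(pooled_freq) == length(genotyped_freq),
            length(pooled_freq) == length(fr_score))
  keep <- !is.na(fr_score) & fr_score <= score_cutoff
  x <- pooled_freq[keep]; y <- genotyped_freq[keep]
  if (length(x) < 3L)
    stop_ps("fewer than 3 variant pairs after strand-score filtering")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
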
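# Shared design builders for simulation-based tests. Depths here are
# scaled down from the study's (tens of thousands of reads per strand)
# to keep the suite fast; properties that need deep coverage say so.

# n_pos non-primer positions spread over amplicons of 200 usable bp each
tiling_amplicons <- function(n_pos, primer_len = 20L, chrom = "chr1") {
  n_amp <- ceiling(n_pos / 200L)
  starts <- 1001L + 300L * (seq_len(n_amp) - 1L)
  data.frame(chrom = chrom, start = starts,
             end = starts + 200L + 2L * primer_len,
             fwd_primer_len = primer_len, rev_primer_len = primer_len,
             stringsAsFactors = FALSE)
}

# error-only pool design: no variants, default per-type error rates
error_only_design <- function(n_pos = 1000L, depth = 200, seed = 1L,
                              error_rates = default_error_rates(),
                              n_individuals = 311L) {
  pool_design(n_individuals, tiling_amplicons(n_pos),
              mean_depth_per_strand = depth, error_rates = error_rates,
              seed = seed)
}

flat_error_rates <- function(lambda) {
  setNames(rep(lambda, 12L), names(default_error_rates()))
}

# one amplicon with no primers: every position usable (variant placement)
bare_amplicon <- function(len = 41L, start = 1001L, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = start + len,
             fwd_primer_len = 0L, rev_primer_len = 0L,
             stringsAsFactors = FALSE)
}

run_pool <- function(design, n_individuals = design$n_individuals, ...) {
  sim <- simulate_pileup(design)
  cols <- mask_primers(parse_pileup(sim$pileup), design$amplicons)
  freqs <- substitution_frequencies(cols)
  thr <- error_thresholds(freqs, ...)
  list(sim = sim, cols = cols, freqs = freqs, thr = thr,
       calls = call_variants(freqs, thr, n_individuals = n_individuals))
}
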
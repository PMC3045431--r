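# A scaled-down pooled-sequencing design: one case pool of 311 diploid
# individuals, four 220 bp amplicons with 20 bp primers, 500 expected
# reads per position per strand, default substitution error rates, and
# two planted rare variants.
n_individuals: 311
mean_depth_per_strand: 500
seed: 7
amplicons:
  - {chrom: chr1, start: 1001, end: 1221, fwd_primer_len: 20, rev_primer_len: 20}
  - {chrom: chr1, start: 1401, end: 1621, fwd_primer_len: 20, rev_primer_len: 20}
  - {chrom: chr1, start: 1801, end: 2021, fwd_primer_len: 20, rev_primer_len: 20}
  - {chrom: chr1, start: 2201, end: 2421, fwd_primer_len: 20, rev_primer_len: 20}
variants:
  - {pos: 1101, ref: G, alt: A, k: 3}
  - {pos: 1501, ref: A, alt: C, k: 9}
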
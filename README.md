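# poolscreen

Rare-variant screening from deep sequencing of pooled DNA.

When a region of interest is sequenced as a single library made from the
combined DNA of hundreds of individuals, only aggregate allele
frequencies are observable — a single heterozygote among N diploid
individuals contributes a frequency of just 1/(2N), often below the
sequencing error rate of some substitutions. `poolscreen` implements the
analysis pipeline for such pooled amplicon screens:

- **Strand-aware pileup parsing** — per-position forward/reverse base
  counts decoded from samtools-style text pileup, with PCR-primer
  positions masked.
- **Empirical error-threshold calling** — for each of the 12 ordered
  ref→alt substitution types, the observed per-strand substitution
  frequencies across all positions form an empirical error
  distribution; the 97.5th percentile of that distribution is the
  calling cutoff, and a variant is called only when *both* strands
  exceed it. Strand balance is scored as
  s = |f_fwd − f_rev| / ((f_fwd + f_rev)/2) ∈ [0, 2].
- **Pool allele-count estimation** — k̂ = round(f · 2N), and the
  detection limit k_min = min{k : k/(2N) > t} implied by a threshold t.
- **Case-control association** — allele- and carrier-based 2×2 tables
  from genotype counts, Pearson χ² (1 df, no continuity correction),
  odds ratios with Woolf confidence intervals
  exp(ln OR ± 1.96·√(1/a + 1/b + 1/c + 1/d)).
- **Random-effects meta-analysis** — DerSimonian–Laird pooling of
  per-study odds ratios supplied as OR + 95% CI, with
  τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)).
- **A synthetic pool simulator** — Poisson depth per strand, binomial
  variant reads at p = k/(2N), binomial errors per substitution type —
  so the whole pipeline can be validated end to end with known truth.

The package ships the printed summary tables of a published pooled
screen of the Nicastrin gene in Alzheimer's cases and controls (311
cases / 360 controls, 16 amplicons) as example inputs.

## Worked example

```r
library(poolscreen)

## association for the screen's significant rare variant:
## 11 heterozygotes of 287 cases vs 3 of 345 controls
case <- genotype_counts("case", 287, 0, 11)
ctrl <- genotype_counts("control", 345, 0, 3)
tab  <- allele_table(case, ctrl)
pearson_chi2(tab)$statistic   # 6.279546
pearson_chi2(tab)$p           # 0.01221394
odds_ratio(tab)               # 4.474245
woolf_ci(tab)                 # lo 1.24217, hi 16.11604

## meta-analysis across the three replication cohorts
studies <- screen_studies_table()
eff <- study_effects(studies$study, studies$or, studies$ci_lo, studies$ci_hi)
dl_meta(eff)
#> DerSimonian-Laird random-effects meta-analysis (3 studies)
#>   pooled OR 2.318 (95% CI 1.007-5.340)
#>   z = 1.98, p = 0.048
#>   Q = 1.317 (df 2), tau^2 = 0.0000, I^2 = 0.0%
```

The χ² of 6.28 (p = 0.012) says the minor-allele count differs between
cases and controls beyond chance at this one variant; the allele-based
OR ≈ 4.47 estimates a four-fold enrichment in cases. The pooled OR of
2.32 with z = 1.98 (p = 0.048) is the weakly significant overall effect
once the two non-significant replication cohorts are averaged in, with
τ² = 0 meaning the three cohorts show no excess heterogeneity beyond
their sampling error.

A full simulated pipeline run from the shell:

```sh
Rscript inst/cli/poolscreen.R simulate \
  --design inst/extdata/example_design.yaml \
  --out-pileup pool.pileup --out-truth truth.tsv
Rscript inst/cli/poolscreen.R call \
  --pileup pool.pileup --n-individuals 311 \
  --out-thresholds thresholds.tsv --out-calls calls.tsv
Rscript inst/cli/poolscreen.R assoc \
  --genotypes inst/extdata/screen_genotypes.tsv --out assoc.tsv
Rscript inst/cli/poolscreen.R meta \
  --effects inst/extdata/screen_studies.tsv --out pooled.tsv
```

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "poolscreen",
                               load_package = "installed")'
```

The suite checks the parser dialect against hand-decoded lines, the
quantile thresholds against an independent interpolation oracle, the
chi-square against the expected-count form, the meta-analysis against
`metafor`, and the caller's calibration, sensitivity and copy-number
recovery on simulated pools with known truth.

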
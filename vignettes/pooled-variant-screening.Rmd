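---
title: "Methods: rare-variant screening from pooled-DNA deep sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant screening from pooled-DNA deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The problem

Sequencing a single library made from the pooled DNA of N diploid
individuals turns individual genotypes into one aggregate signal: a
variant carried on k of the 2N chromosomes appears as an
alternate-allele frequency of p = k/(2N) at its position. For a pool of
~300 individuals a single heterozygote contributes p ≈ 0.0016 — below
the raw error rate of the noisier substitution types on short-read
platforms. Distinguishing rare variants from sequencing and PCR error
is therefore the central statistical problem, and the error rate — not
depth — is the limiting factor once coverage is deep.

`poolscreen` implements a screening pipeline for this setting: parse
strand-resolved base counts from pileup text, build per-substitution
error distributions empirically, call variants with a dual-strand
percentile cutoff, estimate pool allele counts, and carry called or
validated variants into case-control association and random-effects
meta-analysis.

## The calling model

Errors are treated as occurring at a roughly constant per-base
proportion for each ordered substitution type (ref→alt; 12 types), so
the observed frequency of a given substitution across error-only
positions forms a stable empirical distribution. Rather than fitting a
parametric rate, the caller takes, for each type, the empirical
97.5th percentile of the per-strand frequencies pooled over all
non-primer positions with that reference base, and uses it as the
calling cutoff `t`. A substitution is called when

- its forward-strand frequency strictly exceeds `t`, **and**
- its reverse-strand frequency strictly exceeds `t`, **and**
- both strands reach the minimum depth (default 50 reads/strand).

Treating strands separately is the main artifact filter: PCR- and
alignment-induced false signals are typically strand-asymmetric, so
requiring concordant exceedance drives the false-call rate from
roughly 1 − q = 2.5% per strand toward (1 − q)² when strand errors are
independent. Residual strand imbalance is reported as the ratio score

    s = |f_fwd − f_rev| / ((f_fwd + f_rev) / 2) ∈ [0, 2],

with s = 2 meaning a one-strand-only signal. Variants with s > 1 are
excluded from frequency-validation comparisons.

The estimated pool allele count is k̂ = round(f·2N) (ties away from
zero), and a threshold `t` implies the detection limit
k_min = min{k : k/(2N) > t}. With thresholds near 0.004–0.010 and
N = 311 this yields k_min between 3 and 7 — the practically relevant
window for the cleanest and noisiest substitution types respectively.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q` | 0.975 | percentile of the error distribution used as cutoff |
| `min_depth` | 50 reads/strand | below this a position never enters calling |
| `mode` | `"pooled"` | both strands enter one error distribution (vs `"per_strand"`) |
| `two_pass` | `FALSE` | recompute thresholds after dropping first-pass exceedances |
| quantile method | linear interpolation | vs nearest-rank |
| `score_cutoff` | 1 | strand-balance bound for the validation set |

`q` trades sensitivity against specificity directly: at q = 0.975 about
2.5% of error-only (position, type, strand) records exceed the cutoff
on a single strand. `min_depth` guards against unstable frequencies at
amplicon edges, where a handful of reads can produce large spurious
frequencies. Thresholds are computed per pool, because coverage and
error profiles differ between libraries; the same variant can
legitimately clear calling in one pool only.

## Design choices that were genuinely open

**One-pass thresholds.** Variant positions are not excluded before the
error quantile is computed. True variants are rare (a handful among
thousands of position-type records), so their inflation of the 97.5th
percentile is negligible in realistic panels, and a one-pass histogram
is what a screening pipeline computes naturally. A `two_pass` switch
exists for small panels where a common variant could drag its own
threshold up.

**Pooled-strand error distribution.** The two strands' frequencies
enter one distribution per type by default. They estimate the same
underlying rate, and pooling doubles the sample per type; a
`per_strand` mode is available for chemistries with strand-asymmetric
error spectra.

**Strict inequality at the cutoff.** A frequency exactly equal to the
threshold is not called. With continuous frequencies ties are
measure-zero; with discrete shallow-depth data strictness is the
conservative choice.

**Linear-interpolation quantile.** The default matches R's type-7
definition; nearest-rank is available. At the sample sizes involved
(thousands of records per type) the difference is far below the
binomial noise on any threshold.

**Association bases.** Allele-based 2×2 tables (minor vs major allele
counts, totals 2n) are the primary basis and reproduce the screen's
published χ² and OR; carrier-based tables (carriers vs non-carriers,
totals n) are emitted alongside because replication-cohort ORs for rare
variants are conventionally carrier-based — for variants with no
homozygotes the two differ only through the totals. No continuity
correction is applied (required to match the published 1-df χ²); a
Bonferroni column is emitted for transparency, though the screen's
p-values were reported unadjusted.

**CI inversion with z = 1.96.** Published 95% intervals are
conventionally built with 1.96, so converting a printed (OR, CI) back
to a log-OR and SE uses SE = (ln hi − ln lo)/3.92 with the same fixed
multiplier. Using a higher-precision normal quantile would not
round-trip published tables.

**Reconstruction from printed frequencies.** Replication cohorts are
often available only as printed frequencies; counts are rebuilt as
round(freq·2n) with ties away from zero, and carriers assumed
heterozygous (appropriate for variants this rare). Reconstruction from
3-decimal frequencies is exact only when the printed value rounds back
to the true count; one bundled cohort row (the smallest, "Other Western
Europeans") is known not to round-trip, which is why the meta-analysis
consumes printed ORs and CIs rather than reconstructed counts.

## The meta-analysis

DerSimonian–Laird random effects on the log-OR scale: fixed weights
w_i = 1/SE_i², Cochran's Q, the method-of-moments between-study
variance τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)), random-effects
weights w*_i = 1/(SE_i² + τ²), pooled θ* = Σw*θ/Σw* with
SE* = 1/√Σw*, z = θ*/SE* and a two-sided normal p. τ² is truncated at
zero, so when Q ≤ k − 1 the result coincides with fixed-effect
inverse-variance pooling — which is the case for the bundled
three-cohort table (Q ≈ 1.32 < 2). Q and I² are reported even when the
original analysis omitted them.

```{r meta}
studies <- screen_studies_table()
eff <- study_effects(studies$study, studies$or, studies$ci_lo, studies$ci_hi)
dl_meta(eff)
```

Recomputed per-study percent weights differ from the bundled printed
ones in the second decimal (42.15/48.83/9.02 vs 42.14/48.86/9.00)
because the original weights were evidently computed from unrounded
internal estimates while the package necessarily starts from the
printed, rounded ORs and CIs; agreement is to ±0.05 of a percentage
point, and the pooled OR and z agree to the printed precision.

## What the simulator emulates — and what it does not

`simulate_pileup()` generates, per position and strand independently,
a Poisson read depth around the design mean; at variant positions,
Binomial(depth, k/(2N)) alternate reads; for every other alternate
base, binomial error reads at that substitution type's rate λ, drawn
sequentially from the not-yet-assigned reads so that counts always sum
to the printed depth. Overlapping amplicons contribute additive depth
and one pileup line. The same seed yields byte-identical output.

Defaults mirror the screening study the bundled tables come from:
pools of 311 (case) and 360 (control) diploid individuals, a
16-amplicon panel with 20 bp primers, and ~30,000 reads per position
per strand (the bundled screen's per-position depths span roughly
24,000–120,000 combined). Per-type error rates default to the
0.001–0.01 range, with A→C set noisiest (0.009) and G→A cleanest
(0.0035), reproducing the reported ordering in which a G→A variant was
detectable at 3 copies but an A→C variant only at 7.

Deliberately **not** modeled: read-level artifacts (the simulator
starts at the pileup, as does the pipeline), alignment errors and
soft-clipping, indels, PCR duplicates and jackpot amplification,
overdispersion of depth beyond Poisson, unequal DNA contribution of
pool members, and double errors (a variant read mis-read as a third
base — negligible at λ ≤ 0.05, the enforced cap). Consequently,
passing simulation tests demonstrates the statistical behavior of the
caller under its own error model — calibration of the percentile
cutoff, dual-strand false-call suppression, copy-number recovery — but
not robustness to pooling inaccuracy or alignment artifacts, which in
real screens are exactly what the strand-balance score and individual
genotyping validation are for.

## Numerical notes and degenerate inputs

- Frequencies are exact ratios of integer counts; combined frequency
  is count-weighted, so it always lies between the strand frequencies.
- Positions with reference N or zero depth on either strand are
  skipped with a message; a pileup line whose decoded symbols disagree
  with its depth column is an error naming the line.
- A zero margin makes the χ² undefined (NA with a warning); a zero
  2×2 cell makes the OR an error unless the Haldane +0.5 correction is
  requested, and the pipeline's `run_assoc()` requests it.
- The strand-balance score is NA when both strand frequencies are
  zero; such records are never called.
- `estimate_allele_count` rounds ties away from zero so a printed
  frequency of exactly (k + 0.5)/(2N) maps to k + 1, matching how the
  bundled tables were evidently produced.

## Problem sizes used in the test suite

The suite exercises the caller at depths of 150–10,000 reads per
strand and panels of 60–10,000 positions: calibration of the 2.5%
exceedance uses 10⁴ error-only positions at 200 reads/strand;
copy-number recovery uses 400 positions at 10⁴ reads/strand, 25 seeds,
variants of 3–12 copies; threshold ordering uses 100 seeds of 600
positions. These sizes give Monte-Carlo error comfortably inside each
asserted band while keeping a full run under a minute of simulation
time.

## Known limitations

- The empirical threshold needs enough error-only positions per
  substitution type (≥ 40 observations, or the threshold is flagged
  unreliable); tiny panels should keep the default pooled-strand mode,
  which doubles the observations per type.
- Pool allele counts are biased upward by the error rate of the
  variant's own substitution type (k̂ estimates (p + λ(1−p))·2N); at
  λ = 0.005 and 2N = 622 that is ~3 copies. Screening calls at rare
  frequencies should always be validated by individual genotyping, as
  in the bundled study.
- No indel support anywhere in the pipeline.
- Association assumes one 2×2 table per variant; covariates,
  stratification and age-of-onset modeling are out of scope.
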
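# Pooled-amplicon pileup simulator.
#
# Emulates deep sequencing of a single library made from the DNA of N
# diploid individuals: at every position each strand receives a Poisson
# number of reads; reads at a variant site carry the alternate allele
# with probability k/(2N); every other mismatch is a sequencing error
# drawn at a per-substitution-type rate.

#' Default per-substitution-type error rates
#'
#' One per-base error probability for each of the 12 ordered ref->alt
#' substitution types. The values span 0.001-0.01, the range over which a
#' 97.5th-percentile cutoff on a deep pool yields a detection limit of
#' roughly 3-8 variant copies among ~600 alleles. A>C is set high and
#' G>A low, reflecting the common observation that A>C miscalls are among
#' the noisiest Illumina substitutions while G>A is comparatively clean.
#'
#' @return named numeric vector of length 12; names like `"G>A"`.
#' @export
default_error_rates <- function() {
  r <- c(
    "A>C" = 0.009, "A>G" = 0.004, "A>T" = 0.002,
    "C>A" = 0.005, "C>G" = 0.002, "C>T" = 0.006,
    "G>A" = 0.0035, "G>C" = 0.002, "G>T" = 0.005,
    "T>A" = 0.002, "T>C" = 0.006, "T>G" = 0.004
  )
  r[paste0(SUBST_TYPES$ref, ">", SUBST_TYPES$alt)]
}

#' Default amplicon panel
#'
#' Sixteen non-overlapping 220 bp amplicons with 20 bp primers at each
#' end, mirroring a 16-amplicon exon screen. Coordinates are 1-based
#' half-open `[start, end)`.
#'
#' @param chrom chromosome label.
#' @return data.frame with columns `chrom`, `start`, `end`,
#'   `fwd_primer_len`, `rev_primer_len`.
#' @export
default_amplicons <- function(chrom = "chr1") {
  starts <- 1001L + 400L * (0:15)
  data.frame(
    chrom = chrom, start = starts, end = starts + 220L,
    fwd_primer_len = 20L, rev_primer_len = 20L,
    stringsAsFactors = FALSE
  )
}

#' Construct and validate a pool design
#'
#' A pool design fully specifies one simulated pool: the number of
#' diploid individuals, the amplicon panel, the expected per-strand read
#' depth, the per-substitution-type error rates, the planted variants
#' (position, ref, alt, copies `k` among the `2N` pool alleles) and the
#' reference base at every amplicon position.
#'
#' @param n_individuals diploid individuals in the pool.
#' @param amplicons data.frame as returned by [default_amplicons()];
#'   1-based half-open intervals with primer lengths.
#' @param mean_depth_per_strand expected reads per position per strand.
#' @param error_rates named vector over the 12 substitution types; all
#'   values must lie in `[0, 0.05]`.
#' @param variants data.frame with columns `pos`, `ref`, `alt`, `k`
#'   (copies among `2 * n_individuals` alleles), or NULL for none.
#' @param reference named character vector position -> base; positions
#'   not covered are drawn uniformly from A/C/G/T when simulating.
#' @param seed integer RNG seed.
#' @return object of class `pool_design`.
#' @export
pool_design <- function(n_individuals,
                        amplicons = default_amplicons(),
                        mean_depth_per_strand = 30000,
                        error_rates = default_error_rates(),
                        variants = NULL,
                        reference = NULL,
                        seed = 1L) {
  stopifnot(n_individuals >= 1, mean_depth_per_strand > 0)
  need <- paste0(SUBST_TYPES$ref, ">", SUBST_TYPES$alt)
  if (!all(need %in% names(error_rates)))
    stop_ps("error_rates must name all 12 substitution types; missing: %s",
            paste(setdiff(need, names(error_rates)), collapse = ", "))
  if (any(error_rates < 0 | error_rates > 0.05))
    stop_ps("all error rates must lie in [0, 0.05]")
  if (any(amplicons$start >= amplicons$end))
    stop_ps("amplicon start must be < end")
  if (any(amplicons$fwd_primer_len < 0 | amplicons$rev_primer_len < 0) ||
      any(amplicons$fwd_primer_len + amplicons$rev_primer_len >=
          amplicons$end - amplicons$start))
    stop_ps("primer lengths must be >= 0 and sum to less than the amplicon length")
  if (!is.null(variants) && nrow(variants)) {
    if (any(variants$ref == variants$alt))
      stop_ps("variant with ref == alt rejected")
    if (any(variants$k < 0 | variants$k > 2 * n_individuals))
      stop_ps("variant allele count k must satisfy 0 <= k <= 2N")
    inside <- vapply(variants$pos, function(p) {
      any(p >= amplicons$start + amplicons$fwd_primer_len &
          p <  amplicons$end - amplicons$rev_primer_len)
    }, logical(1))
    if (!all(inside))
      stop_ps("variant positions must lie inside non-primer amplicon regions: %s",
              paste(variants$pos[!inside], collapse = ", "))
    if (anyDuplicated(variants$pos))
      stop_ps("at most one variant per position is supported")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    amplicons = amplicons,
    mean_depth_per_strand = mean_depth_per_strand,
    error_rates = error_rates[need],
    variants = variants,
    reference = reference,
    seed = as.integer(seed)
  ), class = "pool_design")
}

#' Read a pool design from a YAML config file
#'
#' Keys mirror the [pool_design()] arguments; `amplicons` and `variants`
#' are lists of records, `error_rates` a map like `"G>A": 0.0035`,
#' `reference` an optional map position -> base.
#'
#' @param path YAML file path.
#' @return a `pool_design`.
#' @export
read_pool_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  amp <- if (!is.null(cfg$amplicons)) {
    do.call(rbind, lapply(cfg$amplicons, function(a)
      data.frame(chrom = a$chrom %||% "chr1", start = a$start, end = a$end,
                 fwd_primer_len = a$fwd_primer_len %||% 0L,
                 rev_primer_len = a$rev_primer_len %||% 0L,
                 stringsAsFactors = FALSE)))
  } else default_amplicons()
  var <- if (!is.null(cfg$variants)) {
    do.call(rbind, lapply(cfg$variants, function(v)
      data.frame(pos = v$pos, ref = v$ref, alt = v$alt, k = v$k,
                 stringsAsFactors = FALSE)))
  } else NULL
  er <- if (!is.null(cfg$error_rates)) unlist(cfg$error_rates) else
    default_error_rates()
  refm <- if (!is.null(cfg$reference)) {
    r <- unlist(cfg$reference)
    names(r) <- names(cfg$reference)
    r
  } else NULL
  pool_design(
    n_individuals = cfg$n_individuals,
    amplicons = amp,
    mean_depth_per_strand = cfg$mean_depth_per_strand %||% 30000,
    error_rates = er,
    variants = var,
    reference = refm,
    seed = cfg$seed %||% 1L
  )
}

#' Simulate a pooled-sequencing pileup with known truth
#'
#' For every amplicon position and each strand independently, the read
#' depth is Poisson with the design mean (overlapping amplicons
#' contribute additively and produce a single summed pileup line). At a
#' variant position the alternate-allele reads are
#' `Binomial(depth, k / (2N))`; for every other alternate base the error
#' reads are binomial at that substitution type's rate, drawn
#' sequentially from the reads not yet assigned so that per-line counts
#' always sum to the printed depth. Forward-strand reads print as
#' uppercase (`.` for a reference match), reverse-strand as lowercase
#' (`,`). The same seed yields byte-identical output.
#'
#' @param design a [pool_design()].
#' @return list with `pileup` (character vector, one samtools-style
#'   pileup line per position: chrom, 1-based pos, ref, depth, bases) and
#'   `truth` (data.frame: `chrom`, `pos`, `ref`, `alt`, `k`, `p` with
#'   `p = k / (2N)`).
#' @export
simulate_pileup <- function(design) {
  stopifnot(inherits(design, "pool_design"))
  amp <- design$amplicons
  set.seed(design$seed)

  # per-position amplicon multiplicity (overlaps sum)
  pos_list <- lapply(seq_len(nrow(amp)), function(i) amp$start[i]:(amp$end[i] - 1L))
  all_pos <- sort(unique(unlist(pos_list)))
  mult <- tabulate(match(unlist(pos_list), all_pos), nbins = length(all_pos))
  chrom <- amp$chrom[1L]
  n <- length(all_pos)

  ref <- character(n)
  if (!is.null(design$reference)) {
    hit <- as.character(all_pos) %in% names(design$reference)
    ref[hit] <- design$reference[as.character(all_pos[hit])]
    ref[!hit] <- sample(BASES, sum(!hit), replace = TRUE)
  } else {
    ref <- sample(BASES, n, replace = TRUE)
  }
  # a planted variant's ref base overrides the random reference
  v <- design$variants
  if (!is.null(v) && nrow(v)) {
    idx <- match(v$pos, all_pos)
    if (anyNA(idx)) stop_ps("variant position outside amplicons")
    ref[idx] <- v$ref
  }

  p_true <- numeric(n)
  alt_of <- rep(NA_character_, n)
  if (!is.null(v) && nrow(v)) {
    idx <- match(v$pos, all_pos)
    p_true[idx] <- v$k / (2 * design$n_individuals)
    alt_of[idx] <- v$alt
  }

  sim_strand <- function() {
    d <- stats::rpois(n, mult * design$mean_depth_per_strand)
    counts <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, BASES))
    true_alt <- integer(n)
    has_v <- !is.na(alt_of)
    true_alt[has_v] <- stats::rbinom(sum(has_v), d[has_v], p_true[has_v])
    remaining <- d - true_alt
    # sequential error draws in fixed A,C,G,T order guarantee conservation
    for (b in BASES) {
      elig <- ref != b
      lam <- design$error_rates[subst_label(ref, b)]
      err <- integer(n)
      err[elig] <- stats::rbinom(sum(elig), remaining[elig], lam[elig])
      remaining <- remaining - err
      counts[, b] <- counts[, b] + err
    }
    for (b in BASES) {
      ib <- has_v & alt_of == b
      counts[ib, b] <- counts[ib, b] + true_alt[ib]
    }
    ridx <- match(ref, BASES)
    counts[cbind(seq_len(n), ridx)] <- counts[cbind(seq_len(n), ridx)] + remaining
    list(depth = d, counts = counts, ref_reads = remaining)
  }
  fwd <- sim_strand()
  rev <- sim_strand()

  bases_str <- vapply(seq_len(n), function(i) {
    r <- ref[i]
    f <- fwd$counts[i, ]; f[r] <- 0L
    rv <- rev$counts[i, ]; rv[r] <- 0L
    paste0(
      strrep(".", fwd$ref_reads[i]),
      paste0(strrep(BASES, f), collapse = ""),
      strrep(",", rev$ref_reads[i]),
      paste0(strrep(tolower(BASES), rv), collapse = "")
    )
  }, character(1))

  pileup <- sprintf("%s\t%d\t%s\t%d\t%s",
                    chrom, all_pos, ref, fwd$depth + rev$depth, bases_str)

  truth <- if (!is.null(v) && nrow(v)) {
    data.frame(chrom = chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               k = v$k, p = v$k / (2 * design$n_individuals),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), k = integer(), p = numeric(),
               stringsAsFactors = FALSE)
  }
  list(pileup = pileup, truth = truth)
}

#' Write simulator output to disk
#'
#' @param sim result of [simulate_pileup()].
#' @param pileup_path,truth_path output file paths (pileup text, truth TSV).
#' @return invisibly, the two paths.
#' @export
write_simulation <- function(sim, pileup_path, truth_path) {
  writeLines(sim$pileup, pileup_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pileup_path, truth_path))
}
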
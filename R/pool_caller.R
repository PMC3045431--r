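# Empirical-error-threshold variant calling for pooled sequencing.
#
# The caller treats the two strands separately: per-strand substitution
# frequencies are pooled into one empirical distribution per ref->alt
# substitution type, the 97.5th percentile of that distribution becomes
# the calling threshold, and a variant is called only when BOTH strands
# exceed the threshold. This dual-strand rule suppresses the strand-
# biased artifacts that dominate pooled amplicon data.

#' Per-position substitution frequencies
#'
#' Expands parsed pileup columns into one record per (position,
#' alternate base): forward, reverse and combined alternate-allele
#' frequencies. Zero-frequency records are retained — they are the bulk
#' of the empirical error distribution. Positions with reference N or a
#' zero depth on either strand are skipped (with a message).
#'
#' @param columns data.frame from [parse_pileup()] (after
#'   [mask_primers()]).
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `count_fwd`,
#'   `count_rev`, `depth_fwd`, `depth_rev`, `depth_total`, `f_fwd`,
#'   `f_rev`, `f_combined`.
#' @export
substitution_frequencies <- function(columns) {
  skip <- columns$ref == "N" | columns$depth_fwd == 0L | columns$depth_rev == 0L
  if (any(skip))
    message(sum(skip), " position(s) skipped (reference N or zero strand depth)")
  cols <- columns[!skip, , drop = FALSE]
  if (!nrow(cols))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  recs <- lapply(BASES, function(b) {
    keep <- cols$ref != b
    d <- cols[keep, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(chrom = d$chrom, pos = d$pos, ref = d$ref, alt = b,
               count_fwd = d[[paste0(b, "_fwd")]],
               count_rev = d[[paste0(b, "_rev")]],
               depth_fwd = d$depth_fwd, depth_rev = d$depth_rev,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out$depth_total <- out$depth_fwd + out$depth_rev
  out$f_fwd <- out$count_fwd / out$depth_fwd
  out$f_rev <- out$count_rev / out$depth_rev
  out$f_combined <- (out$count_fwd + out$count_rev) / out$depth_total
  out
}

#' Empirical per-substitution-type error thresholds
#'
#' For each of the 12 ref->alt substitution types, pools the observed
#' per-strand frequencies (both strands enter one distribution by
#' default) across all positions whose reference matches, and returns
#' the empirical q-quantile as the calling threshold. With
#' `two_pass = TRUE`, positions whose combined frequency exceeds a
#' first-pass threshold are dropped and the quantile recomputed, so
#' candidate variants do not inflate their own cutoff.
#'
#' @param freqs data.frame from [substitution_frequencies()].
#' @param q percentile, default 0.975.
#' @param mode `"pooled"` (both strands in one distribution, the
#'   default) or `"per_strand"` (separate forward/reverse thresholds).
#' @param method quantile definition: `"linear"` interpolation between
#'   order statistics (stats::quantile type 7, the default) or
#'   `"nearest"` rank (type 1).
#' @param min_obs fewer observations than this flags the threshold as
#'   unreliable (default 40).
#' @param two_pass exclude first-pass exceedances before the final
#'   quantile (default FALSE: single-pass histogram).
#' @return data.frame: `ref`, `alt`, `type`, `threshold_fwd`,
#'   `threshold_rev`, `threshold` (their max, used for reporting),
#'   `n_obs`, `reliable`.
#' @export
error_thresholds <- function(freqs, q = 0.975,
                             mode = c("pooled", "per_strand"),
                             method = c("linear", "nearest"),
                             min_obs = 40L, two_pass = FALSE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  qtype <- if (method == "linear") 7L else 1L
  stopifnot(q > 0.5, q < 1)
  res <- SUBST_TYPES
  res$type <- subst_label(res$ref, res$alt)
  res$threshold_fwd <- res$threshold_rev <- res$threshold <- NA_real_
  res$n_obs <- 0L
  one <- function(v) stats::quantile(v, q, type = qtype, names = FALSE)
  for (i in seq_len(nrow(res))) {
    sel <- freqs$ref == res$ref[i] & freqs$alt == res$alt[i]
    d <- freqs[sel, , drop = FALSE]
    if (!nrow(d))
      stop_ps("no observations for substitution type %s", res$type[i])
    if (two_pass) {
      t0 <- if (mode == "pooled") one(c(d$f_fwd, d$f_rev)) else
        max(one(d$f_fwd), one(d$f_rev))
      keep <- d$f_combined <= t0
      if (sum(keep) >= 2L) d <- d[keep, , drop = FALSE]
    }
    if (mode == "pooled") {
      t <- one(c(d$f_fwd, d$f_rev))
      res$threshold_fwd[i] <- res$threshold_rev[i] <- t
      res$n_obs[i] <- 2L * nrow(d)
    } else {
      res$threshold_fwd[i] <- one(d$f_fwd)
      res$threshold_rev[i] <- one(d$f_rev)
      res$n_obs[i] <- nrow(d)
    }
    res$threshold[i] <- max(res$threshold_fwd[i], res$threshold_rev[i])
  }
  res$reliable <- res$n_obs >= min_obs
  if (any(!res$reliable))
    message("threshold(s) flagged unreliable (< ", min_obs, " observations): ",
            paste(res$type[!res$reliable], collapse = ", "))
  rownames(res) <- NULL
  res
}

#' Forward/reverse strand-balance ratio score
#'
#' `|f_fwd - f_rev| / mean(f_fwd, f_rev)`, in `[0, 2]`. Zero means
#' perfectly strand-balanced; 2 means the substitution appears on one
#' strand only — the signature of a sequencing/PCR artifact. NA when
#' both frequencies are zero.
#'
#' @param f_fwd,f_rev per-strand alternate-allele frequencies.
#' @return numeric score vector.
#' @export
fr_ratio_score <- function(f_fwd, f_rev) {
  s <- abs(f_fwd - f_rev) / ((f_fwd + f_rev) / 2)
  s[f_fwd + f_rev == 0] <- NA_real_
  s
}

#' Estimate the pool minor-allele count
#'
#' Converts a combined pool frequency into copies among the `2N` pool
#' alleles: `round(f * 2N)`, ties away from zero.
#'
#' @param f_combined combined alternate-allele frequency in `[0, 1]`.
#' @param n_individuals diploid individuals in the pool.
#' @return estimated allele count (integer-valued).
#' @export
estimate_allele_count <- function(f_combined, n_individuals) {
  stopifnot(all(f_combined >= 0 & f_combined <= 1))
  round_half_away(f_combined * 2 * n_individuals)
}

#' Minimum detectable variant allele count under a threshold
#'
#' The smallest integer count `k` whose pool frequency `k / (2N)`
#' strictly exceeds the calling threshold.
#'
#' @param t calling threshold in `[0, 1)`.
#' @param n_individuals diploid individuals in the pool.
#' @return smallest detectable `k`.
#' @export
min_detectable_count <- function(t, n_individuals) {
  stopifnot(all(t >= 0 & t < 1))
  floor(t * 2 * n_individuals) + 1
}

#' Call variants with the dual-strand threshold rule
#'
#' A substitution is called only when its forward AND reverse
#' frequencies strictly exceed the empirical threshold for its
#' substitution type and both strands reach the minimum depth. All
#' candidate records are returned, called or not, so near-threshold
#' substitutions remain inspectable.
#'
#' @param freqs data.frame from [substitution_frequencies()].
#' @param thresholds data.frame from [error_thresholds()] computed on
#'   the same pool.
#' @param n_individuals diploid individuals in the pool (for the allele
#'   count estimate); NULL skips the estimate.
#' @param min_depth minimum reads per strand for a position to enter
#'   calling (default 50; guards against unstable frequencies at
#'   amplicon edges).
#' @return `freqs` augmented with `fr_score`, `threshold_fwd`,
#'   `threshold_rev`, `called`, `depth_ok` and (when `n_individuals`
#'   is given) `k_hat`.
#' @export
call_variants <- function(freqs, thresholds, n_individuals = NULL,
                          min_depth = 50L) {
  key <- subst_label(freqs$ref, freqs$alt)
  idx <- match(key, thresholds$type)
  if (anyNA(idx))
    stop_ps("thresholds missing for substitution type(s): %s",
            paste(unique(key[is.na(idx)]), collapse = ", "))
  out <- freqs
  out$fr_score <- fr_ratio_score(out$f_fwd, out$f_rev)
  out$threshold_fwd <- thresholds$threshold_fwd[idx]
  out$threshold_rev <- thresholds$threshold_rev[idx]
  out$depth_ok <- out$depth_fwd >= min_depth & out$depth_rev >= min_depth
  out$called <- out$depth_ok &
    out$f_fwd > out$threshold_fwd & out$f_rev > out$threshold_rev
  if (!is.null(n_individuals))
    out$k_hat <- estimate_allele_count(out$f_combined, n_individuals)
  out
}
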
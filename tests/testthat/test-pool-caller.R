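# independent quantile oracle: direct linear interpolation between
# sorted order statistics at h = (n-1)q + 1
oracle_quantile <- function(x, q) {
  s <- sort(x)
  h <- (length(s) - 1) * q + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

col_row <- function(ref = "G", counts_fwd = c(A = 0L, C = 0L, G = 0L, T = 0L),
                    counts_rev = c(A = 0L, C = 0L, G = 0L, T = 0L),
                    pos = 50L) {
  df <- data.frame(chrom = "chr1", pos = pos, ref = ref,
                   depth = sum(counts_fwd) + sum(counts_rev),
                   stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T")) {
    df[[paste0(b, "_fwd")]] <- counts_fwd[[b]]
    df[[paste0(b, "_rev")]] <- counts_rev[[b]]
  }
  df$depth_fwd <- sum(counts_fwd)
  df$depth_rev <- sum(counts_rev)
  df
}

test_that("substitution frequencies are per-strand count ratios", {
  cols <- col_row(ref = "G", counts_fwd = c(A = 1L, C = 0L, G = 99L, T = 0L),
                  counts_rev = c(A = 0L, C = 0L, G = 100L, T = 0L))
  fr <- substitution_frequencies(cols)
  expect_identical(nrow(fr), 3L)          # one record per alt base
  ga <- fr[fr$alt == "A", ]
  expect_equal(ga$f_fwd, 0.01)
  expect_equal(ga$f_rev, 0)
  expect_equal(ga$f_combined, 0.005)
  # zero-frequency records retained
  expect_equal(fr$f_combined[fr$alt %in% c("C", "T")], c(0, 0))
  # combined frequency always between the strand frequencies
  expect_true(all(fr$f_combined >= pmin(fr$f_fwd, fr$f_rev) &
                  fr$f_combined <= pmax(fr$f_fwd, fr$f_rev)))
})

test_that("N-reference and zero-depth positions are skipped", {
  cols <- rbind(col_row(ref = "N", pos = 1L,
                        counts_fwd = c(A = 5L, C = 0L, G = 0L, T = 0L),
                        counts_rev = c(A = 5L, C = 0L, G = 0L, T = 0L)),
                col_row(ref = "A", pos = 2L,
                        counts_fwd = c(A = 5L, C = 0L, G = 0L, T = 0L)),
                col_row(ref = "A", pos = 3L,
                        counts_fwd = c(A = 5L, C = 0L, G = 0L, T = 0L),
                        counts_rev = c(A = 5L, C = 0L, G = 0L, T = 0L)))
  expect_message(fr <- substitution_frequencies(cols), "2 position")
  expect_identical(unique(fr$pos), 3L)
})

test_that("error thresholds equal the empirical quantile of the pooled strand frequencies", {
  # constant distribution: threshold = the constant
  n <- 30L
  fr <- data.frame(chrom = "chr1", pos = rep(1:n, each = 3),
                   ref = "A", alt = rep(c("C", "G", "T"), n),
                   f_fwd = 0.003, f_rev = 0.003, f_combined = 0.003,
                   depth_fwd = 1000L, depth_rev = 1000L, depth_total = 2000L,
                   stringsAsFactors = FALSE)
  # give the other ref bases something to summarize too
  other <- do.call(rbind, lapply(c("C", "G", "T"), function(r) {
    d <- fr[fr$ref == "A", ]
    d$ref <- r
    d$alt <- rep(setdiff(c("A", "C", "G", "T"), r), n)
    d
  }))
  thr <- suppressMessages(error_thresholds(rbind(fr, other)))
  expect_true(all(abs(thr$threshold - 0.003) < 1e-12))

  # uniform grid: agrees with the independent interpolation oracle
  grid <- seq(0, 0.01, by = 0.001)
  fr2 <- rbind(fr, other)
  fr2$f_fwd <- rep_len(grid, nrow(fr2))
  fr2$f_rev <- rep_len(rev(grid), nrow(fr2))
  thr2 <- suppressMessages(error_thresholds(fr2))
  for (i in seq_len(nrow(thr2))) {
    sel <- fr2$ref == thr2$ref[i] & fr2$alt == thr2$alt[i]
    expect_equal(thr2$threshold[i],
                 oracle_quantile(c(fr2$f_fwd[sel], fr2$f_rev[sel]), 0.975))
  }

  # nearest-rank method matches a sorted-vector lookup
  thr3 <- suppressMessages(error_thresholds(fr2, method = "nearest"))
  sel <- fr2$ref == "A" & fr2$alt == "C"
  v <- sort(c(fr2$f_fwd[sel], fr2$f_rev[sel]))
  expect_equal(thr3$threshold[thr3$type == "A>C"],
               v[ceiling(0.975 * length(v))])
})

test_that("a noisier substitution type earns a higher threshold", {
  er <- flat_error_rates(0.001)
  er["A>C"] <- 0.008
  er["G>A"] <- 0.002
  hits <- vapply(1:20, function(s) {
    d <- error_only_design(n_pos = 600L, depth = 200, seed = s,
                           error_rates = er)
    out <- run_pool(d)
    t <- out$thr
    t$threshold[t$type == "A>C"] > t$threshold[t$type == "G>A"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("missing substitution observations raise errors", {
  fr <- data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "C",
                   f_fwd = 0, f_rev = 0, f_combined = 0,
                   depth_fwd = 100L, depth_rev = 100L, depth_total = 200L,
                   stringsAsFactors = FALSE)
  expect_error(suppressMessages(error_thresholds(fr)),
               "no observations for substitution type")
})

test_that("dual-strand rule calls only strand-concordant exceedances", {
  thr <- data.frame(ref = "G", alt = "A", type = "G>A",
                    threshold_fwd = 0.01, threshold_rev = 0.01,
                    threshold = 0.01, n_obs = 100L, reliable = TRUE,
                    stringsAsFactors = FALSE)
  mk <- function(ff, fr) data.frame(
    chrom = "chr1", pos = 1L, ref = "G", alt = "A",
    count_fwd = 0L, count_rev = 0L, depth_fwd = 1000L, depth_rev = 1000L,
    depth_total = 2000L, f_fwd = ff, f_rev = fr,
    f_combined = (ff + fr) / 2, stringsAsFactors = FALSE)

  expect_true(call_variants(mk(0.02, 0.02), thr)$called)
  # one-strand artifact is never called, however extreme
  expect_false(call_variants(mk(0.05, 0.0), thr)$called)
  # boundary is strict
  expect_false(call_variants(mk(0.01, 0.02), thr)$called)
  # low-depth positions are excluded from calling
  low <- mk(0.02, 0.02)
  low$depth_fwd <- 40L
  expect_false(call_variants(low, thr, min_depth = 50L)$called)
  expect_true(call_variants(low, thr, min_depth = 10L)$called)
})

test_that("strand-balance ratio score follows its definition", {
  expect_equal(fr_ratio_score(0.01, 0.01), 0)
  expect_equal(fr_ratio_score(0.02, 0), 2)
  expect_equal(fr_ratio_score(0.03, 0.01), 1.0)
  expect_true(is.na(fr_ratio_score(0, 0)))
  s <- fr_ratio_score(runif(50, 0, 0.1), runif(50, 0, 0.1))
  expect_true(all(s >= 0 & s <= 2))
})

test_that("allele-count estimation rounds half away from zero", {
  expect_equal(estimate_allele_count(0.012, 311), 7)   # 7.464
  expect_equal(estimate_allele_count(0, 311), 0)
  expect_equal(estimate_allele_count(1, 311), 622)
  expect_equal(round_half_away(7.5), 8)    # tie away from zero
  expect_equal(round_half_away(-7.5), -8)
})

test_that("minimum detectable count matches exhaustive search", {
  brute <- function(t, n) {
    for (k in 1:(2 * n)) if (k / (2 * n) > t) return(k)
  }
  for (t in c(0, 0.004, 0.010, 0.0032, 0.0112)) {
    expect_equal(min_detectable_count(t, 311), brute(t, 311),
                 info = paste("t =", t))
  }
  expect_equal(min_detectable_count(0.004, 311), 3)
  expect_equal(min_detectable_count(0.010, 311), 7)
  expect_equal(min_detectable_count(0, 311), 1)
})

test_that("planted variants at callable counts are recovered", {
  # sensitivity: k >= k_min at 100+ reads/strand is called in >= 90% of seeds
  er <- flat_error_rates(0.001)
  hits <- vapply(1:30, function(s) {
    d <- pool_design(311, tiling_amplicons(200L),
                     mean_depth_per_strand = 150, error_rates = er,
                     variants = data.frame(pos = 1050L, ref = "G", alt = "A",
                                           k = 25L),
                     seed = s)
    out <- run_pool(d)
    v <- out$calls[out$calls$pos == 1050L & out$calls$alt == "A", ]
    kmin <- min_detectable_count(
      out$thr$threshold[out$thr$type == "G>A"], 311)
    kmin <= 25L && v$called
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("two-pass thresholds are not inflated by the variants themselves", {
  er <- flat_error_rates(0.001)
  d <- pool_design(311, tiling_amplicons(200L), mean_depth_per_strand = 500,
                   error_rates = er,
                   variants = data.frame(pos = 1050L, ref = "G", alt = "A",
                                         k = 60L),
                   seed = 4)
  sim <- simulate_pileup(d)
  fr <- substitution_frequencies(mask_primers(parse_pileup(sim$pileup),
                                              d$amplicons))
  t1 <- suppressMessages(error_thresholds(fr, two_pass = FALSE))
  t2 <- suppressMessages(error_thresholds(fr, two_pass = TRUE))
  expect_lte(t2$threshold[t2$type == "G>A"], t1$threshold[t1$type == "G>A"])
})
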
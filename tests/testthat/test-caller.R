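# Normalization, threshold derivation and segment calling

profile_from_ratios <- function(ratios, chrom = "chr1") {
  n <- length(ratios)
  data.frame(probe_id = sprintf("p%d", 1:n), chrom = chrom,
             start = seq(0L, by = 10L, length.out = n),
             end = seq(0L, by = 10L, length.out = n) + 50L,
             log2_ratio = ratios, stringsAsFactors = FALSE)
}

test_that("normalization removes shifts exactly and is idempotent", {
  prof <- profile_from_ratios(rnorm(101, 0, 0.2) + 0.3)
  norm <- normalize_profile(prof)
  expect_equal(median(norm$log2_ratio), 0)
  again <- normalize_profile(norm)
  expect_equal(again$log2_ratio, norm$log2_ratio)
})

test_that("robust SD estimate recovers the simulated null SD", {
  probes <- make_probe_grid(from = 0L, to = 2L * 20000L - 2L, stagger = 2L)
  prof <- simulate_profile(probes, NULL, noise_model(null_sd = 0.2, seed = 12L))
  norm <- normalize_profile(prof)
  expect_equal(attr(norm, "sd_estimate"), 0.2, tolerance = 0.01)
})

test_that("degenerate all-identical profiles are flagged", {
  expect_warning(norm <- normalize_profile(profile_from_ratios(rep(1, 10))),
                 "fixed_threshold")
  expect_true(attr(norm, "sd_zero"))
  expect_error(call_segments(norm), "fixed_threshold")
})

test_that("threshold derivation is multiplier times SD", {
  expect_identical(derive_threshold(0.2, 2), 0.4)
  expect_equal(derive_threshold(0.3, 2), 0.6)
  thr0 <- derive_threshold(0, 2)
  expect_equal(as.numeric(thr0), 0)
  expect_true(attr(thr0, "degenerate"))
})

test_that("the k-consecutive rule is enforced at the run level", {
  ratios <- c(0, -1, -1, 0, 0, -1, -1, -1, 0)
  prof <- profile_from_ratios(ratios)
  k3 <- call_segments(prof, caller_config(fixed_threshold = 0.4, k_consecutive = 3))
  expect_equal(nrow(k3), 1L)
  expect_equal(k3$n_probes, 3L)
  k2 <- call_segments(prof, caller_config(fixed_threshold = 0.4, k_consecutive = 2))
  expect_equal(nrow(k2), 2L)
  # alternating flagged/unflagged with max_gap 0 never reaches k = 3
  alt <- profile_from_ratios(rep(c(-1, 0), 10))
  expect_equal(nrow(call_segments(alt, caller_config(fixed_threshold = 0.4))), 0L)
  # but a gap tolerance of 1 merges the alternation into one segment
  gap1 <- call_segments(alt, caller_config(fixed_threshold = 0.4, max_gap = 1))
  expect_equal(nrow(gap1), 1L)
  expect_equal(gap1$n_probes, 10L)
})

test_that("segments span first to last flagged probe and split at chromosomes", {
  ratios <- c(0, -1, -1, -1, 0)
  prof <- profile_from_ratios(ratios)
  seg <- call_segments(prof, caller_config(fixed_threshold = 0.4))
  expect_equal(seg$start, prof$start[2])
  expect_equal(seg$end, prof$end[4])
  two_chrom <- rbind(profile_from_ratios(c(-1, -1), "chr1"),
                     profile_from_ratios(c(-1, -1), "chr2"))
  expect_equal(nrow(call_segments(two_chrom,
                                  caller_config(fixed_threshold = 0.4,
                                                k_consecutive = 3))), 0L)
})

test_that("duplication segments are called on the positive side", {
  prof <- profile_from_ratios(c(0, 2, 2, 2, 0, -1, -1, -1, 0))
  segs <- call_segments(prof, caller_config(fixed_threshold = 0.4))
  expect_setequal(segs$kind, c("deletion", "duplication"))
  expect_true(all(segs$n_probes == 3L))
})

test_that("unsorted probes are rejected", {
  prof <- profile_from_ratios(c(-1, -1, -1, 0))
  prof <- prof[c(2, 1, 3, 4), ]
  expect_error(call_segments(prof, caller_config(fixed_threshold = 0.4)),
               "sorted")
})

test_that("calls depend only on coordinates and ratios, not probe ids", {
  set.seed(31)
  prof <- profile_from_ratios(rnorm(200, 0, 0.5))
  a <- call_segments(prof, caller_config(fixed_threshold = 0.4))
  prof2 <- prof
  prof2$probe_id <- sprintf("zz_%03d", seq_len(nrow(prof)))
  b <- call_segments(prof2, caller_config(fixed_threshold = 0.4))
  expect_equal(a[c("chrom", "start", "end", "kind", "n_probes", "mean_ratio")],
               b[c("chrom", "start", "end", "kind", "n_probes", "mean_ratio")])
})

test_that("raising the threshold never increases flagged probes or calls", {
  set.seed(32)
  prof <- profile_from_ratios(rnorm(2000, 0, 0.3))
  counts <- sapply(c(0.2, 0.4, 0.6, 0.8), function(thr) {
    segs <- call_segments(prof, caller_config(fixed_threshold = thr,
                                              k_consecutive = 1))
    sum(segs$n_probes)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("segment calls equal the brute-force run scan and shrink with k", {
  set.seed(33)
  n_by_k <- integer(4)
  for (rep in 1:250) {
    prof <- profile_from_ratios(rnorm(sample(20:60, 1), 0, 0.45))
    for (k in 1:4) {
      got <- call_segments(prof, caller_config(fixed_threshold = 0.4,
                                               k_consecutive = k))
      want <- brute_force_segments(prof, 0.4, k)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got[c("start", "end", "kind", "n_probes", "mean_ratio")],
                     want[c("start", "end", "kind", "n_probes", "mean_ratio")])
      }
      if (k <= 4) n_by_k[k] <- n_by_k[k] + nrow(got)
    }
  }
  expect_true(all(diff(n_by_k) <= 0))
})

test_that("feature-fraction rule is inclusive at the 50% boundary", {
  ratios <- c(rep(-1, 4), rep(0, 4))
  prof <- profile_from_ratios(ratios)
  feats <- data.frame(feature_id = "g1", chrom = "chr1", start = 0L,
                      end = max(prof$end), stringsAsFactors = FALSE)
  expect_true(feature_fraction_calls(prof, feats)$called)    # 4/8 = 50%
  prof$log2_ratio[4] <- 0                                    # 3/8
  expect_false(feature_fraction_calls(prof, feats)$called)
  off <- data.frame(feature_id = "g2", chrom = "chr9", start = 0L, end = 100L)
  expect_warning(res <- feature_fraction_calls(prof, off), "no probes")
  expect_true(is.na(res$called))
})

test_that("feature call probability matches the binomial tail", {
  # 8 probes over a deleted gene, sensitivity 0.5: per-probe
  # P(ratio <= -0.8) = 0.5 Phi((-0.8+2)/0.5) + 0.5 Phi(-0.8/0.2)
  m <- noise_model(sensitivity = 0.5, seed = NULL)
  probes <- make_probe_grid(from = 2000L, to = 2070L, stagger = 10L)
  del <- data.frame(chrom = "chr1", start = 1990L, end = 2130L,
                    kind = "deletion", label = "g", stringsAsFactors = FALSE)
  feats <- data.frame(feature_id = "g", chrom = "chr1", start = 1990L,
                      end = 2130L, stringsAsFactors = FALSE)
  set.seed(44)
  calls <- replicate(1500, {
    prof <- simulate_profile(probes, del, m, seed = NULL)
    feature_fraction_calls(prof, feats)$called
  })
  q <- 0.5 * pnorm((-0.8 + 2) / 0.5) + 0.5 * pnorm(-0.8 / 0.2)
  p_want <- 1 - pbinom(3, 8, q) # >= 4 of 8
  expect_lt(abs(mean(calls) - p_want),
            4 * sqrt(p_want * (1 - p_want) / 1500))
})
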
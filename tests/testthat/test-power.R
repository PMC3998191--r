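# Designed-vs-detected accounting and detection power

del104 <- list(chrom = "chr1", start = 5000L, end = 5104L)
cfg04 <- caller_config(fixed_threshold = 0.4)

# pooled fixed-length probe grids over the deletion region, one per stagger
pooled_grids <- function(staggers, from = 3000L, to = 7000L) {
  p <- do.call(rbind, lapply(staggers, function(s) {
    make_probe_grid(from = from, to = to, stagger = s)
  }))
  p[order(p$start, p$set_id), ]
}

test_that("noise-free simulation detects every designed probe at every stagger", {
  probes <- pooled_grids(design_config()$staggers)
  m <- noise_model(null_sd = 1e-9, del_sd = 0, sensitivity = 1, seed = 51L)
  rep <- designed_vs_detected(simulate_profile(probes, data.frame(
    chrom = "chr1", start = 5000L, end = 5104L, kind = "deletion",
    label = "d104", stringsAsFactors = FALSE), m), del104, cfg04)
  expect_equal(nrow(rep), 19L)
  expect_equal(rep$n_detected, rep$n_designed)
  expect_true(all(rep$percent_detected == 100))
  expect_true(all(rep$called))
  # designed counts obey the start-window bracket
  w <- 104L + 50L - 1L
  expect_true(all(rep$n_designed %in% c(w %/% rep$stagger, w %/% rep$stagger + 1L)))
})

test_that("a deterministic 8-of-9 profile reproduces the 17 bp worked example", {
  # 9 probes staggered 17 bp across the 104 bp deletion; one fails to respond
  probes <- make_probe_grid(from = 5000L - 49L + 15L, to = 5103L, stagger = 17L)
  expect_equal(nrow(probes), 9L)
  probes$log2_ratio <- rep(-2, 9L)
  probes$log2_ratio[1L] <- -0.10506
  rep <- designed_vs_detected(probes, del104, cfg04)
  expect_equal(rep$n_designed, 9L)
  expect_equal(rep$n_detected, 8L)
  expect_equal(rep$percent_detected, 100 * 8 / 9, tolerance = 1e-12) # 88.9%
  expect_true(rep$called)
})

test_that("percent-detected summary is the unweighted mean", {
  reports <- data.frame(set_id = c("a", "b"), stagger = c(2L, 49L),
                        n_designed = c(5L, 5L), n_detected = c(4L, 5L),
                        percent_detected = c(80, 100), called = TRUE)
  expect_equal(percent_detected_summary(reports), 90)
  reports$percent_detected <- c(100, 100)
  expect_equal(percent_detected_summary(reports), 100)
})

test_that("a call is impossible when fewer designed probes than k", {
  probes <- make_probe_grid(from = 4951L + 30L, to = 5103L, stagger = 100L)
  probes$log2_ratio <- -3
  rep <- designed_vs_detected(probes, del104,
                              caller_config(fixed_threshold = 0.4,
                                            k_consecutive = 3))
  expect_lt(rep$n_designed, 3L)
  expect_false(rep$called)
})

test_that("mean percent detected converges to 100 x sensitivity", {
  staggers <- design_config()$staggers
  for (sens in c(0.94, 0.99)) {
    m <- noise_model(sensitivity = sens, seed = NULL)
    set.seed(round(100 * sens))
    means <- replicate(60, {
      probes <- pooled_grids(staggers, from = 4600L, to = 5400L)
      prof <- simulate_profile(probes, data.frame(
        chrom = "chr1", start = 5000L, end = 5104L, kind = "deletion",
        label = "d", stringsAsFactors = FALSE), m, seed = NULL)
      percent_detected_summary(designed_vs_detected(prof, del104, cfg04))
    })
    q <- sens * pnorm((-0.4 + 2) / 0.5) + (1 - sens) * pnorm(-0.4 / 0.2)
    expect_equal(mean(means), 100 * q, tolerance = 0.02)
    expect_equal(mean(means), 100 * sens, tolerance = 0.02)
  }
})

test_that("noise-free minimum detectable stagger equals the closed form", {
  m0 <- noise_model(null_sd = 1e-9, del_sd = 0, sensitivity = 1)
  for (cs in list(c(104L, 3L), c(104L, 2L), c(30L, 3L), c(4L, 3L))) {
    d <- cs[1]; k <- cs[2]
    s_star <- max_stagger_guaranteeing_k(d, 50L, k)
    cand <- sort(unique(c(2L, 6L, 17L, s_star - 1L, s_star, s_star + 1L,
                          s_star + 5L)))
    cand <- cand[cand >= 1L]
    res <- min_detectable_stagger(d, m0,
                                  caller_config(fixed_threshold = 0.4,
                                                k_consecutive = k),
                                  staggers = cand, phases = "all",
                                  power_target = 1)
    expect_equal(as.integer(res), s_star)
  }
})

test_that("with k = 1 and noise-free response any covering stagger detects", {
  m0 <- noise_model(null_sd = 1e-9, del_sd = 0, sensitivity = 1)
  res <- min_detectable_stagger(1L, m0,
                                caller_config(fixed_threshold = 0.4,
                                              k_consecutive = 1L),
                                staggers = c(2L, 10L, 25L, 50L),
                                phases = "all")
  expect_equal(as.integer(res), 50L) # largest tested stagger <= d + L - 1
})

test_that("power is non-increasing in stagger and none is reported honestly", {
  m0 <- noise_model(null_sd = 1e-9, del_sd = 0, sensitivity = 1)
  res <- min_detectable_stagger(104L, m0,
                                caller_config(fixed_threshold = 0.4),
                                staggers = sort(c(design_config()$staggers,
                                                  51L, 52L, 60L, 80L)),
                                phases = "all")
  curve <- attr(res, "power_curve")
  expect_true(all(diff(curve$power) <= 1e-12))
  expect_equal(as.integer(res), 51L)
  expect_message(
    none <- min_detectable_stagger(4L, m0,
                                   caller_config(fixed_threshold = 0.4,
                                                 k_consecutive = 3L),
                                   staggers = c(30L, 40L), phases = "all"),
    "no candidate stagger")
  expect_true(is.na(none))
})

test_that("power runs are reproducible given a seed", {
  m <- noise_model(sensitivity = 0.94)
  a <- min_detectable_stagger(28L, m, cfg04, staggers = c(10L, 22L, 32L),
                              n_reps = 50L, seed = 99L)
  b <- min_detectable_stagger(28L, m, cfg04, staggers = c(10L, 22L, 32L),
                              n_reps = 50L, seed = 99L)
  expect_identical(attr(a, "power_curve"), attr(b, "power_curve"))
})

test_that("the published 104 bp table fixture loads with its known shape", {
  t1 <- phyb104_table1()
  expect_equal(names(t1), c("stagger", "designed", "detected", "percent"))
  expect_equal(nrow(t1), 19L)
  expect_true(all(t1$detected <= t1$designed))
})
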
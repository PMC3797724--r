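# CBS, log-ratios, LAF, event flags and focal deletion detection.

test_that("cbs finds exact breakpoints on noiseless steps", {
  expect_equal(cbs_segment(rep(1, 50)), integer(0))
  expect_equal(cbs_segment(c(rep(0, 20), rep(1, 20))), 20L)
  expect_equal(cbs_segment(c(rep(0, 10), rep(1, 10), rep(0, 10))),
               c(10L, 20L))
  # non-finite values are masked; breakpoints map back to original indices
  x <- c(rep(0, 10), NA, rep(0, 9), rep(1, 20))
  expect_equal(cbs_segment(x), 20L)
  expect_equal(cbs_segment(numeric(0)), integer(0))
  expect_equal(cbs_segment(c(1, 2)), integer(0))
})

test_that("cbs output is a strictly increasing partition", {
  set.seed(17)
  for (r in 1:5) {
    x <- c(rnorm(15, 0, 0.2), rnorm(25, 1, 0.2), rnorm(10, -0.5, 0.2))
    bps <- cbs_segment(x)
    expect_true(all(diff(bps) > 0))
    expect_true(all(bps >= 1 & bps < length(x)))
    cuts <- c(0, bps, length(x))
    expect_equal(sum(diff(cuts)), length(x))
  }
})

test_that("self-comparison yields zero ratios, no breakpoints, no flags", {
  set.seed(23)
  cov <- data.table::data.table(
    chrom = "chr1", start = seq(0, 990000, 1e4), end = seq(1e4, 1e6, 1e4),
    coverage = rpois(100, 5000))
  w <- windowed_log_ratio(cov, cov)
  expect_true(all(w$ratio == 0))
  segs <- segment_log_ratios(w)
  expect_equal(nrow(segs), 1)
  h <- data.table::data.table(chrom = "chr1", pos = seq(5000, 995000, 5000))
  h[, `:=`(a_count = 50L, b_count = 50L)]
  segs <- call_loh_and_events(lesser_allele_fraction(h, segs))
  expect_false(any(segs$loh | segs$gain | segs$loss))
})

test_that("log-ratio responds to a doubled window and masks low coverage", {
  cov <- data.table::data.table(
    chrom = "chr1", start = seq(0, 99000, 1000), end = seq(1000, 1e5, 1000),
    coverage = 1000)
  tum <- data.table::copy(cov)
  tum[50, coverage := 2000]
  w <- windowed_log_ratio(tum, cov)
  expect_equal(w$ratio[50], log2(2 / (1 + 1 / 100)), tolerance = 1e-6)
  low <- data.table::copy(cov)[10, coverage := 5]
  w2 <- windowed_log_ratio(tum, low)
  expect_true(is.na(w2$ratio[10]))
  expect_error(windowed_log_ratio(tum, data.table::copy(cov)[, coverage := 0]),
               "zero total")
})

test_that("site and segment LAF follow allele counts", {
  h <- data.table::data.table(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    a_count = c(50L, 30L, 0L, 0L), b_count = c(50L, 10L, 80L, 0L))
  segs <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L)
  out <- lesser_allele_fraction(h, segs)
  expect_equal(out$n_hets, 3L)  # zero-depth site skipped
  expect_equal(out$laf, mean(c(0.5, 0.25, 0)))
  # LAF always in [0, 0.5]
  set.seed(3)
  hr <- data.table::data.table(chrom = "chr1",
                               pos = sample(1000L, 200),
                               a_count = rpois(200, 40),
                               b_count = rpois(200, 10))
  lr <- lesser_allele_fraction(hr[a_count + b_count > 0], segs)
  expect_true(lr$laf >= 0 && lr$laf <= 0.5)
})

test_that("LOH / gain / loss flags are independent", {
  segs <- data.table::data.table(
    chrom = "chr1", start = c(0, 10, 20), end = c(10, 20, 30),
    mean_ratio = c(0, 0.9, -0.6), laf = c(0.02, 0.45, NA))
  out <- call_loh_and_events(segs)
  expect_equal(out$loh, c(TRUE, FALSE, FALSE))   # copy-neutral LOH
  expect_equal(out$gain, c(FALSE, TRUE, FALSE))
  expect_equal(out$loss, c(FALSE, FALSE, TRUE))
})

test_that("focal deletion detection calls planted drops and stays quiet", {
  cfg <- sim_config(seed = 13)
  fd <- cfg$focal_deletion
  # flat region: no call
  flat <- simulate_base_coverage(cfg, "Met2", "chrXs", 4e7, 4e7 + 5e4)
  expect_null(detect_focal_deletion(flat))
  expect_error(
    detect_focal_deletion(flat[pos < 4e7 + 600], coarse_window = 500),
    "shorter than 3")
  # windowed (not base-level) input: breakpoints at window granularity
  set.seed(13)
  win <- data.table::data.table(
    chrom = "chrXs", start = seq(0, 39500, 500), end = seq(500, 40000, 500))
  mid <- win$start >= 12000 & win$start < 28000
  win[, tumor := rpois(.N, ifelse(mid, 1.5e5, 2e5))]
  win[, normal := rpois(.N, 1e5)]
  call <- detect_focal_deletion(win)
  expect_lte(abs(call$start - 12001), 500)
  expect_lte(abs(call$end - 28001), 500)
  expect_gt(call$drop, 0.3)
})
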
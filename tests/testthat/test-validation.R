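# Deep-validation rule and temporal classification.

test_that("validation rule uses strict inequalities", {
  expect_false(validate_site(6, 700))    # 0.86% fails the fraction gate
  expect_false(validate_site(5, 100))    # count must be strictly > 5
  expect_true(validate_site(6, 100))     # 6% and 6 reads pass
  expect_false(validate_site(60, 6000))  # exactly 1% fails (strict >)
  expect_warning(res <- validate_site(0, 0), "zero total")
  expect_false(res)
  # Sanger observations bypass the count rule
  expect_true(validate_site(1, 1, sanger = TRUE))
  expect_false(validate_site(0, 1, sanger = TRUE))
  expect_error(validate_site(10, 5), ">= 0|<=")
})

test_that("raising thresholds never converts absent to present", {
  grid <- data.table::CJ(v = 0:40, t = 1:200)[v <= t]
  base <- validate_site(grid$v, grid$t, min_reads = 5, min_fraction = 0.01)
  for (mr in c(8, 12)) {
    expect_true(all(validate_site(grid$v, grid$t, min_reads = mr) <= base))
  }
  for (mf in c(0.05, 0.2)) {
    expect_true(all(validate_site(grid$v, grid$t, min_fraction = mf) <= base))
  }
})

make_obs <- function(spec) {
  # spec: list(site_chr_pos = character vector of samples it is present in)
  samples <- c("Met2", "Met1", "PT1", "PT2", "PT3", "PT4")
  data.table::rbindlist(lapply(names(spec), function(s) {
    parts <- strsplit(s, "_")[[1]]
    data.table::data.table(
      chrom = parts[1], pos = as.integer(parts[2]), ref = "A", alt = "T",
      sample = samples, present = samples %in% spec[[s]])
  }))
}

test_that("timeline classification partitions the sites", {
  all_s <- c("Met2", "Met1", "PT1", "PT2", "PT3", "PT4")
  obs <- make_obs(list(
    chr1_100 = all_s,                       # shared
    chr1_200 = "Met2",                      # private
    chr1_300 = c("Met2", "Met1", "PT1"),    # partial
    chr1_400 = c("Met1", "PT1", "PT2", "PT3", "PT4")))  # unvalidated
  res <- classify_timeline(obs, "Met2", setdiff(all_s, "Met2"))
  expect_equal(res[pos == 100, label], "shared")
  expect_equal(res[pos == 200, label], "private-to-index")
  expect_equal(res[pos == 300, label], "partial")
  expect_equal(res[pos == 400, label], "unvalidated")
  s <- attr(res, "summary")
  expect_equal(s$n_validated, 3)
  expect_equal(s$n_shared + s$n_private + s$n_partial, s$n_validated)
  expect_equal(nrow(res), 4)

  expect_error(classify_timeline(obs[sample != "PT4"], "Met2",
                                 setdiff(all_s, "Met2")),
               "missing sample")
})

test_that("classification accepts raw counts through the validation rule", {
  obs <- data.table::data.table(
    chrom = "chr1", pos = 1L, ref = "A", alt = "T",
    sample = c("Met2", "Met1"),
    variant_count = c(300L, 3L), total_count = c(1000L, 1000L))
  res <- classify_timeline(obs, "Met2", "Met1")
  expect_equal(res$label, "private-to-index")
})

test_that("validation accuracy is confirmed/candidates", {
  expect_equal(round(validation_accuracy(61, 44), 2), 0.72)
  expect_equal(validation_accuracy(10, 0), 0)
  expect_equal(validation_accuracy(10, 10), 1)
  expect_error(validation_accuracy(0, 0), "> 0")
  expect_error(validation_accuracy(10, 11), "confirmed")
})
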
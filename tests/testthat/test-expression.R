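# RPKM, mutant fraction and expressed-driver classification.

test_that("rpkm is the standard normalization", {
  expect_equal(rpkm(1000, 2000, 1e7), 50)
  expect_equal(rpkm(0, 2000, 1e7), 0)
  expect_equal(rpkm(1000, 2000, 2e7), rpkm(1000, 2000, 1e7) / 2)
  expect_error(rpkm(10, 0, 1e7), "> 0")
})

test_that("mutant fraction applies the site depth floor", {
  expect_equal(mutant_fraction(40, 100), 0.4)
  expect_equal(mutant_fraction(0, 100), 0)
  expect_true(is.na(mutant_fraction(1, 3)))
  expect_equal(mutant_fraction(c(4, 1), c(10, 2)), c(0.4, NA))
})

mk_report <- function(frs, rpkms = 20) {
  data.table::data.table(
    gene = "G", sample = paste0("S", seq_along(frs)),
    rpkm_value = rep_len(rpkms, length(frs)), fraction = frs)
}

test_that("driver classification follows the rule table", {
  req <- c("S1", "S2", "S3")
  expect_equal(classify_driver_candidates(
    mk_report(c(0.45, 0.4, 0.5)), required_samples = req)$class,
    "expressed-driver-candidate")
  expect_equal(classify_driver_candidates(
    mk_report(c(0.10, 0.2, 0.25)), required_samples = req)$class,
    "expressed-low-fraction")
  expect_equal(classify_driver_candidates(
    mk_report(c(0, NA, 0)), required_samples = req)$class,
    "mutant-not-detected")
  expect_equal(classify_driver_candidates(
    mk_report(c(0.5, 0.5, 0.5), rpkms = c(20, 0.5, 20)),
    required_samples = req)$class,
    "gene-not-expressed")
  # boundary: fraction must strictly exceed the threshold
  expect_equal(classify_driver_candidates(
    mk_report(c(0.30, 0.5, 0.5)), required_samples = req)$class,
    "expressed-low-fraction")
  # "any" mode relaxes the quantifier
  expect_equal(classify_driver_candidates(
    mk_report(c(0.1, 0.5, 0.1)), required_samples = req,
    mode = "any")$class,
    "expressed-driver-candidate")
  expect_error(classify_driver_candidates(
    mk_report(c(0.4, 0.4)), required_samples = req), "absent")
})

test_that("raising the fraction threshold never adds candidates", {
  cfg <- sim_config(seed = 19)
  rna <- simulate_rna(cfg)
  tr <- truth_table(cfg)
  shared <- tr$mutations[label == "founder", gene]
  rep <- expression_report(rna$gene_counts[gene %in% shared],
                           rna$site_counts[gene %in% shared])
  cand <- function(fm) {
    cls <- classify_driver_candidates(rep, fraction_min = fm,
                                      required_samples = cfg$rna_samples)
    cls[class == "expressed-driver-candidate", gene]
  }
  c30 <- cand(0.30); c40 <- cand(0.40); c60 <- cand(0.60)
  expect_true(all(c40 %in% c30))
  expect_true(all(c60 %in% c40))
  # partition: every shared gene gets exactly one class
  cls <- classify_driver_candidates(rep, required_samples = cfg$rna_samples)
  expect_setequal(cls$gene, shared)
  expect_false(any(duplicated(cls$gene)))
})

test_that("observed fractions are calibrated against generator truth", {
  cfg <- sim_config(seed = 19)
  rna <- simulate_rna(cfg)
  tr <- truth_table(cfg)
  g <- merge(rna$site_counts[depth >= 20],
             tr$genes[, .(gene, mutant_fraction)], by = "gene")
  g <- g[mutant_fraction > 0 &
           (gene %in% tr$mutations[label == "founder", gene] |
              sample == "Met2")]
  e <- cfg$error_rate
  g[, f_true := mutant_fraction + (1 - mutant_fraction) * e]
  g[, err := abs(alt_count / depth - f_true)]
  g[, se := sqrt(f_true * (1 - f_true) / depth)]
  expect_lte(mean(g$err), 2 * mean(g$se))
})
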
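# Junction, RNA and perturbation-matrix generators.

test_that("junction generator plants the focal deletion breakpoints", {
  cfg <- sim_config(seed = 4)
  j <- simulate_junctions(cfg)
  fd <- cfg$focal_deletion
  del <- j[chrom1 == fd$chrom & type == "deletion" & pos1 == fd$start]
  tumors <- cfg$samples[role == "tumor", sample]
  expect_setequal(del$sample, tumors)
  expect_true(all(del$pos1 == 76916706 & del$pos2 == 76932433))
  expect_identical(j, simulate_junctions(cfg))
})

test_that("junction types are consistent with endpoint orientations", {
  cfg <- sim_config(seed = 4)
  j <- simulate_junctions(cfg)
  expect_identical(
    type_junction(j$chrom1, j$pos1, j$strand1, j$chrom2, j$pos2, j$strand2),
    j$type)
  ct <- cfg$chromothripsis
  shatter <- j[!(pos1 == cfg$focal_deletion$start &
                   type == "deletion" & chrom1 == cfg$focal_deletion$chrom)]
  expect_true(all(shatter$pos1 > ct$start & shatter$pos2 <= ct$end))
  expect_equal(nrow(shatter), ct$n_junctions)
})

test_that("zero junctions and undersized regions are handled", {
  cfg <- tiny_config(seed = 4)
  cfg$chromothripsis$n_junctions <- 0L
  j <- simulate_junctions(cfg)
  expect_true(all(j$type == "deletion" & j$pos1 == cfg$focal_deletion$start))
  cfg$chromothripsis$n_junctions <- 1e5L
  expect_error(simulate_junctions(cfg), "too small")
})

test_that("RNA counts follow configured expression and mutant fractions", {
  cfg <- sim_config(seed = 6)
  rna <- simulate_rna(cfg)
  tr <- truth_table(cfg)
  # unexpressed genes: zero gene reads and zero site depth
  off <- tr$genes[expression == 0, gene]
  expect_true(all(rna$gene_counts[gene %in% off, reads] == 0))
  expect_true(all(rna$site_counts[gene %in% off, depth] == 0))
  # fraction-zero expressed genes show only error-level mutant reads
  zero_fr <- intersect(sprintf("FND%02d", 4:6), tr$genes[expression > 0, gene])
  z <- rna$site_counts[gene %in% zero_fr & depth > 0]
  f <- sum(z$alt_count) / sum(z$depth)
  expect_lt(f, cfg$error_rate + 4 * sqrt(cfg$error_rate / sum(z$depth)))
  expect_identical(rna, simulate_rna(cfg))
})

test_that("mutant fraction recovers truth at deep RNA coverage", {
  # one gene at expression 80 with rna_depth 125 -> site depth ~ 1e4;
  # binomial SE ~ 0.005, so 0.015 is a 3-sigma band
  cfg <- tiny_config(seed = 8, error_rate = 1e-4,
                     true_expression = c(LPAR1L = 80, GATA2L = 10,
                                         NUFIP1L = 10, MET2G01 = 5,
                                         MET2G02 = 5),
                     true_mutant_rna_fractions = c(LPAR1L = 0.4, GATA2L = 0.2,
                                                   NUFIP1L = 0.2,
                                                   MET2G01 = 0.3,
                                                   MET2G02 = 0.3),
                     rna_depth = 125)
  rna <- simulate_rna(cfg)
  s <- rna$site_counts[gene == "LPAR1L" & sample == "Met2"]
  expect_gt(s$depth, 5000)
  expect_lt(abs(s$alt_count / s$depth - 0.4), 0.015)
})

test_that("a positive mutant fraction on an unexpressed gene warns", {
  cfg <- tiny_config(seed = 8,
                     true_expression = c(LPAR1L = 0, GATA2L = 10,
                                         NUFIP1L = 10, MET2G01 = 5,
                                         MET2G02 = 5),
                     true_mutant_rna_fractions = c(LPAR1L = 0.4, GATA2L = 0,
                                                   NUFIP1L = 0, MET2G01 = 0,
                                                   MET2G02 = 0))
  expect_warning(rna <- simulate_rna(cfg), "unexpressed")
  expect_true(all(rna$site_counts[gene == "LPAR1L", alt_count] == 0))
})

test_that("perturbation matrix plants the configured response", {
  cfg <- sim_config(seed = 12)
  X <- simulate_perturbation_matrix(cfg)
  expect_true(all(X > 0))
  rsp <- attr(X, "responsive_genes")
  dce <- rank_by_dce(X, 1)
  expect_lt(abs(mean(dce[rsp]) - log2(cfg$perturb$effect)), 0.25)
  # non-responsive genes: DCE symmetric about 0
  expect_lt(abs(mean(dce[setdiff(names(dce), rsp)])), 0.05)
  # null effect size centers everything at 0
  cfg0 <- sim_config(seed = 12, perturb = list(effect = 1))
  d0 <- rank_by_dce(simulate_perturbation_matrix(cfg0), 1)
  expect_lt(abs(mean(d0)), 0.05)
  cfgbad <- sim_config(seed = 12, perturb = list(effect = 0))
  expect_error(simulate_perturbation_matrix(cfgbad), "effect")
  expect_identical(X, simulate_perturbation_matrix(cfg))
})
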
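# Somatic score, calling, panel filtering, coding annotation and the
# mutation-rate arithmetic.

test_that("somatic score matches a direct binomial evaluation", {
  # tumor 15/30, normal 0/30, e = 0.01: evaluate the three binomial
  # log-likelihood terms independently
  e <- 0.01
  l10 <- function(k, n, p) dbinom(k, n, p, log = TRUE) / log(10)
  num <- l10(15, 30, 0.5) + l10(0, 30, e)
  germ <- l10(15, 30, 0.5) + l10(0, 30, 0.5)
  null <- l10(15, 30, e) + l10(0, 30, e)
  expect_equal(somatic_score(15, 30, 0, 30, e), num - max(germ, null))
})

test_that("score behaves at null and germline configurations", {
  expect_lte(somatic_score(0, 50, 0, 50), 0)
  expect_lt(somatic_score(25, 50, 25, 50), 0)   # germline het dominates
  # clear somatic site flips negative when tumor and normal are swapped
  expect_gt(somatic_score(20, 50, 0, 50), 0)
  expect_lt(somatic_score(0, 50, 20, 50), 0)
})

test_that("score is monotone in tumor variant count with clean normal", {
  # monotone over the clearly somatic range (tumor VAF <= 0.25); nearer VAF
  # 0.5 the germline-heterozygote model regains likelihood and the score
  # flattens, without ever dropping near a calling threshold
  s <- somatic_score(0:25, rep(100, 26), rep(0, 26), rep(100, 26))
  expect_true(all(diff(s) >= -1e-12))
  s_all <- somatic_score(0:50, rep(100, 51), rep(0, 51), rep(100, 51))
  expect_true(all(s_all[11:51] > 4))
})

test_that("degenerate inputs raise", {
  expect_error(somatic_score(0, 0, 0, 50), "zero depth")
  expect_error(somatic_score(1, 10, 0, 10, error_rate = 0.7), "error_rate")
})

test_that("call_somatic applies gates and returns sorted unique sites", {
  cfg <- tiny_config(seed = 21)
  pu <- simulate_dna_pileups(cfg)
  expect_error(call_somatic(pu, "Met2", "Skin"), "missing normal")
  empty <- pu[0]
  expect_equal(nrow(call_somatic(empty, "Met2", "Normal")), 0)

  all_sites <- call_somatic(pu, "Met2", "Normal", score_min = -Inf,
                            min_depth = 10)
  deep <- merge(pu[sample == "Met2"], pu[sample == "Normal"],
                by = c("chrom", "pos", "ref", "alt"))
  expect_equal(nrow(all_sites), nrow(deep[depth.x >= 10 & depth.y >= 10]))

  calls <- call_somatic(pu, "Met2", "Normal")
  expect_false(any(duplicated(calls[, .(chrom, pos, ref, alt)])))
  expect_true(all(diff(order(calls$chrom, calls$pos)) > 0))
  expect_true(all(calls$tvaf >= 0 & calls$tvaf <= 1))
})

test_that("panel filtering equals the brute-force oracle", {
  set.seed(31)
  v <- data.table::data.table(
    chrom = "chr1", pos = sample(1e6, 80), ref = "A", alt = "T")
  in_panel <- sample(nrow(v), 30)
  panel <- data.table::data.table(
    v[in_panel, .(chrom, pos, ref, alt)], hits = sample(1:5, 30, TRUE))
  for (mh in c(0L, 2L)) {
    kept <- filter_against_panel(v, panel, max_hits = mh)
    # oracle: exhaustive per-variant lookup
    hits <- vapply(seq_len(nrow(v)), function(i) {
      h <- panel[chrom == v$chrom[i] & pos == v$pos[i] &
                   ref == v$ref[i] & alt == v$alt[i], hits]
      if (length(h)) h else 0L
    }, integer(1))
    expect_equal(nrow(kept), sum(hits <= mh))
    expect_equal(nrow(attr(kept, "removed")), sum(hits > mh))
  }
  expect_equal(nrow(filter_against_panel(v, panel[0])), nrow(v))
})

test_that("coding annotation classifies by codon translation", {
  gm <- gene_models(
    genes = data.table::data.table(gene = "T1", chrom = "c", strand = "+",
                                   cds = "ATGGCTCTGTGC"),
    exons = data.table::data.table(gene = "T1", chrom = "c",
                                   start = 100L, end = 112L))
  ann <- function(pos, ref, alt) {
    annotate_coding(data.table::data.table(chrom = "c", pos = pos, ref = ref,
                                           alt = alt), gm)$annotation
  }
  expect_equal(ann(105, "C", "A"), "nonsynonymous")   # GCT -> GAT (A>D)
  expect_equal(ann(109, "G", "A"), "synonymous")      # CTG -> CTA (L=L)
  expect_equal(ann(112, "C", "A"), "stopgain")        # TGC -> TGA (*)
  expect_equal(ann(111, "TCA", "T"), "frameshift")    # 2-bp exonic deletion
  expect_equal(ann(105, "CTGA", "C"), "inframe")      # 3-bp exonic deletion
  expect_equal(ann(500, "A", "G"), "non-coding")
  expect_error(ann(105, "C", "C"), "equals reference")

  # minus strand: genomic alleles are complemented before translation
  gm2 <- gene_models(
    genes = data.table::data.table(gene = "T2", chrom = "c", strand = "-",
                                   cds = "ATGGCTCTGTGC"),
    exons = data.table::data.table(gene = "T2", chrom = "c",
                                   start = 100L, end = 112L))
  v <- annotate_coding(
    data.table::data.table(chrom = "c", pos = 108, ref = "G", alt = "T"), gm2)
  expect_equal(v$annotation, "nonsynonymous")         # cds GCT -> GAT
})

test_that("mutation rate per Mb is simple division", {
  expect_equal(round(mutation_rate_per_mb(44, 51.7), 2), 0.85)
  expect_equal(mutation_rate_per_mb(0, 10), 0)
  expect_equal(mutation_rate_per_mb(20, 8), 2 * mutation_rate_per_mb(10, 8))
  expect_error(mutation_rate_per_mb(5, 0), "footprint")
})
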
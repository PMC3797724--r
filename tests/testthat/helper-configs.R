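# Small worlds for fast unit tests.  The default sim_config() is the full
# stated world; tiny_config() shrinks the genome to one chromosome with a
# handful of genes so generators run in milliseconds.

tiny_gene_models <- function(seed = 1) {
  mk <- function(name, start) {
    list(genes = data.table::data.table(gene = name, chrom = "chr1",
                                        strand = "+"),
         exons = data.table::data.table(gene = name, chrom = "chr1",
                                        start = start + c(0L, 600L),
                                        end = start + c(300L, 900L)))
  }
  parts <- Map(mk, c("LPAR1L", "GATA2L", "NUFIP1L", "MET2G01", "MET2G02"),
               c(50000L, 150000L, 250000L, 350000L, 450000L))
  genes <- data.table::rbindlist(lapply(parts, `[[`, "genes"))
  exons <- data.table::rbindlist(lapply(parts, `[[`, "exons"))
  set.seed(seed)
  genes$cds <- vapply(genes$gene, function(g) {
    paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  }, character(1))
  gene_models(genes, exons)
}

tiny_config <- function(seed = 1, purity = 1, dna_depth = 100,
                        error_rate = 0.01, cn = 2L, major = 1L, minor = 1L,
                        n_error_sites = 200L, n_artifact_sites = 5L, ...) {
  sim_config(
    seed = seed,
    genome = data.table::data.table(chrom = "chr1", length = 1e6),
    gene_models = tiny_gene_models(seed),
    samples = data.table::data.table(
      sample = c("Normal", "Met1", "Met2"),
      role = c("normal", "tumor", "tumor"),
      timepoint = c("germline", "diagnosis", "relapse"),
      purity = c(NA, purity, purity)),
    n_founder_mutations = 3L, n_private_mutations = 2L,
    dna_depth = dna_depth, error_rate = error_rate,
    n_error_sites = n_error_sites, n_artifact_sites = n_artifact_sites,
    ploidy_profile = data.table::data.table(
      chrom = "chr1", start = 0, end = 1e6, cn = cn, major = major,
      minor = minor),
    focal_deletion = list(chrom = "chr1", start = 600001, end = 616001,
                          gene = NA, cn = max(1L, cn - 1L)),
    chromothripsis = list(chrom = "chr1", start = 700000, end = 800000,
                          n_junctions = 5L, states = c(cn, max(1L, cn - 1L))),
    rna_samples = c("Met1", "Met2"),
    ...)
}
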
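# RNA generators: per-gene read counts and per-site mutant allele counts.

SIM_RNA_LIBSIZE <- 2e6  # declared mapped-read library size per RNA sample

#' Simulate RNA read counts
#'
#' Gene-level counts are Poisson around
#' `expression * exon_kb * libsize/1e6` so that the RPKM estimate recovers the
#' configured RPKM-scale expression.  Mutant-allele site counts are binomial
#' at the configured true mutant transcript fraction (plus sequencing error)
#' with site depth proportional to the gene's expression.  Setting a positive
#' mutant fraction on an unexpressed gene draws a warning; its counts are 0.
#'
#' @param config a [sim_config] object.
#' @return list with `gene_counts`
#'   (`gene, sample, reads, exon_length, total_mapped`) and `site_counts`
#'   (`chrom, pos, ref, alt, gene, sample, alt_count, depth`).
#' @export
simulate_rna <- function(config) {
  cfg <- config
  truth <- truth_table(cfg)
  gm <- cfg$gene_models
  exlen <- gene_exon_length(gm)
  expr <- truth$genes$expression
  names(expr) <- truth$genes$gene
  e <- cfg$error_rate

  fr <- cfg$true_mutant_rna_fractions
  fr <- fr[names(fr) %in% names(expr)]
  bad <- names(fr)[fr > 0 & expr[names(fr)] == 0]
  if (length(bad)) {
    warning("mutant RNA fraction set for unexpressed gene(s): ",
            paste(bad, collapse = ", "), "; counts will be 0")
  }

  gene_counts <- rbindlist(lapply(cfg$rna_samples, function(s) {
    run_seeded(substream(cfg$seed, paste0("rna-genes:", s)), function() {
      lam <- expr * (exlen[names(expr)] / 1000) * (SIM_RNA_LIBSIZE / 1e6)
      data.table(gene = names(expr), sample = s,
                 reads = rpois(length(lam), lam),
                 exon_length = as.integer(exlen[names(expr)]),
                 total_mapped = SIM_RNA_LIBSIZE)
    })
  }))

  muts <- truth$mutations
  site_counts <- rbindlist(lapply(cfg$rna_samples, function(s) {
    present <- muts$label == "founder" | s == "Met2"
    frac <- ifelse(present, fr[muts$gene], 0)
    frac[is.na(frac)] <- 0
    gexpr <- expr[muts$gene]
    run_seeded(substream(cfg$seed, paste0("rna-sites:", s)), function() {
      depth <- rpois(nrow(muts), gexpr * cfg$rna_depth)
      f_eff <- frac + (1 - frac) * e
      data.table(chrom = muts$chrom, pos = muts$pos, ref = muts$ref,
                 alt = muts$alt, gene = muts$gene, sample = s,
                 alt_count = rbinom(nrow(muts), depth, f_eff), depth = depth)
    })
  }))
  list(gene_counts = gene_counts, site_counts = site_counts)
}
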
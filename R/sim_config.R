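# Simulation configuration: the "stated world" every generator draws from.
# One integer seed reproduces the entire dataset; per-generator and per-sample
# RNG streams are derived by fixed hashing so adding one output never
# perturbs another.

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a deterministic sub-seed for a named RNG stream
#'
#' @param seed master integer seed.
#' @param key stream label, e.g. `"pileups:Met2"`.
#' @return an integer seed below 2^31.
#' @keywords internal
substream <- function(seed, key) {
  u <- utf8ToInt(key)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) %% 1e9 * 7919 + h * 104729) %% 2147483629)
}

run_seeded <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fn()
}

#' Gene model collection
#'
#' A light container for exon-resolved gene models with an attached coding
#' sequence, enough to compute exonic footprints, RPKM exon lengths and
#' codon-level annotation of small variants.
#'
#' @param genes `data.table` with columns `gene`, `chrom`, `strand`
#'   (`"+"`/`"-"`) and `cds` (spliced coding sequence, mRNA sense strand;
#'   may be `NA` when unknown, e.g. models read from BED12).
#' @param exons `data.table` with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), non-overlapping and sorted within gene.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  genes <- as.data.table(genes)
  exons <- as.data.table(exons)
  stopifnot(all(c("gene", "chrom", "strand") %in% names(genes)),
            all(c("gene", "chrom", "start", "end") %in% names(exons)))
  if (!"cds" %in% names(genes)) genes[, cds := NA_character_]
  setorder(exons, gene, start)
  bad <- exons[, any(diff(start) <= 0) || any(end <= start) ||
                 any(head(end, -1) > tail(start, -1)), by = gene]
  if (any(bad$V1)) {
    stop("exons must be sorted, non-overlapping, with end > start (gene ",
         paste(bad$gene[bad$V1], collapse = ", "), ")")
  }
  len <- exons[, sum(end - start), by = gene]
  if (any(len$V1 < 3)) stop("total exon length must be >= 3")
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ",
      nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' Total exonic length per gene
#' @param gm a [gene_models] object.
#' @return named integer vector of summed exon lengths (bp).
#' @export
gene_exon_length <- function(gm) {
  len <- gm$exons[, sum(end - start), by = gene]
  setNames(as.integer(len$V1), len$gene)
}

#' Default synthetic gene complement
#'
#' 20 evenly spaced 4-exon genes on each of three 5 Mb autosomes, plus a
#' 20-exon minus-strand gene (`ATRXL`) on the X-like contig whose exons 10-12
#' (transcription order) sit inside the default focal deletion.  Coding
#' sequences are random but fixed by the seed.
#'
#' @param seed integer seed fixing the coding sequences.
#' @return a [gene_models] object.
#' @export
default_gene_models <- function(seed = 1L) {
  founder_names <- c("LPAR1L", "GATA2L", "NUFIP1L", sprintf("FND%02d", 4:15))
  private_names <- sprintf("MET2G%02d", 1:30)
  background_names <- sprintf("BKG%02d", 1:15)

  genes_list <- list()
  exons_list <- list()
  for (ci in 1:3) {
    chrom <- paste0("chr", ci)
    for (i in 1:20) {
      slot <- (ci - 1) * 20 + i
      name <- if (i <= 5) {
        founder_names[(ci - 1) * 5 + i]
      } else if (i <= 15) {
        private_names[(ci - 1) * 10 + (i - 5)]
      } else {
        background_names[(ci - 1) * 5 + (i - 15)]
      }
      gstart <- 100000 + (i - 1) * 240000
      ex_start <- gstart + c(0L, 2000L, 4000L, 6000L)
      exons_list[[slot]] <- data.table(
        gene = name, chrom = chrom, start = ex_start, end = ex_start + 300L)
      genes_list[[slot]] <- data.table(gene = name, chrom = chrom, strand = "+")
    }
  }

  # ATRX-like gene on the X-like contig, minus strand, 20 exons of 150 bp.
  # Exon ordinals count from the transcription start (highest coordinate).
  atrx_starts <- c(
    76896000, 76899000, 76902000, 76905000, 76908000, 76911000, 76913500,
    76915800, 76917500, 76922000, 76929000, 76933500, 76936000, 76939000,
    76942000, 76945000, 76948000, 76951000, 76954000, 76957000)
  exons_list[[61]] <- data.table(
    gene = "ATRXL", chrom = "chrXs",
    start = as.integer(atrx_starts), end = as.integer(atrx_starts + 150L))
  genes_list[[61]] <- data.table(gene = "ATRXL", chrom = "chrXs", strand = "-")

  genes <- rbindlist(genes_list)
  exons <- rbindlist(exons_list)
  lens <- exons[, sum(end - start), by = gene]
  cds_seq <- run_seeded(substream(seed, "cds"), function() {
    vapply(seq_len(nrow(lens)), function(i) {
      paste(sample(DNA_BASES, lens$V1[i], replace = TRUE), collapse = "")
    }, character(1))
  })
  genes[, cds := cds_seq[match(gene, lens$gene)]]
  gene_models(genes, exons)
}

default_ploidy_profile <- function() {
  # chromothripsis: irregular fragment sizes (as shattering produces), two
  # copy-number states oscillating across the region
  block_kb <- c(500, 300, 400, 300, 500, 300, 400, 300)
  bounds <- 1000000 + c(0, cumsum(block_kb * 1000))
  blocks <- lapply(seq_along(block_kb), function(b) {
    tetra <- b %% 2 == 0
    data.table(chrom = "chr3", start = bounds[b], end = bounds[b + 1],
               cn = if (tetra) 4L else 2L,
               major = if (tetra) 2L else 1L,
               minor = if (tetra) 2L else 1L)
  })
  rbindlist(c(list(
    data.table(chrom = "chr1", start = 0, end = 2500000, cn = 2L, major = 2L, minor = 0L),
    data.table(chrom = "chr1", start = 2500000, end = 5000000, cn = 4L, major = 2L, minor = 2L),
    data.table(chrom = "chr2", start = 0, end = 5000000, cn = 4L, major = 3L, minor = 1L),
    data.table(chrom = "chr3", start = 0, end = 1000000, cn = 4L, major = 2L, minor = 2L)),
    blocks,
    list(
      data.table(chrom = "chr3", start = 4000000, end = 5000000, cn = 4L, major = 2L, minor = 2L),
      data.table(chrom = "chrXs", start = 0, end = 76916705, cn = 4L, major = 2L, minor = 2L),
      data.table(chrom = "chrXs", start = 76916705, end = 76932432, cn = 3L, major = 2L, minor = 1L),
      data.table(chrom = "chrXs", start = 76932432, end = 77000000, cn = 4L, major = 2L, minor = 2L)
    )))
}

#' Build a simulation configuration
#'
#' Describes a miniature longitudinal tumor study: one germline sample, a
#' diagnostic metastasis (Met1), four sections of the resected primary tumor
#' (PT1-PT4) and a terminal metastasis (Met2).  Defaults encode the assumed
#' world: a founder mutation set shared by every tumor sample, a Met2-private
#' set, a near-tetraploid genome with an LOH arm, a 3:1 allele-ratio
#' chromosome, an oscillating two-state chromothripsis region, and a 15,727 bp
#' focal hemizygous deletion on an X-like contig at the canonical coordinates
#' 76916706-76932433 (1-based; `end` is the first retained base).
#'
#' @param seed master integer seed; the whole dataset is a pure function of it.
#' @param genome `data.table(chrom, length)`.
#' @param gene_models a [gene_models] object (default [default_gene_models()]).
#' @param samples `data.table(sample, role, timepoint, purity)`;
#'   `role` is `"normal"` or `"tumor"`, `purity` the tumor cell fraction.
#' @param n_founder_mutations,n_private_mutations numbers of planted somatic
#'   SNVs shared by all tumors / unique to Met2 (each in its own gene).
#' @param dna_depth mean haploid-pair read depth (coverage of the diploid
#'   normal); tumor depth scales with local copy number and purity.
#' @param rna_depth RNA reads per unit expression at a mutant site.
#' @param error_rate per-base sequencing error fraction.
#' @param het_spacing mean spacing (bp) of germline heterozygous sites.
#' @param n_error_sites number of error-only sites interrogated in pileups
#'   (used to measure the caller's false-positive rate).
#' @param n_artifact_sites,artifact_rate recurrent platform-artifact sites
#'   (elevated non-reference rate in tumors, present in the normal panel).
#' @param panel_size number of unrelated germline genomes in the panel.
#' @param ploidy_profile `data.table(chrom, start, end, cn, major, minor)`
#'   covering the genome (0-based half-open).
#' @param focal_deletion list `(chrom, start, end, gene, cn)`; 1-based
#'   coordinates, `end` exclusive, so length = end - start.
#' @param chromothripsis list `(chrom, start, end, n_junctions, states)`.
#' @param rna_samples samples with transcriptome data.
#' @param true_expression named RPKM-scale expression per gene.
#' @param true_mutant_rna_fractions named mutant-allele transcript fraction
#'   per mutated gene (applies in samples carrying the mutation).
#' @param perturb list controlling the perturbation expression matrix:
#'   `n_genes`, `n_responsive`, `effect` (fold change in mutant cells at 1 h
#'   and 2 h), `sigma` (log-normal measurement noise), `baseline_meanlog`,
#'   `baseline_sdlog`, `common_responsive`, `common_effect` (ligand response
#'   shared by both conditions, cancelling in the differential statistic).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = NULL,
                       gene_models = NULL,
                       samples = NULL,
                       n_founder_mutations = 15L,
                       n_private_mutations = 30L,
                       dna_depth = 100,
                       rna_depth = 5,
                       error_rate = 0.01,
                       het_spacing = 5000,
                       n_error_sites = 20000L,
                       n_artifact_sites = 50L,
                       artifact_rate = 0.05,
                       panel_size = 119L,
                       ploidy_profile = NULL,
                       focal_deletion = NULL,
                       chromothripsis = NULL,
                       rna_samples = c("Met1", "PT1", "Met2"),
                       true_expression = NULL,
                       true_mutant_rna_fractions = NULL,
                       perturb = NULL) {
  if (is.null(genome)) {
    genome <- data.table(chrom = c("chr1", "chr2", "chr3", "chrXs"),
                         length = c(5e6, 5e6, 5e6, 77e6))
  }
  genome <- as.data.table(genome)
  if (is.null(gene_models)) gene_models <- default_gene_models(seed)
  if (is.null(samples)) {
    samples <- data.table(
      sample = c("Normal", "Met1", "PT1", "PT2", "PT3", "PT4", "Met2"),
      role = c("normal", rep("tumor", 6)),
      timepoint = c("germline", "diagnosis", rep("resection", 4), "relapse"),
      purity = c(NA_real_, 0.9, 0.65, 0.65, 0.65, 0.65, 0.9))
  }
  samples <- as.data.table(samples)
  if (is.null(ploidy_profile)) ploidy_profile <- default_ploidy_profile()
  ploidy_profile <- as.data.table(ploidy_profile)
  if (is.null(focal_deletion)) {
    focal_deletion <- list(chrom = "chrXs", start = 76916706, end = 76932433,
                           gene = "ATRXL", cn = 3L)
  }
  if (is.null(chromothripsis)) {
    chromothripsis <- list(chrom = "chr3", start = 1000000, end = 4000000,
                           n_junctions = 48L, states = c(4L, 2L))
  }
  founder_genes <- intersect(
    c("LPAR1L", "GATA2L", "NUFIP1L", sprintf("FND%02d", 4:15)),
    gene_models$genes$gene)
  private_genes <- intersect(sprintf("MET2G%02d", 1:30), gene_models$genes$gene)
  if (n_founder_mutations > length(founder_genes)) {
    stop("n_founder_mutations exceeds the founder gene pool (",
         length(founder_genes), ")")
  }
  if (n_private_mutations > length(private_genes)) {
    stop("n_private_mutations exceeds the private gene pool (",
         length(private_genes), ")")
  }
  founder_genes <- founder_genes[seq_len(n_founder_mutations)]
  private_genes <- private_genes[seq_len(n_private_mutations)]

  if (is.null(true_expression)) {
    true_expression <- c(
      LPAR1L = 80, GATA2L = 30, NUFIP1L = 25,
      setNames(c(8, 12, 6), sprintf("FND%02d", 4:6)),
      setNames(c(5, 10, 15, 20, 9, 7), sprintf("FND%02d", 7:12)),
      setNames(c(0, 0, 0), sprintf("FND%02d", 13:15)),
      setNames(rep(c(0, 2, 6, 12, 25, 40), 5), sprintf("MET2G%02d", 1:30)),
      setNames(rep(c(1, 4, 10, 22, 35), 3), sprintf("BKG%02d", 1:15)),
      ATRXL = 15)
  }
  if (is.null(true_mutant_rna_fractions)) {
    true_mutant_rna_fractions <- c(
      LPAR1L = 0.5, GATA2L = 0.5, NUFIP1L = 0.45,
      setNames(rep(0, 3), sprintf("FND%02d", 4:6)),
      setNames(rep(0.1, 6), sprintf("FND%02d", 7:12)),
      setNames(rep(0, 3), sprintf("FND%02d", 13:15)),
      setNames(rep(0.3, 30), sprintf("MET2G%02d", 1:30)))
    # default world: unexpressed genes carry no mutant transcripts
    expressed <- names(true_expression)[true_expression > 0]
    true_mutant_rna_fractions[
      !(names(true_mutant_rna_fractions) %in% expressed)] <- 0
  }
  perturb_defaults <- list(
    n_genes = 5000L, n_responsive = 100L, effect = 4, sigma = 0.25,
    baseline_meanlog = 6, baseline_sdlog = 1,
    common_responsive = 300L, common_effect = 2)
  perturb <- if (is.null(perturb)) perturb_defaults else
    modifyList(perturb_defaults, perturb)

  cfg <- structure(list(
    seed = as.integer(seed), genome = genome, gene_models = gene_models,
    samples = samples,
    founder_genes = founder_genes, private_genes = private_genes,
    n_founder_mutations = as.integer(n_founder_mutations),
    n_private_mutations = as.integer(n_private_mutations),
    dna_depth = dna_depth, rna_depth = rna_depth, error_rate = error_rate,
    het_spacing = het_spacing, n_error_sites = as.integer(n_error_sites),
    n_artifact_sites = as.integer(n_artifact_sites),
    artifact_rate = artifact_rate, panel_size = as.integer(panel_size),
    ploidy_profile = ploidy_profile, focal_deletion = focal_deletion,
    chromothripsis = chromothripsis, rna_samples = rna_samples,
    true_expression = true_expression,
    true_mutant_rna_fractions = true_mutant_rna_fractions,
    perturb = perturb), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  g <- cfg$genome
  if (any(g$length <= 0)) stop("chromosome lengths must be > 0")
  pur <- cfg$samples[role == "tumor", purity]
  if (any(is.na(pur)) || any(pur < 0 | pur > 1)) {
    stop("tumor purity must lie in [0, 1]")
  }
  if (!any(cfg$samples$role == "normal")) stop("a normal sample is required")
  if (cfg$dna_depth <= 0 || cfg$rna_depth <= 0) stop("depths must be > 0")
  if (cfg$error_rate <= 0 || cfg$error_rate >= 0.5) {
    stop("error_rate must lie in (0, 0.5)")
  }
  fr <- cfg$true_mutant_rna_fractions
  if (any(fr < 0 | fr > 1)) stop("mutant RNA fractions must lie in [0, 1]")
  in_genome <- function(ch, start, end) {
    len <- g$length[g$chrom == ch]
    length(len) == 1 && start >= 0 && end <= len && end > start
  }
  fd <- cfg$focal_deletion
  if (!in_genome(fd$chrom, fd$start - 1, fd$end - 1)) {
    stop("focal_deletion outside genome bounds")
  }
  ct <- cfg$chromothripsis
  if (!in_genome(ct$chrom, ct$start, ct$end)) {
    stop("chromothripsis_region outside genome bounds")
  }
  pp <- copy(cfg$ploidy_profile)
  setorder(pp, chrom, start)
  for (ch in g$chrom) {
    rows <- pp[chrom == ch]
    if (nrow(rows) == 0 || rows$start[1] != 0 ||
        rows$end[nrow(rows)] != g[chrom == ch, length] ||
        (nrow(rows) > 1 && any(head(rows$end, -1) != tail(rows$start, -1)))) {
      stop("ploidy_profile must tile chromosome ", ch, " contiguously")
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed ", x$seed, "; ",
      nrow(x$genome), " chromosomes (",
      format(sum(x$genome$length), big.mark = ","), " bp); ",
      nrow(x$samples), " samples; ",
      x$n_founder_mutations, " founder + ",
      x$n_private_mutations, " private mutations\n", sep = "")
  invisible(x)
}

# Purity-weighted per-haploid mixture factor: expected coverage relative to a
# diploid genome is mix/2, where mix = purity*cn + 2*(1-purity).
mixture_cn <- function(cn, purity) purity * cn + 2 * (1 - purity)

ploidy_at <- function(profile, chroms, pos0) {
  q <- data.table(chrom = chroms, start = pos0, end = pos0 + 1L,
                  qid = seq_along(chroms))
  p <- copy(profile)
  setkey(p, chrom, start, end)
  hit <- foverlaps(q, p, type = "within", nomatch = NA)
  setorder(hit, qid)
  hit[, .(cn, major, minor)]
}

genome_mean_mix <- function(cfg, purity) {
  pp <- cfg$ploidy_profile
  sum((pp$end - pp$start) * mixture_cn(pp$cn, purity)) /
    sum(pp$end - pp$start)
}

# Map a 0-based offset into the spliced CDS to genomic position, honouring
# strand; returns 1-based genomic positions.
cds_to_genome <- function(gm, gene_name, cds_idx0) {
  ex <- gm$exons[gene == gene_name]
  strand <- gm$genes[gene == gene_name, strand]
  widths <- ex$end - ex$start
  total <- sum(widths)
  stopifnot(all(cds_idx0 >= 0 & cds_idx0 < total))
  gidx <- if (strand == "+") cds_idx0 else total - 1 - cds_idx0
  cum <- cumsum(c(0, widths))
  exi <- findInterval(gidx, cum, rightmost.closed = FALSE)
  ex$start[exi] + (gidx - cum[exi]) + 1L
}

# Inverse: 1-based genomic position -> 0-based CDS offset (NA if intronic or
# outside the gene).
genome_to_cds <- function(gm, gene_name, pos1) {
  ex <- gm$exons[gene == gene_name]
  strand <- gm$genes[gene == gene_name, strand]
  widths <- ex$end - ex$start
  cum <- cumsum(c(0, widths))
  total <- sum(widths)
  p0 <- pos1 - 1L
  out <- rep(NA_integer_, length(p0))
  for (i in seq_along(p0)) {
    hit <- which(ex$start <= p0[i] & p0[i] < ex$end)
    if (length(hit) == 1) {
      gidx <- cum[hit] + (p0[i] - ex$start[hit])
      out[i] <- if (strand == "+") gidx else total - 1L - gidx
    }
  }
  out
}

complement_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

#' Ground truth for a simulated dataset
#'
#' Recomputes, deterministically from the configuration alone, every planted
#' event: somatic mutation sites with per-sample true variant allele
#' fractions, per-segment expected coverage log-ratios / lesser allele
#' fractions / event flags, and per-gene expression with mutant transcript
#' fractions.  Used by parameter-recovery tests; the generators draw noisy
#' data around exactly these values.
#'
#' @param config a [sim_config] object.
#' @return list with elements `mutations`, `vafs` (long, per sample),
#'   `segments` (per tumor sample), and `genes`.
#' @export
truth_table <- function(config) {
  cfg <- config
  gm <- cfg$gene_models
  mut_genes <- c(cfg$founder_genes, cfg$private_genes)
  labels <- c(rep("founder", length(cfg$founder_genes)),
              rep("private", length(cfg$private_genes)))

  muts <- run_seeded(substream(cfg$seed, "mutations"), function() {
    rows <- lapply(seq_along(mut_genes), function(i) {
      gname <- mut_genes[i]
      strand <- gm$genes[gene == gname, strand]
      cds <- gm$genes[gene == gname, cds]
      total <- nchar(cds)
      # draw coding positions until one admits a protein-changing substitution
      for (try in 1:25) {
        idx0 <- sample.int(total, 1) - 1L
        codon_i <- idx0 %/% 3L
        within <- idx0 %% 3L
        codon <- substr(cds, codon_i * 3 + 1, codon_i * 3 + 3)
        ref_cds <- substr(cds, idx0 + 1, idx0 + 1)
        alts <- sample(setdiff(DNA_BASES, ref_cds))
        aa_ref <- translate_codon(codon)
        pick <- NA_character_
        for (a in alts) {
          mcodon <- codon
          substr(mcodon, within + 1, within + 1) <- a
          aa <- translate_codon(mcodon)
          if (aa != aa_ref && aa != "*") { pick <- a; break }
        }
        if (!is.na(pick)) break
      }
      if (is.na(pick)) pick <- alts[1]
      pos1 <- cds_to_genome(gm, gname, idx0)
      ref_g <- if (strand == "+") ref_cds else complement_base(ref_cds)
      alt_g <- if (strand == "+") pick else complement_base(pick)
      data.table(gene = gname, chrom = gm$genes[gene == gname, chrom],
                 pos = pos1, ref = ref_g, alt = alt_g, label = labels[i])
    })
    rbindlist(rows)
  })
  pl <- ploidy_at(cfg$ploidy_profile, muts$chrom, muts$pos - 1L)
  muts[, cn := pl$cn]
  muts[, mult := pmax(1L, as.integer(round(cn / 2)))]
  muts[, site_id := paste(chrom, pos, ref, alt, sep = ":")]
  setorder(muts, chrom, pos)

  tumors <- cfg$samples[role == "tumor"]
  vafs <- rbindlist(lapply(seq_len(nrow(tumors)), function(i) {
    s <- tumors$sample[i]; p <- tumors$purity[i]
    f <- ifelse(muts$label == "founder" | s == "Met2",
                p * muts$mult / mixture_cn(muts$cn, p), 0)
    data.table(site_id = muts$site_id, sample = s, vaf = f)
  }))
  vafs <- rbind(vafs, data.table(site_id = muts$site_id,
                                 sample = cfg$samples[role == "normal", sample][1],
                                 vaf = 0))

  segs <- rbindlist(lapply(seq_len(nrow(tumors)), function(i) {
    s <- tumors$sample[i]; p <- tumors$purity[i]
    pp <- copy(cfg$ploidy_profile)
    mean_mix <- genome_mean_mix(cfg, p)
    pp[, mix := mixture_cn(cn, p)]
    pp[, expected_ratio := log2(mix / mean_mix)]
    fmin <- (p * pp$minor + (1 - p)) / pp$mix
    pp[, expected_laf := pmin(fmin, 1 - fmin)]
    pp[, `:=`(sample = s,
              expected_loh = expected_laf < 0.15,
              expected_gain = expected_ratio >= 0.3,
              expected_loss = expected_ratio <= -0.3)]
    pp
  }))

  all_genes <- gm$genes$gene
  fr <- cfg$true_mutant_rna_fractions
  genes <- data.table(
    gene = all_genes,
    label = ifelse(all_genes %in% cfg$founder_genes, "founder",
                   ifelse(all_genes %in% cfg$private_genes, "private",
                          "background")),
    expression = as.numeric(cfg$true_expression[all_genes]),
    mutant_fraction = ifelse(all_genes %in% names(fr),
                             as.numeric(fr[all_genes]), 0))
  genes[is.na(expression), expression := 0]

  list(mutations = muts[], vafs = vafs, segments = segs, genes = genes)
}
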
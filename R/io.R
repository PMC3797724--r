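# Readers and writers for the plain-text interchange formats used by the
# pipeline: pileup/coverage/het TSVs, VCF 4.2 (minimal, SNV/indel sites),
# SEG, BEDPE, BED12 gene models and GMT gene-set collections.

#' Write / read a generic TSV table
#' @param x a data.frame / data.table.
#' @param path file path.
#' @return `read_tsv()` returns a `data.table`.
#' @export
write_tsv <- function(x, path) fwrite(x, path, sep = "\t")

#' @rdname write_tsv
#' @export
read_tsv <- function(path) fread(path, sep = "\t")

#' Write somatic variant calls as VCF 4.2
#'
#' INFO fields: `SS` (somatic score), `TVAF`, `NVAF`, `PANEL_N` (panel-of-
#' normals hit count); FILTER is `PASS`, `panel_fail` or `low_depth`.
#'
#' @param variants call table from [call_somatic()] (optionally after
#'   [filter_against_panel()] / [annotate_coding()]); a `filter` column, if
#'   present, is written to FILTER.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(variants, path) {
  v <- as.data.table(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=oncotrace",
    '##INFO=<ID=SS,Number=1,Type=Float,Description="Somatic score (log10 LR)">',
    '##INFO=<ID=TVAF,Number=1,Type=Float,Description="Tumor variant allele fraction">',
    '##INFO=<ID=NVAF,Number=1,Type=Float,Description="Normal variant allele fraction">',
    '##INFO=<ID=PANEL_N,Number=1,Type=Integer,Description="Panel of normals hit count">',
    '##FILTER=<ID=panel_fail,Description="Seen in panel of normals">',
    '##FILTER=<ID=low_depth,Description="Insufficient depth">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("SS=%.4g;TVAF=%.4g;NVAF=%.4g;PANEL_N=%d",
                  if (!is.null(v$score)) v$score else rep(NA_real_, nrow(v)),
                  v$tvaf, v$nvaf,
                  if (!is.null(v$panel_hits)) v$panel_hits else
                    rep(0L, nrow(v)))
  filt <- if (!is.null(v$filter)) v$filter else rep("PASS", nrow(v))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  v$chrom, v$pos, v$ref, v$alt, filt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF back into a call table
#' @param path VCF path written by [write_vcf()] (or similar site-only VCF).
#' @return `data.table(chrom, pos, ref, alt, filter, score, tvaf, nvaf,
#'   panel_hits)`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      filter = character(), score = numeric(),
                      tvaf = numeric(), nvaf = numeric(),
                      panel_hits = integer()))
  }
  f <- tstrsplit(lines, "\t", fixed = TRUE)
  getinfo <- function(info, key) {
    vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
      hit <- kv[startsWith(kv, paste0(key, "="))]
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
    }, character(1))
  }
  info <- f[[8]]
  data.table(chrom = f[[1]], pos = as.integer(f[[2]]), ref = f[[4]],
             alt = f[[5]], filter = f[[7]],
             score = as.numeric(getinfo(info, "SS")),
             tvaf = as.numeric(getinfo(info, "TVAF")),
             nvaf = as.numeric(getinfo(info, "NVAF")),
             panel_hits = as.integer(getinfo(info, "PANEL_N")))
}

#' Write segments as a SEG table
#' @param segments segment table (`chrom,start,end,n_windows,mean_ratio`).
#' @param path output path.
#' @param sample sample identifier for the ID column.
#' @return invisibly, `path`.
#' @export
write_seg <- function(segments, path, sample = "tumor") {
  s <- as.data.table(segments)
  out <- data.table(ID = sample, chrom = s$chrom, loc.start = s$start,
                    loc.end = s$end,
                    num.mark = if (!is.null(s$n_windows)) s$n_windows else NA,
                    seg.mean = s$mean_ratio)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write / read junctions as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name(type), score,
#' strand1, strand2.  Positions are converted between 1-based points and
#' 0-based half-open single-base intervals.
#'
#' @param junctions junction table (see [simulate_junctions()]).
#' @param path file path.
#' @return `read_bedpe()` returns a junction `data.table`.
#' @export
write_bedpe <- function(junctions, path) {
  j <- as.data.table(junctions)
  out <- data.table(chrom1 = j$chrom1, start1 = j$pos1 - 1L, end1 = j$pos1,
                    chrom2 = j$chrom2, start2 = j$pos2 - 1L, end2 = j$pos2,
                    name = j$type, score = ".",
                    strand1 = j$strand1, strand2 = j$strand2)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  b <- fread(path, sep = "\t", header = FALSE)
  data.table(chrom1 = b$V1, pos1 = b$V3, strand1 = b$V9,
             chrom2 = b$V4, pos2 = b$V6, strand2 = b$V10, type = b$V7)
}

#' Write / read gene models as BED12
#'
#' The coding sequence cannot be represented in BED12; models read back have
#' `cds = NA` and support exon arithmetic but not codon-level annotation.
#'
#' @param models a [gene_models] object.
#' @param path file path.
#' @return `read_bed12()` returns a [gene_models] object.
#' @export
write_bed12 <- function(models, path) {
  rows <- vapply(unique(models$exons$gene), function(g) {
    ex <- models$exons[gene == g]
    info <- models$genes[gene == g]
    paste(ex$chrom[1], min(ex$start), max(ex$end), g, 0, info$strand,
          min(ex$start), max(ex$end), "0",
          nrow(ex), paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - min(ex$start), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_bed12
#' @export
read_bed12 <- function(path) {
  b <- fread(path, sep = "\t", header = FALSE)
  exons <- rbindlist(lapply(seq_len(nrow(b)), function(i) {
    sizes <- as.integer(strsplit(b$V11[i], ",")[[1]])
    offs <- as.integer(strsplit(b$V12[i], ",")[[1]])
    data.table(gene = b$V4[i], chrom = b$V1[i],
               start = b$V2[i] + offs, end = b$V2[i] + offs + sizes)
  }))
  genes <- data.table(gene = b$V4, chrom = b$V1, strand = b$V6,
                      cds = NA_character_)
  gene_models(genes, exons)
}

#' Read / write GMT gene-set collections
#'
#' @param path GMT path (set name, description, tab-separated members).
#' @param sets named list of character vectors.
#' @param description description field (recycled).
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / restore a simulation configuration as JSON
#'
#' @param config a [sim_config] object.
#' @param path JSON path.
#' @return `read_sim_config()` returns a [sim_config] object.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$gene_models <- list(genes = x$gene_models$genes,
                        exons = x$gene_models$exons)
  # named vectors must become JSON objects, not bare arrays
  x$true_expression <- as.list(x$true_expression)
  x$true_mutant_rna_fractions <- as.list(x$true_mutant_rna_fractions)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gm <- gene_models(as.data.table(x$gene_models$genes),
                    as.data.table(x$gene_models$exons))
  sim_config(seed = x$seed, genome = as.data.table(x$genome),
             gene_models = gm, samples = as.data.table(x$samples),
             n_founder_mutations = x$n_founder_mutations,
             n_private_mutations = x$n_private_mutations,
             dna_depth = x$dna_depth, rna_depth = x$rna_depth,
             error_rate = x$error_rate, het_spacing = x$het_spacing,
             n_error_sites = x$n_error_sites,
             n_artifact_sites = x$n_artifact_sites,
             artifact_rate = x$artifact_rate, panel_size = x$panel_size,
             ploidy_profile = as.data.table(x$ploidy_profile),
             focal_deletion = x$focal_deletion,
             chromothripsis = x$chromothripsis,
             rna_samples = x$rna_samples,
             true_expression = unlist(x$true_expression),
             true_mutant_rna_fractions = unlist(x$true_mutant_rna_fractions),
             perturb = x$perturb)
}
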
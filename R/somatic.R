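# Somatic small-variant calling from paired tumor/normal pileups.
#
# The score is a transparent binomial log10 likelihood ratio contrasting a
# somatic model (tumor at its estimated variant fraction, normal at the error
# rate) against the better of two null models: a germline heterozygote
# (both samples at VAF 0.5) and pure sequencing error (both at the error
# rate).  Higher is more confidently somatic.

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Somatic score: binomial log10 likelihood ratio
#'
#' `score = log10[L(tumor | VAF = m) * L(normal | VAF = e)] -
#'  log10 max[L(both | VAF = 0.5), L(both | VAF = e)]` with binomial
#' likelihoods, where `m` is the observed tumor variant fraction floored at
#' the error rate `e`.  The score is non-negative whenever the error-only
#' null dominates the germline model (the numerator profiles the tumor VAF),
#' so calling thresholds must be positive; see [call_somatic()].
#'
#' @param tumor_alt,tumor_depth,normal_alt,normal_depth integer vectors of
#'   variant read counts and total depths.
#' @param error_rate per-base error fraction in (0, 0.5).
#' @return numeric vector of scores (log10 units).
#' @export
somatic_score <- function(tumor_alt, tumor_depth, normal_alt, normal_depth,
                          error_rate = 0.01) {
  if (error_rate <= 0 || error_rate >= 0.5) {
    stop("error_rate must lie in (0, 0.5)")
  }
  if (any(tumor_depth <= 0) || any(normal_depth <= 0)) {
    stop("somatic score undefined at zero depth")
  }
  l10 <- function(k, n, p) dbinom(k, n, p, log = TRUE) / log(10)
  e <- error_rate
  m <- pmax(tumor_alt / tumor_depth, e)
  num <- l10(tumor_alt, tumor_depth, m) + l10(normal_alt, normal_depth, e)
  germ <- l10(tumor_alt, tumor_depth, 0.5) + l10(normal_alt, normal_depth, 0.5)
  null <- l10(tumor_alt, tumor_depth, e) + l10(normal_alt, normal_depth, e)
  num - pmax(germ, null)
}

#' Call somatic variants from a pileup table
#'
#' Scores every site with [somatic_score()] for one tumor against the paired
#' normal and returns sites passing the score and depth gates, coordinate
#' sorted and duplicate free.
#'
#' @param pileups long pileup `data.table`
#'   (`chrom,pos,ref,alt,sample,ref_count,alt_count,depth`), as produced by
#'   [simulate_dna_pileups()] or read from TSV.
#' @param tumor,normal sample names to pair.
#' @param score_min minimum somatic score (default 4).  The likelihood-ratio
#'   score is >= 0 against the error-only null by construction; 4 log10 units
#'   corresponds to a per-site false-positive rate around 1e-5 at 100x depth
#'   and 1% error.
#' @param min_depth minimum depth required in both samples (default 10).
#' @param error_rate per-base error fraction.
#' @return `data.table(chrom, pos, ref, alt, score, tvaf, nvaf, tumor_depth,
#'   normal_depth)` sorted by (chrom, pos, ref, alt).
#' @export
call_somatic <- function(pileups, tumor, normal, score_min = 4,
                         min_depth = 10, error_rate = 0.01) {
  pu <- as.data.table(pileups)
  need <- c("chrom", "pos", "ref", "alt", "sample", "alt_count", "depth")
  stopifnot(all(need %in% names(pu)))
  empty_calls <- data.table(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), score = numeric(), tvaf = numeric(),
    nvaf = numeric(), tumor_depth = integer(), normal_depth = integer())
  if (nrow(pu) == 0) return(empty_calls)
  tu <- pu[sample == tumor]
  no <- pu[sample == normal]
  if (nrow(no) == 0) stop("missing normal sample '", normal, "' in pileups")
  if (nrow(tu) == 0) stop("missing tumor sample '", tumor, "' in pileups")
  m <- merge(tu, no, by = c("chrom", "pos", "ref", "alt"),
             suffixes = c("_t", "_n"))
  m <- m[depth_t >= min_depth & depth_n >= min_depth &
           depth_t > 0 & depth_n > 0]
  if (nrow(m) == 0) return(empty_calls)
  m[, score := somatic_score(alt_count_t, depth_t, alt_count_n, depth_n,
                             error_rate)]
  out <- m[score >= score_min,
           .(chrom, pos, ref, alt, score,
             tvaf = alt_count_t / depth_t, nvaf = alt_count_n / depth_n,
             tumor_depth = depth_t, normal_depth = depth_n)]
  out <- unique(out, by = c("chrom", "pos", "ref", "alt"))
  setorder(out, chrom, pos, ref, alt)
  out[]
}

#' Filter variants against a panel of normals
#'
#' Removes variants observed in more than `max_hits` panel genomes; a site
#' absent from the panel counts as 0 hits.  The removed set is attached as
#' attribute `"removed"`.
#'
#' @param variants variant `data.table` with `chrom,pos,ref,alt` columns.
#' @param panel `data.table(chrom,pos,ref,alt,hits)` (see [simulate_panel()]);
#'   `panel_size` column or attribute is carried through if present.
#' @param max_hits maximum tolerated panel genomes carrying the variant
#'   (default 0: any panel hit removes the variant).
#' @return the retained variants with a `panel_hits` column.
#' @export
filter_against_panel <- function(variants, panel, max_hits = 0L) {
  v <- copy(as.data.table(variants))
  p <- as.data.table(panel)
  v[, panel_hits := 0L]
  if (nrow(p) > 0) {
    v[p, panel_hits := i.hits, on = c("chrom", "pos", "ref", "alt")]
  }
  kept <- v[panel_hits <= max_hits]
  removed <- v[panel_hits > max_hits]
  setattr(kept, "removed", removed)
  kept[]
}

#' Annotate coding effect of small variants
#'
#' SNVs falling in an exon are classified by codon translation
#' (synonymous / nonsynonymous / stopgain), indels by length modulo 3
#' (frameshift / inframe); everything else is non-coding.  Requires gene
#' models carrying a spliced coding sequence (`cds`); models without one
#' (e.g. from BED12) yield `nonsynonymous`-blind exonic classification and
#' are reported as `coding-unresolved`.
#'
#' @param variants `data.table` with `chrom,pos,ref,alt`.
#' @param models a [gene_models] object.
#' @return copy of `variants` with `gene` and `annotation` columns.
#' @export
annotate_coding <- function(variants, models) {
  v <- copy(as.data.table(variants))
  if (any(v$ref == v$alt)) stop("variant allele equals reference")
  ex <- models$exons
  v[, `:=`(gene = NA_character_, annotation = "non-coding")]
  for (i in seq_len(nrow(v))) {
    hit <- ex[chrom == v$chrom[i] & start < v$pos[i] & v$pos[i] <= end]
    if (nrow(hit) == 0) next
    gname <- hit$gene[1]
    v[i, gene := gname]
    ref <- v$ref[i]; alt <- v$alt[i]
    if (nchar(ref) != nchar(alt)) {
      v[i, annotation := if ((abs(nchar(ref) - nchar(alt)) %% 3) != 0)
        "frameshift" else "inframe"]
      next
    }
    g <- models$genes[gene == gname]
    if (is.na(g$cds)) { v[i, annotation := "coding-unresolved"]; next }
    idx0 <- genome_to_cds(models, gname, v$pos[i])
    if (is.na(idx0)) next
    ref_c <- if (g$strand == "+") ref else complement_base(ref)
    alt_c <- if (g$strand == "+") alt else complement_base(alt)
    codon_i <- idx0 %/% 3L
    codon <- substr(g$cds, codon_i * 3 + 1, codon_i * 3 + 3)
    if (substr(codon, idx0 %% 3L + 1, idx0 %% 3L + 1) != ref_c) {
      # reference mismatch against the model: trust the model's codon
      substr(codon, idx0 %% 3L + 1, idx0 %% 3L + 1) <- ref_c
    }
    mcodon <- codon
    substr(mcodon, idx0 %% 3L + 1, idx0 %% 3L + 1) <- alt_c
    aa_ref <- translate_codon(codon)
    aa_alt <- translate_codon(mcodon)
    ann <- if (aa_alt == aa_ref) "synonymous"
      else if (aa_alt == "*") "stopgain"
      else "nonsynonymous"
    v[i, annotation := ann]
  }
  v[]
}

#' Nonsynonymous mutation rate per megabase
#'
#' @param n_nonsyn number of (validated) nonsynonymous mutations.
#' @param footprint_mb interrogated footprint in Mb (the coding or callable
#'   territory the count was made over); must be > 0.
#' @return mutations per Mb.
#' @export
mutation_rate_per_mb <- function(n_nonsyn, footprint_mb) {
  if (any(footprint_mb <= 0)) stop("footprint must be > 0")
  n_nonsyn / footprint_mb
}
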
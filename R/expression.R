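# DNA-RNA integration: RPKM, mutant-allele transcript fraction, and the
# expressed-driver classification.

#' Reads per kilobase of exon per million mapped reads
#'
#' @param reads gene read count.
#' @param exon_length total exon length in bp (> 0).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return `1e9 * reads / (exon_length * total_mapped)`.
#' @export
rpkm <- function(reads, exon_length, total_mapped) {
  if (any(exon_length <= 0) || any(total_mapped <= 0)) {
    stop("exon_length and total_mapped must be > 0")
  }
  1e9 * reads / (exon_length * total_mapped)
}

#' Mutant-allele transcript fraction at a site
#'
#' @param variant_reads,total_reads RNA read counts at the mutant position.
#' @param min_site_depth minimum site depth for a defined fraction
#'   (default 5); below it the fraction is NA.
#' @return numeric vector (NA where depth is insufficient).
#' @export
mutant_fraction <- function(variant_reads, total_reads, min_site_depth = 5) {
  ifelse(total_reads >= min_site_depth, variant_reads / total_reads,
         NA_real_)
}

#' Build a per-gene, per-sample expression report
#'
#' Combines gene-level RNA counts (RPKM) with site-level mutant allele counts
#' into the table consumed by [classify_driver_candidates()].
#'
#' @param gene_counts `data.table(gene, sample, reads, exon_length,
#'   total_mapped)`.
#' @param site_counts `data.table(gene, sample, alt_count, depth)`, one
#'   mutant site per mutated gene (extra columns are kept).
#' @param min_site_depth passed to [mutant_fraction()].
#' @return `data.table(gene, sample, rpkm_value, fraction)`; genes without a
#'   mutant site have NA fractions.
#' @export
expression_report <- function(gene_counts, site_counts, min_site_depth = 5) {
  gc <- as.data.table(gene_counts)
  sc <- as.data.table(site_counts)
  rep <- gc[, .(gene, sample,
                rpkm_value = rpkm(reads, exon_length, total_mapped))]
  fr <- sc[, .(fraction = mutant_fraction(alt_count, depth,
                                          min_site_depth)[1]),
           by = .(gene, sample)]
  out <- merge(rep, fr, by = c("gene", "sample"), all.x = TRUE)
  setorder(out, gene, sample)
  out[]
}

#' Classify mutated genes by expressed-driver evidence
#'
#' Per gene, across the required samples: `gene-not-expressed` when RPKM
#' falls below `rpkm_min` in any required sample; otherwise
#' `mutant-not-detected` when the fraction is 0 or undefined,
#' `expressed-low-fraction` when positive but not above `fraction_min`, and
#' `expressed-driver-candidate` when the fraction strictly exceeds
#' `fraction_min` (in all required samples under `mode = "all"`, in at least
#' one under `mode = "any"`).
#'
#' @param report output of [expression_report()] (columns `gene`, `sample`,
#'   `rpkm_value`, `fraction`).
#' @param rpkm_min detectable-expression threshold (default 1 RPKM).
#' @param fraction_min driver mutant-fraction threshold (default 0.30,
#'   strict `>`).
#' @param required_samples samples the rule is evaluated over; all must be
#'   present for every gene.
#' @param mode `"all"` (default) or `"any"`: quantifier for the fraction
#'   condition across required samples.
#' @return `data.table(gene, class)` plus per-sample RPKM/fraction summary
#'   columns (`min_rpkm`, `min_fraction`, `max_fraction`).
#' @export
classify_driver_candidates <- function(report, rpkm_min = 1,
                                       fraction_min = 0.30,
                                       required_samples,
                                       mode = c("all", "any")) {
  mode <- match.arg(mode)
  r <- as.data.table(report)[sample %in% required_samples]
  chk <- r[, .N, by = gene]
  if (any(chk$N < length(required_samples))) {
    stop("required sample(s) absent for gene(s): ",
         paste(chk[N < length(required_samples), gene], collapse = ", "))
  }
  out <- r[, {
    fr <- fraction
    cls <- if (any(rpkm_value < rpkm_min)) {
      "gene-not-expressed"
    } else if (all(is.na(fr) | fr == 0)) {
      "mutant-not-detected"
    } else {
      pass <- !is.na(fr) & fr > fraction_min
      hit <- if (mode == "all") all(pass) else any(pass)
      if (hit) "expressed-driver-candidate" else "expressed-low-fraction"
    }
    .(class = cls, min_rpkm = min(rpkm_value),
      min_fraction = suppressWarnings(min(fr, na.rm = TRUE)),
      max_fraction = suppressWarnings(max(fr, na.rm = TRUE)))
  }, by = gene]
  out[!is.finite(min_fraction), min_fraction := NA_real_]
  out[!is.finite(max_fraction), max_fraction := NA_real_]
  setorder(out, gene)
  out[]
}
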
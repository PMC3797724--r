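# Ultra-deep amplicon validation and temporal (shared vs private)
# classification of validated variants across the sample timeline.

#' Score a site present/absent under the deep-sequencing validation rule
#'
#' A site is present when it has strictly more than `min_reads` variant reads
#' AND a variant read fraction strictly above `min_fraction` (both
#' inequalities strict).  Zero total reads yields absent with a warning.
#' A Sanger observation (`sanger = TRUE`) is a direct presence/absence call
#' and bypasses the count rule: it is present iff `variant_count > 0`.
#'
#' @param variant_count,total_count integer vectors of amplicon read counts.
#' @param min_reads minimum variant reads (exclusive; default 5).
#' @param min_fraction minimum variant read fraction (exclusive; default 0.01).
#' @param sanger logical vector; TRUE marks Sanger observations.
#' @return logical vector: TRUE = present.
#' @export
validate_site <- function(variant_count, total_count, min_reads = 5,
                          min_fraction = 0.01, sanger = FALSE) {
  stopifnot(all(variant_count >= 0), all(variant_count <= total_count))
  sanger <- rep_len(sanger, length(variant_count))
  if (any(total_count == 0 & !sanger)) {
    warning("zero total reads at ", sum(total_count == 0 & !sanger),
            " site(s); scored absent")
  }
  deep <- total_count > 0 & variant_count > min_reads &
    variant_count / total_count > min_fraction
  ifelse(sanger, variant_count > 0, deep)
}

#' Classify validated variants along the sample timeline
#'
#' A site is `shared` when present in the index sample and in every early
#' sample; `private-to-index` when present in the index only; `partial` when
#' present in the index and a strict non-empty subset of the early samples;
#' `unvalidated` when absent from the index.
#'
#' @param validations `data.table(chrom, pos, ref, alt, sample, present)`
#'   (logical `present`), or with `variant_count`/`total_count` columns, in
#'   which case [validate_site()] is applied first.  Every site must be
#'   observed in every listed sample.
#' @param index_sample name of the index (latest) sample.
#' @param early_samples character vector of earlier samples (diagnostic
#'   metastasis and primary-tumor sections).
#' @param ... passed to [validate_site()] when presence must be computed.
#' @return `data.table(chrom, pos, ref, alt, label, n_early_present)` with a
#'   `summary` attribute (counts and fractions per label).
#' @export
classify_timeline <- function(validations, index_sample, early_samples, ...) {
  v <- copy(as.data.table(validations))
  if (!"present" %in% names(v)) {
    stopifnot(all(c("variant_count", "total_count") %in% names(v)))
    v[, present := validate_site(variant_count, total_count, ...)]
  }
  samples <- c(index_sample, early_samples)
  obs <- v[sample %in% samples,
           .(n_obs = .N), by = .(chrom, pos, ref, alt)]
  gaps <- obs[n_obs < length(samples)]
  if (nrow(gaps) > 0) {
    stop("missing sample observations at ", nrow(gaps), " site(s), e.g. ",
         gaps[1, paste(chrom, pos, ref, alt, sep = ":")])
  }
  res <- v[sample %in% samples, {
    idx <- present[sample == index_sample]
    ne <- sum(present[sample %in% early_samples])
    lab <- if (!idx) "unvalidated"
      else if (ne == length(early_samples)) "shared"
      else if (ne == 0) "private-to-index"
      else "partial"
    .(label = lab, n_early_present = ne)
  }, by = .(chrom, pos, ref, alt)]
  setorder(res, chrom, pos, ref, alt)
  validated <- res[label != "unvalidated"]
  smry <- list(
    n_sites = nrow(res),
    n_validated = nrow(validated),
    n_shared = sum(res$label == "shared"),
    n_private = sum(res$label == "private-to-index"),
    n_partial = sum(res$label == "partial"),
    shared_fraction = if (nrow(validated)) {
      sum(res$label == "shared") / nrow(validated)
    } else NA_real_)
  setattr(res, "summary", smry)
  res[]
}

#' Orthogonal validation accuracy
#'
#' @param candidates number of candidate mutations submitted to validation
#'   (> 0).
#' @param confirmed number confirmed (<= candidates).
#' @return confirmed / candidates.
#' @export
validation_accuracy <- function(candidates, confirmed) {
  if (any(candidates <= 0)) stop("candidates must be > 0")
  if (any(confirmed > candidates) || any(confirmed < 0)) {
    stop("confirmed must lie in [0, candidates]")
  }
  confirmed / candidates
}
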
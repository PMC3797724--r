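# Coverage log-ratios, segmentation, lesser allele fraction, LOH/gain/loss
# flags and fine-scale focal deletion mapping.

#' Windowed tumor/normal coverage log-ratio
#'
#' `ratio = log2[(tumor_w / tumor_total) / (normal_w / normal_total)]`; the
#' total-coverage normalization makes the ratio relative to the genome-wide
#' average ploidy of the tumor, the usual read-count identifiability limit.
#' Windows whose normal coverage falls below `min_normal` are masked (NA).
#'
#' @param tumor,normal coverage tables `data.table(chrom, start, end,
#'   coverage)` over identical windows (0-based half-open).
#' @param min_normal masking floor on normal coverage (default 10).
#' @return `data.table(chrom, start, end, tumor_cov, normal_cov, ratio)`.
#' @export
windowed_log_ratio <- function(tumor, normal, min_normal = 10) {
  tu <- as.data.table(tumor); no <- as.data.table(normal)
  m <- merge(tu[, .(chrom, start, end, tumor_cov = coverage)],
             no[, .(chrom, start, end, normal_cov = coverage)],
             by = c("chrom", "start", "end"))
  tt <- sum(m$tumor_cov * (m$end - m$start))
  nt <- sum(m$normal_cov * (m$end - m$start))
  if (tt <= 0 || nt <= 0) stop("zero total coverage")
  m[, ratio := log2((tumor_cov / tt) / (normal_cov / nt))]
  m[normal_cov < min_normal | !is.finite(ratio), ratio := NA_real_]
  setorder(m, chrom, start)
  m[]
}

#' Segment coverage log-ratios chromosome by chromosome
#'
#' Runs [cbs_segment()] on the per-chromosome ratio series and summarizes
#' segment means.  An optional purity converts the (relative) ratio into an
#' integer copy-number estimate under a diploid-normal assumption:
#' `cn = (2 * 2^ratio - 2 * (1 - purity)) / purity`, reported alongside the
#' raw mean ratio.
#'
#' @param windows output of [windowed_log_ratio()].
#' @param alpha,n_perm CBS split significance parameters.
#' @param purity optional tumor purity for copy-number integerization.
#' @return `data.table(chrom, start, end, n_windows, mean_ratio, cn)`.
#' @export
segment_log_ratios <- function(windows, alpha = 0.01, n_perm = 1000,
                               purity = NULL) {
  w <- as.data.table(windows)
  segs <- w[, {
    ok <- which(is.finite(ratio))
    if (length(ok) == 0) {
      data.table(start = integer(), end = integer(),
                 n_windows = integer(), mean_ratio = numeric())
    } else {
      r <- ratio[ok]
      bps <- cbs_segment(r, alpha = alpha, n_perm = n_perm)
      cuts <- c(0L, bps, length(r))
      rbindlist(lapply(seq_len(length(cuts) - 1L), function(k) {
        idx <- ok[(cuts[k] + 1L):cuts[k + 1L]]
        data.table(start = start[idx[1]], end = end[idx[length(idx)]],
                   n_windows = length(idx), mean_ratio = mean(ratio[idx]))
      }))
    }
  }, by = chrom]
  if (!is.null(purity)) {
    segs[, cn := as.integer(round((2 * 2^mean_ratio - 2 * (1 - purity)) /
                                    purity))]
  } else {
    segs[, cn := as.integer(round(2 * 2^mean_ratio))]
  }
  setorder(segs, chrom, start)
  segs[]
}

#' Per-segment lesser allele fraction
#'
#' Site LAF = min(a, b) / (a + b) at germline-heterozygous sites (zero-depth
#' sites skipped); segment LAF = mean over the sites it contains, NA when a
#' segment holds no usable site.
#'
#' @param hets `data.table(chrom, pos, a_count, b_count)` for one tumor
#'   sample.
#' @param segments segment table with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return copy of `segments` with `laf` and `n_hets` columns.
#' @export
lesser_allele_fraction <- function(hets, segments) {
  h <- as.data.table(hets)
  segs <- copy(as.data.table(segments))
  h <- h[a_count + b_count > 0]
  h[, laf := pmin(a_count, b_count) / (a_count + b_count)]
  hq <- h[, .(chrom, start = pos - 1L, end = pos, laf)]
  sq <- copy(segs)[, segment_id := .I]
  setkey(sq, chrom, start, end)
  ov <- foverlaps(hq, sq[, .(chrom, start, end, segment_id)],
                  type = "within", nomatch = NULL)
  agg <- ov[, .(laf = mean(laf), n_hets = .N), by = segment_id]
  segs[, `:=`(laf = NA_real_, n_hets = 0L)]
  segs[agg$segment_id, `:=`(laf = agg$laf, n_hets = agg$n_hets)]
  segs[]
}

#' Flag LOH, gain and loss on segments
#'
#' Flags are independent, so copy-neutral LOH (low LAF at ratio ~0) is
#' representable.
#'
#' @param segments segment table with `mean_ratio` and `laf` columns.
#' @param laf_threshold LOH when segment LAF < this (default 0.15).
#' @param gain_threshold,loss_threshold log2-ratio thresholds
#'   (defaults +0.3 / -0.3).
#' @return copy of `segments` with logical `loh`, `gain`, `loss` columns.
#' @export
call_loh_and_events <- function(segments, laf_threshold = 0.15,
                                gain_threshold = 0.3,
                                loss_threshold = -0.3) {
  segs <- copy(as.data.table(segments))
  segs[, `:=`(loh = !is.na(laf) & laf < laf_threshold,
              gain = mean_ratio >= gain_threshold,
              loss = mean_ratio <= loss_threshold)]
  segs[]
}

#' Detect a focal deletion at fine scale
#'
#' Aggregates base- or fine-window coverage into coarse windows, segments the
#' log-ratios with CBS, and calls a deletion when an internal segment sits
#' lower than both flanking segments by at least `min_drop` log2 units.  With
#' base-resolution input, each breakpoint is then sharpened to the base by a
#' maximal-t change-point scan in its neighbourhood.
#'
#' @param cov either base-level coverage `data.table(chrom, pos, tumor,
#'   normal)` (see [simulate_base_coverage()]) or windowed coverage
#'   `data.table(chrom, start, end, tumor, normal)` with windows <= 1 kb.
#' @param models optional [gene_models] object (or NULL); when given, the
#'   affected exon ordinals (transcription order) of the gene overlapping the
#'   call are reported.
#' @param gene_name gene to annotate against (default: the first gene on the
#'   covered chromosome).
#' @param min_drop minimum log2 drop below both flanks (default 0.3; the
#'   noiseless drop of a 4-to-3 copy hemizygous loss is ~0.415 at full
#'   purity, ~0.39 at 90% purity).
#' @param coarse_window aggregation width for the CBS pass (default 500 bp).
#' @param alpha,n_perm CBS split significance parameters.
#' @return `NULL` when no deletion is found, else a list with `chrom`,
#'   `start`, `end` (1-based, end exclusive so length = end - start),
#'   `length`, `drop` (observed log2 drop), `exons` (affected exon ordinals)
#'   and `segments` (the coarse segment table).
#' @export
detect_focal_deletion <- function(cov, models = NULL, gene_name = NULL,
                                  min_drop = 0.3, coarse_window = 500,
                                  alpha = 0.01, n_perm = 1000) {
  cv <- as.data.table(cov)
  base_level <- "pos" %in% names(cv)
  if (base_level) {
    setorder(cv, pos)
    pos0 <- cv$pos[1]
    cv[, window_id := (pos - pos0) %/% as.integer(coarse_window)]
    agg <- cv[, .(tumor = sum(tumor), normal = sum(normal),
                  start = pos0 + window_id[1] * coarse_window),
              by = window_id]
    call_chrom <- cv$chrom[1]
  } else {
    setorder(cv, start)
    pos0 <- cv$start[1] + 1L
    coarse_window <- as.integer(stats::median(cv$end - cv$start))
    agg <- cv[, .(tumor, normal, start = start + 1L, window_id = .I - 1L)]
    call_chrom <- cv$chrom[1]
  }
  if (nrow(agg) < 3) stop("region shorter than 3 fine windows")
  tt <- sum(agg$tumor); nt <- sum(agg$normal)
  if (tt <= 0 || nt <= 0) stop("zero total coverage")
  agg[, ratio := log2(((tumor + 0.5) / tt) / ((normal + 0.5) / nt))]

  bps <- cbs_segment(agg$ratio, alpha = alpha, n_perm = n_perm)
  if (length(bps) == 0) return(NULL)
  cuts <- c(0L, bps, nrow(agg))
  means <- vapply(seq_len(length(cuts) - 1L), function(k) {
    mean(agg$ratio[(cuts[k] + 1L):cuts[k + 1L]])
  }, numeric(1))
  K <- length(means)
  if (K < 3) return(NULL)
  cand <- which(vapply(2:(K - 1), function(k) {
    means[k] <= means[k - 1] - min_drop && means[k] <= means[k + 1] - min_drop
  }, logical(1))) + 1L
  if (length(cand) == 0) return(NULL)
  drops <- vapply(cand, function(k) {
    min(means[k - 1], means[k + 1]) - means[k]
  }, numeric(1))
  k <- cand[which.max(drops)]

  # segment k spans windows (cuts[k]+1):cuts[k+1]; boundary = first base
  # (1-based) right of the cut
  left_b <- pos0 + cuts[k] * coarse_window
  right_b <- pos0 + cuts[k + 1L] * coarse_window
  if (base_level) {
    refine <- function(boundary) {
      lo <- boundary - 2L * coarse_window
      hi <- boundary + 2L * coarse_window - 1L
      sl <- cv[pos >= lo & pos <= hi]
      if (nrow(sl) < 4) return(boundary)
      r <- log2((sl$tumor + 0.5) / (sl$normal + 0.5))
      b <- max_t_split(r)
      sl$pos[b] + 1L
    }
    left_b <- refine(left_b)
    right_b <- refine(right_b)
  }

  exons <- integer(0)
  if (!is.null(models)) {
    if (is.null(gene_name)) {
      on_chrom <- unique(models$exons[chrom == call_chrom, gene])
      gene_name <- if (length(on_chrom) >= 1) on_chrom[1] else NA_character_
    }
    if (!is.na(gene_name)) {
      ex <- models$exons[gene == gene_name]
      strand <- models$genes[gene == gene_name, strand]
      ord <- if (strand == "+") order(ex$start) else order(-ex$start)
      ex <- ex[ord]
      hit <- which(ex$start + 1L <= right_b - 1L & ex$end >= left_b)
      exons <- sort(hit)
    }
  }
  list(chrom = call_chrom, start = as.integer(left_b),
       end = as.integer(right_b),
       length = as.integer(right_b - left_b),
       drop = min(means[k - 1], means[k + 1]) - means[k],
       exons = exons,
       segments = data.table(chrom = call_chrom,
                             start = pos0 + head(cuts, -1) * coarse_window,
                             end = pos0 + tail(cuts, -1) * coarse_window,
                             mean_ratio = means))
}

#' Quick static copy-number overview plot
#'
#' Scatter of window log-ratios with segment means overlaid, one panel per
#' chromosome, written to a PNG when `file` is given.
#'
#' @param windows output of [windowed_log_ratio()].
#' @param segments output of [segment_log_ratios()].
#' @param file optional PNG path.
#' @return invisibly, the file path or NULL.
#' @export
plot_copy_number <- function(windows, segments, file = NULL) {
  w <- as.data.table(windows); s <- as.data.table(segments)
  chroms <- unique(w$chrom)
  if (!is.null(file)) png(file, width = 1200, height = 300 * length(chroms))
  op <- par(mfrow = c(length(chroms), 1), mar = c(2, 4, 2, 1))
  on.exit({ par(op); if (!is.null(file)) dev.off() }, add = TRUE)
  for (ch in chroms) {
    wi <- w[chrom == ch]
    plot((wi$start + wi$end) / 2e6, wi$ratio, pch = 16, cex = 0.4,
         col = "grey40", xlab = "", ylab = "log2 ratio", main = ch,
         ylim = range(w$ratio, na.rm = TRUE))
    si <- s[chrom == ch]
    segments(si$start / 1e6, si$mean_ratio, si$end / 1e6, si$mean_ratio,
             col = "red", lwd = 2)
    abline(h = 0, lty = 3)
  }
  invisible(file)
}
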
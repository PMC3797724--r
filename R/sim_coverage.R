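# Coverage and heterozygous-site generators for copy-number / LAF analysis.

SIM_READ_LEN <- 50  # bp per sequenced read; sets the counting noise scale

check_region <- function(cfg, chrom, start, end) {
  len <- cfg$genome$length[cfg$genome$chrom == chrom]
  if (length(len) != 1 || start < 0 || end > len || end <= start) {
    stop("region ", chrom, ":", start, "-", end, " outside genome bounds")
  }
  invisible(TRUE)
}

#' Simulate windowed coverage and heterozygous-site allele counts
#'
#' Tumor window coverage is proportional to the purity-weighted local copy
#' number mixture; the normal is diploid everywhere.  Germline heterozygous
#' sites are planted at a configurable mean spacing, with tumor allele counts
#' reflecting allele-specific copy number (which parental allele is the
#' lesser one is randomized per site, as in unphased data).
#'
#' @param config a [sim_config] object.
#' @param window window width in bp (default 100000); a final partial window
#'   is emitted with `partial = TRUE`.
#' @param region optional `list(chrom, start, end)` (0-based half-open) to
#'   restrict output; errors if outside genome bounds.
#' @return list with `windows` (`chrom,start,end,sample,coverage,partial`)
#'   and `hets` (`chrom,pos,sample,a_count,b_count`).
#' @export
simulate_coverage_laf <- function(config, window = 100000, region = NULL) {
  cfg <- config
  stopifnot(window > 0)
  genome <- cfg$genome
  if (!is.null(region)) {
    check_region(cfg, region$chrom, region$start, region$end)
    genome <- data.table(chrom = region$chrom, length = region$end)
  }

  win <- rbindlist(lapply(seq_len(nrow(genome)), function(i) {
    lo <- if (!is.null(region)) region$start else 0
    starts <- seq(lo, genome$length[i] - 1, by = window)
    data.table(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + window, genome$length[i]))
  }))
  win[, partial := (end - start) < window]

  pp <- copy(cfg$ploidy_profile)
  setkey(pp, chrom, start, end)
  # expected mixture per window = length-weighted mean of overlapping states
  wq <- copy(win)[, wid := .I]
  ov <- foverlaps(wq, pp, type = "any", nomatch = NULL)
  ov[, olap := pmin(end, i.end) - pmax(start, i.start)]

  samples <- cfg$samples
  windows <- rbindlist(lapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample[i]
    is_tumor <- samples$role[i] == "tumor"
    p <- if (is_tumor) samples$purity[i] else 0
    wmix <- ov[, sum(olap * mixture_cn(cn, p)) / sum(olap), by = wid]
    mix <- rep(2, nrow(win))
    if (is_tumor) mix[wmix$wid] <- wmix$V1
    run_seeded(substream(cfg$seed, paste0("coverage:", s)), function() {
      mu <- cfg$dna_depth * (mix / 2) * (win$end - win$start) / SIM_READ_LEN
      n_reads <- rpois(nrow(win), mu)
      data.table(chrom = win$chrom, start = win$start, end = win$end,
                 sample = s,
                 coverage = n_reads * SIM_READ_LEN / (win$end - win$start),
                 partial = win$partial)
    })
  }))

  het_pos <- run_seeded(substream(cfg$seed, "hets"), function() {
    rbindlist(lapply(seq_len(nrow(genome)), function(i) {
      lo <- if (!is.null(region)) region$start else 0
      n <- max(1, floor((genome$length[i] - lo) / cfg$het_spacing))
      pos <- sort(floor(runif(n, lo, genome$length[i])) + 1L)
      data.table(chrom = genome$chrom[i], pos = as.integer(pos),
                 flip = runif(n) < 0.5)
    }))
  })
  hp <- ploidy_at(cfg$ploidy_profile, het_pos$chrom, het_pos$pos - 1L)

  hets <- rbindlist(lapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample[i]
    is_tumor <- samples$role[i] == "tumor"
    p <- if (is_tumor) samples$purity[i] else 0
    mix <- if (is_tumor) mixture_cn(hp$cn, p) else rep(2, nrow(het_pos))
    f_minor <- if (is_tumor) (p * hp$minor + (1 - p)) / mix else
      rep(0.5, nrow(het_pos))
    run_seeded(substream(cfg$seed, paste0("hets:", s)), function() {
      depth <- rpois(nrow(het_pos), cfg$dna_depth * mix / 2)
      b <- rbinom(nrow(het_pos), depth, f_minor)
      a <- depth - b
      swap <- het_pos$flip
      data.table(chrom = het_pos$chrom, pos = het_pos$pos, sample = s,
                 a_count = ifelse(swap, b, a), b_count = ifelse(swap, a, b))
    })
  }))
  list(windows = windows, hets = hets)
}

#' Simulate base-resolution coverage over a region
#'
#' Per-base read depth for one tumor sample and the matched normal, used for
#' fine-scale focal-deletion mapping.
#'
#' @param config a [sim_config] object.
#' @param sample tumor sample name.
#' @param chrom,start,end region (1-based `start`, `end` exclusive).
#' @return `data.table(chrom, pos, tumor, normal)`, one row per base.
#' @export
simulate_base_coverage <- function(config, sample, chrom, start, end) {
  cfg <- config
  check_region(cfg, chrom, start - 1, end - 1)
  srow <- as.data.frame(cfg$samples)
  srow <- srow[srow$sample == sample, ]
  if (nrow(srow) != 1 || srow$role != "tumor") {
    stop("'sample' must name a tumor sample")
  }
  p <- srow$purity
  pos <- seq.int(start, end - 1L)
  pl <- ploidy_at(cfg$ploidy_profile, rep(chrom, length(pos)), pos - 1L)
  mix <- mixture_cn(pl$cn, p)
  run_seeded(substream(cfg$seed,
                       paste("basecov", sample, chrom, start, end, sep = ":")),
             function() {
    data.table(chrom = chrom, pos = pos,
               tumor = rpois(length(pos), cfg$dna_depth * mix / 2),
               normal = rpois(length(pos), cfg$dna_depth))
  })
}
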
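# Structural junction generator: a dense cluster inside the chromothripsis
# region (index tumor only) plus one deletion-type junction spanning the focal
# deletion breakpoints in every tumor sample.

# Orientation conventions (same-chromosome, left <= right):
#   +/- spanning a gap  -> deletion
#   -/+                 -> tandem-duplication
#   +/+ or -/-          -> inversion
junction_strands <- list(
  "deletion" = c("+", "-"),
  "tandem-duplication" = c("-", "+"),
  "inversion" = c("+", "+"))

#' Simulate structural junctions
#'
#' Junction endpoints are uniform within the configured chromothripsis region
#' with types drawn from deletion / tandem-duplication / inversion; these are
#' emitted for the index tumor (Met2).  One deletion-type junction spanning
#' exactly the focal-deletion breakpoints is emitted for every tumor sample.
#'
#' @param config a [sim_config] object.
#' @return `data.table(sample, chrom1, pos1, strand1, chrom2, pos2, strand2,
#'   type, confidence)`.
#' @export
simulate_junctions <- function(config) {
  cfg <- config
  ct <- cfg$chromothripsis
  fd <- cfg$focal_deletion
  n <- ct$n_junctions
  if (n < 0) stop("n_junctions must be >= 0")
  if (n > 0 && (ct$end - ct$start) < 10 * n) {
    stop("chromothripsis region too small for ", n, " junctions")
  }
  tumors <- cfg$samples[role == "tumor", sample]
  index <- if ("Met2" %in% tumors) "Met2" else tumors[length(tumors)]

  fdel <- data.table(sample = tumors, chrom1 = fd$chrom,
                     pos1 = as.integer(fd$start), strand1 = "+",
                     chrom2 = fd$chrom, pos2 = as.integer(fd$end),
                     strand2 = "-", type = "deletion", confidence = "high")
  if (n == 0) return(fdel[])

  shatter <- run_seeded(substream(cfg$seed, "junctions"), function() {
    a <- floor(runif(n, ct$start, ct$end)) + 1L
    b <- floor(runif(n, ct$start, ct$end)) + 1L
    lo <- pmin(a, b); hi <- pmax(a, b)
    types <- sample(names(junction_strands), n, replace = TRUE)
    s1 <- vapply(types, function(t) junction_strands[[t]][1], character(1))
    s2 <- vapply(types, function(t) junction_strands[[t]][2], character(1))
    inv_flip <- types == "inversion" & runif(n) < 0.5
    s1[inv_flip] <- "-"; s2[inv_flip] <- "-"
    data.table(sample = index, chrom1 = ct$chrom, pos1 = as.integer(lo),
               strand1 = s1, chrom2 = ct$chrom, pos2 = as.integer(hi),
               strand2 = s2, type = types, confidence = "high")
  })
  res <- rbind(fdel, shatter)
  setorder(res, sample, chrom1, pos1)
  res[]
}
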
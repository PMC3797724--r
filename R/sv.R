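# Structural junction typing and chromothripsis-like region scoring.

#' Type a structural junction from its endpoint orientations
#'
#' Intra-chromosomal junctions (left <= right): `+/-` spanning a gap is a
#' deletion, `-/+` a tandem-duplication, equal orientations an inversion;
#' endpoints on different chromosomes are interchromosomal.
#'
#' @param chrom1,pos1,strand1 left endpoint (vectors recycled to a common
#'   length).
#' @param chrom2,pos2,strand2 right endpoint.
#' @return character vector of junction types.
#' @export
type_junction <- function(chrom1, pos1, strand1, chrom2, pos2, strand2) {
  n <- max(length(chrom1), length(chrom2), length(pos1), length(pos2))
  chrom1 <- rep_len(chrom1, n); chrom2 <- rep_len(chrom2, n)
  strand1 <- rep_len(as.character(strand1), n)
  strand2 <- rep_len(as.character(strand2), n)
  if (!all(c(strand1, strand2) %in% c("+", "-"))) {
    stop("unknown orientation code (expected '+'/'-')")
  }
  ifelse(chrom1 != chrom2, "interchromosomal",
         ifelse(strand1 == strand2, "inversion",
                ifelse(strand1 == "+", "deletion", "tandem-duplication")))
}

#' Score a region for chromothripsis-like evidence
#'
#' Evidence is (i) a high density of clustered junctions, (ii) few major
#' copy-number states, and (iii) oscillation between the two most prevalent
#' states.  Major states are found by rounding segment log2 ratios to the
#' nearest 0.5 bin and keeping bins covering at least 10% of the region
#' length; oscillations count adjacent-segment alternations between the two
#' most prevalent states.
#'
#' @param junctions junction table (`chrom1,pos1,chrom2,pos2,...`); a
#'   junction is counted when both endpoints fall inside the region.
#' @param segments segment table with `chrom`, `start`, `end`, `mean_ratio`
#'   covering the region.
#' @param region list `(chrom, start, end)` (0-based half-open).
#' @param min_junctions_per_mb junction-count threshold per Mb of region
#'   (default 10; the verdict requires `count >= threshold * region_Mb`).
#' @param max_states maximum number of major copy-number states (default 2).
#' @param min_oscillations minimum state alternations (default 5).
#' @param state_bin,state_floor bin width (log2) and minimum fraction of the
#'   region a bin must cover to count as a major state.
#' @return one-row `data.table`: region, `n_junctions`, `density_per_mb`,
#'   `n_states`, `oscillations`, `verdict`.
#' @export
score_chromothripsis <- function(junctions, segments, region,
                                 min_junctions_per_mb = 10,
                                 max_states = 2L, min_oscillations = 5L,
                                 state_bin = 0.5, state_floor = 0.1) {
  if (region$end <= region$start) stop("empty region")
  j <- as.data.table(junctions)
  n_j <- if (nrow(j) == 0) 0L else j[
    chrom1 == region$chrom & chrom2 == region$chrom &
      pos1 > region$start & pos1 <= region$end &
      pos2 > region$start & pos2 <= region$end, .N]
  mb <- (region$end - region$start) / 1e6
  density <- n_j / mb

  s <- as.data.table(segments)[chrom == region$chrom & end > region$start &
                                 start < region$end]
  if (nrow(s) == 0) stop("segments do not cover the region")
  s <- copy(s)
  s[, `:=`(start = pmax(start, region$start), end = pmin(end, region$end))]
  setorder(s, start)
  s[, state := round(mean_ratio / state_bin) * state_bin]
  cover <- s[, .(len = sum(end - start)), by = state]
  major <- cover[len >= state_floor * (region$end - region$start)]
  setorder(major, -len)
  n_states <- nrow(major)

  osc <- 0L
  if (n_states >= 2) {
    top2 <- major$state[1:2]
    st <- s$state[s$state %in% top2]
    if (length(st) >= 2) osc <- sum(diff(match(st, top2)) != 0)
  }
  verdict <- n_j >= min_junctions_per_mb * mb &&
    n_states <= max_states && osc >= min_oscillations
  data.table(chrom = region$chrom, start = region$start, end = region$end,
             n_junctions = n_j, density_per_mb = density,
             n_states = n_states, oscillations = as.integer(osc),
             verdict = verdict)
}
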
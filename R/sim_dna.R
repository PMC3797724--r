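# DNA-level generators: per-site pileup counts and the panel of normals.

# Catalog of interrogated sites: planted somatic mutations, recurrent
# platform-artifact sites, and error-only sites used to measure specificity.
sim_site_catalog <- function(cfg) {
  truth <- truth_table(cfg)
  muts <- truth$mutations[, .(chrom, pos, ref, alt)]
  muts[, kind := "mutation"]

  extra <- run_seeded(substream(cfg$seed, "sites"), function() {
    n <- cfg$n_error_sites + cfg$n_artifact_sites
    ch <- sample(cfg$genome$chrom, n, replace = TRUE,
                 prob = cfg$genome$length)
    len <- cfg$genome$length[match(ch, cfg$genome$chrom)]
    pos <- floor(runif(n) * len) + 1
    ref <- sample(DNA_BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                  character(1))
    data.table(chrom = ch, pos = as.integer(pos), ref = ref, alt = alt,
               kind = c(rep("artifact", cfg$n_artifact_sites),
                        rep("error", cfg$n_error_sites)))
  })
  sites <- rbind(muts, extra)
  sites <- unique(sites, by = c("chrom", "pos"))
  setorder(sites, chrom, pos)
  sites[]
}

#' Simulate per-site pileup tables for every sample
#'
#' Draws sequencing depth Poisson around the configured mean (scaled by local
#' copy number and purity in tumors) and variant read counts binomially at the
#' true variant allele fraction plus the per-base error rate.  The normal
#' sample carries only error-level variant reads at somatic sites.  Besides
#' the planted mutations, the table interrogates error-only sites and a small
#' set of recurrent artifact sites (elevated non-reference rate in tumors)
#' that the panel of normals is designed to remove.
#'
#' @param config a [sim_config] object.
#' @return `data.table` with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `sample`, `ref_count`, `alt_count`, `depth`
#'   (`depth - ref_count - alt_count` = reads supporting the other two bases).
#' @export
simulate_dna_pileups <- function(config) {
  cfg <- config
  sites <- sim_site_catalog(cfg)
  truth <- truth_table(cfg)
  e <- cfg$error_rate

  pl <- ploidy_at(cfg$ploidy_profile, sites$chrom, sites$pos - 1L)
  site_cn <- pl$cn
  vaf_map <- truth$vafs
  sites[, site_id := paste(chrom, pos, ref, alt, sep = ":")]

  out <- lapply(seq_len(nrow(cfg$samples)), function(i) {
    s <- cfg$samples$sample[i]
    is_tumor <- cfg$samples$role[i] == "tumor"
    p <- if (is_tumor) cfg$samples$purity[i] else 0
    mix <- if (is_tumor) mixture_cn(site_cn, p) else rep(2, nrow(sites))
    f <- rep(0, nrow(sites))
    sv <- vaf_map[sample == s]
    f[match(sv$site_id, sites$site_id)] <- sv$vaf
    f[sites$kind == "artifact" & is_tumor] <- cfg$artifact_rate
    f_eff <- f + (1 - f) * e
    run_seeded(substream(cfg$seed, paste0("pileups:", s)), function() {
      depth <- rpois(nrow(sites), cfg$dna_depth * mix / 2)
      alt_n <- rbinom(nrow(sites), depth, f_eff)
      other <- rbinom(nrow(sites), depth - alt_n, 2 * e / 3)
      data.table(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                 alt = sites$alt, sample = s,
                 ref_count = depth - alt_n - other, alt_count = alt_n,
                 depth = depth)
    })
  })
  res <- rbindlist(out)
  setorder(res, chrom, pos, sample)
  res[]
}

#' Simulate a panel of normals
#'
#' Recurrent artifact sites are observed in a random subset of the panel
#' genomes (always at least one); true somatic sites are absent.
#'
#' @param config a [sim_config] object.
#' @return `data.table(chrom, pos, ref, alt, hits, panel_size)` -- a
#'   panel-of-normals site table usable with [filter_against_panel()].
#' @export
simulate_panel <- function(config) {
  cfg <- config
  sites <- sim_site_catalog(cfg)
  art <- sites[kind == "artifact"]
  run_seeded(substream(cfg$seed, "panel"), function() {
    art[, hits := 1L + rbinom(.N, cfg$panel_size - 1L, 0.25)]
  })
  art[, kind := NULL]
  art[, panel_size := cfg$panel_size]
  art[]
}
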
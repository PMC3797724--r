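# oncotrace

Longitudinal tumor genome and transcriptome analysis in R.

`oncotrace` is built for the study design in which one patient is sampled
repeatedly over the disease course — a diagnostic metastasis (**Met1**),
several sections of the resected primary tumor (**PT1–PT4**), a terminal
metastasis (**Met2**) and a germline control — and the questions are:

* which somatic small variants are real (paired tumor/normal likelihood
  score + panel-of-normals filtering + ultra-deep validation)?
* which of them were present since diagnosis (*shared*) and which arose
  *de novo* during treatment (*private to the index sample*)?
* what does the tumor genome look like — copy number, lesser allele
  fraction (LAF), LOH, focal deletions, chromothripsis-like shattering?
* which shared mutant genes actually **express** their mutant allele
  (the expressed-driver candidates), by integrating DNA calls with RNA?
* downstream of one candidate receptor mutation: which gene sets respond to
  ligand differently in mutant vs wild-type cells (CE/DCE ranking +
  gene-permutation enrichment)?

A seeded synthetic-data module emulates the whole study (clonal structure,
near-tetraploid genome with LOH and an oscillating two-state chromothripsis
region, a 15,727 bp focal deletion at canonical coordinates
`76916706–76932433`, RNA with planted mutant-allele fractions, and a
two-condition perturbation time course), so every stage runs end to end
with no download, and every estimate can be checked against a deterministic
`truth_table()`.

## The statistics at the core

* **Somatic score** — binomial log10 likelihood ratio
  `S = log10 [ L(tumor | m̂) L(normal | e) ] − log10 max[ L(both | 0.5), L(both | e) ]`,
  with `m̂` the tumor variant fraction floored at the error rate `e`.
  Default calling threshold 4 (per-site FPR ≈ 1e−5 at 100×, e = 0.01).
* **Deep-validation rule** — present ⇔ variant reads **> 5** and variant
  fraction **> 1%** (strict), then timeline classification into
  shared / private-to-index / partial.
* **CBS** — circular binary segmentation: maximal arc statistic on
  circularized partial sums, permutation significance (α = 0.01, 1,000
  permutations, early stopping), recursion, no undo.
* **LAF** — `min(a, b)/(a + b)` at germline-het sites; LOH ⇔ segment
  LAF < 0.15; gain/loss at ±0.3 log2.
* **RPKM** — `1e9 · reads/(exon_length · total_mapped)`; expressed-driver
  candidate ⇔ RPKM ≥ 1 and mutant transcript fraction > 30% in all
  required samples.
* **CE/DCE** — `CE_T = log2 X_T − log2 X_0`, `DCE_T = CE_mt,T − CE_wt,T`;
  weighted KS enrichment with a 10,000-fold gene-permutation null,
  sign-conditioned p-values, NES and pooled-null FDR.

## Worked example

```r
library(oncotrace)

cfg  <- sim_config(seed = 1)                       # the default stated world
pu   <- simulate_dna_pileups(cfg)
calls <- filter_against_panel(
  call_somatic(pu, tumor = "Met2", normal = "Normal"),
  simulate_panel(cfg))
calls <- annotate_coding(calls, cfg$gene_models)
nrow(calls)
#> [1] 45        # the 15 founder + 30 Met2-private planted mutations,
#>               # 0 false positives among 20,000 error-only sites

calls[1:3, .(chrom, pos, ref, alt, score = round(score, 1), gene, annotation)]
#>     chrom    pos ref alt score    gene    annotation
#> 1:   chr1 100021   G   T  27.7  LPAR1L nonsynonymous
#> 2:   chr1 344091   G   A  23.0  GATA2L nonsynonymous
#> 3:   chr1 580084   G   C  27.4 NUFIP1L nonsynonymous

# focal deletion from base-resolution coverage (planted 4 -> 3 copies)
bc  <- simulate_base_coverage(cfg, "Met2", "chrXs", 76890000, 76960000)
del <- detect_focal_deletion(bc, models = cfg$gene_models)
#> chrXs:76916706-76932435 (15729 bp, drop 0.38 log2), exons 10,11,12
#  (planted: 76916706-76932433, 15,727 bp, exons 10-12)

# expressed-driver integration over the 15 shared mutant genes
rna <- simulate_rna(cfg); tr <- truth_table(cfg)
shared <- tr$mutations[label == "founder", gene]
rep <- expression_report(rna$gene_counts[gene %in% shared],
                         rna$site_counts[gene %in% shared])
classify_driver_candidates(rep, required_samples = cfg$rna_samples)[
  class == "expressed-driver-candidate"]
#>       gene min_rpkm min_fraction   <- exactly the 3 planted high-fraction
#> 1:  GATA2L     28.3         0.47      genes; the 30%-rule separates them
#> 2:  LPAR1L     73.3         0.48      from low-fraction passengers
#> 3: NUFIP1L     25.0         0.40

# perturbation response: planted responsive set, 10,000 gene permutations
X <- simulate_perturbation_matrix(cfg)
gsea_permutation(rank_by_dce(X, 1),
                 list(RESPONSIVE = attr(X, "responsive_genes")),
                 n_perm = 10000, seed = 7)
#>           set size   ES  NES     pval FDR
#> 1: RESPONSIVE  100 0.91 3.87 0.00016   0
```

A command-line interface covers the same stages
(`simulate`, `call-somatic`, `validate`, `cnv`, `chromothripsis`,
`integrate`, `perturb-gsea`):

```sh
Rscript inst/cli/oncotrace simulate --outdir data/ --seed 1
Rscript inst/cli/oncotrace call-somatic --pileups data/pileups.tsv \
    --normal Normal --tumor Met2 --panel data/panel.tsv --out calls.vcf
```

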
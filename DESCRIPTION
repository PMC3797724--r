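Package: oncotrace
Title: Longitudinal Tumor Genome and Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Mara", "Jensen", email = "mara.jensen@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal multi-sample tumor sequencing studies:
    somatic small-variant calling from paired tumor/normal pileups with
    panel-of-normals filtering, ultra-deep amplicon validation and temporal
    (shared versus metastasis-private) classification, coverage-based copy
    number analysis with circular binary segmentation, lesser-allele-fraction
    and LOH calling, focal deletion detection at base resolution,
    chromothripsis-like region scoring, DNA-RNA integration to nominate
    expressed driver mutations, and a perturbation-response statistic with
    gene-permutation set enrichment. A seeded synthetic-data module emulates
    the clonal, copy-number and expression structure of a diagnosis /
    primary-tumor / relapse-metastasis sample series so the whole pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
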
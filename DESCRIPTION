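Package: mutclust
Title: Detection and Classification of Clustered Somatic Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects clustered somatic mutations in single-sample catalogs by
    calibrating a sample-dependent inter-mutational distance (IMD) threshold
    against a simulated background that preserves pentanucleotide sequence
    context, genic/intergenic ratios, transcriptional strand asymmetries and
    per-chromosome mutational burden. A regional correction adjusts the
    threshold in sliding megabase windows for local mutation-rate
    heterogeneity, and every clustered event is subclassified into
    doublet-base substitutions, multi-base substitutions, omikli, kataegis,
    clustered indels or other. Includes partitioned VCF output, rainfall
    plots, SBS-96 spectra and a synthetic-fixture generator with planted
    events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
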
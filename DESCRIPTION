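Package: methshift
Title: Screens and Quantification for Iron-Dependent Epigenetic
    Demethylation Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting iron-dependent epigenetic
    demethylation during adipocyte differentiation. Provides bedGraph/BED
    readers for per-CpG whole-genome bisulfite sequencing tracks, interval
    algebra for promoter and enhancer window construction, a coverage-filtered
    CpG demethylation screen with cross-condition contrasts, CPM/length
    normalisation and fuzzy c-means temporal clustering of ChIP-seq signal
    around transcription start sites with Dmin cluster-count diagnostics,
    DMR-anchored aggregation profiles of methylation and histone-signal
    change, closed-form assay quantifications (lysosomal flux, HTRF DF%,
    ChIP percent-input, bisulfite-clone summaries, pixel colocalization),
    and a seeded synthetic-data generator with planted ground truth that
    emulates the multi-condition, multi-timepoint study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
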
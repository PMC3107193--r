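Package: cisrobust
Title: Composition, Conservation and Robustness Analysis of Cis-Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for partitioning a promoter into its
    conserved proximal core and composition-biased distal portion, and for
    quantifying the robustness of reporter expression it drives. Provides
    k-mer composition profiling with reverse-complement class collapsing,
    baseline-relative dinucleotide enrichment, a trinucleotide
    nucleosome-depletion score, Vista-style sliding-window conservation
    profiling with conserved-block and boundary calling, genome tiling and
    candidate-fragment selection by AT-enrichment, nonparametric
    robustness statistics (cell-count consistency, intensity-ratio
    dispersion, centroid-distance scatter), and synthetic-data generators
    for sequences of prescribed dinucleotide composition and per-animal
    reporter-expression datasets with controllable overdispersion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
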
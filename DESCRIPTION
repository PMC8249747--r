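Package: gselexchip
Title: Simulation and Analysis of Genomic SELEX Tiling-Array Screens for
    Bacterial Transcription Factor Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse genomic SELEX (gSELEX) screens of
    bacterial transcription-factor binding read out on two-channel tiling
    arrays. Provides a synthetic-data engine (circular toy genomes with
    operons and intergenic spacers, affinity landscapes, fragment libraries,
    multiplicative selection cycles, clone sampling), tiling-probe design and
    hybridization to per-probe sample/reference ratios, peak calling by the
    consecutive-elevated-probe criterion, annotation of peaks to intergenic
    spacers and candidate regulated transcription units (including divergent
    promoters), classification of factors by regulon size (single-target,
    local, global, nucleoid-associated) and by TF-gene/target-gene
    organization (type-A adjacent versus type-B separated), IUPAC motif and
    palindrome search, and a packaged registry of the published single-target
    factors of Escherichia coli K-12.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
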
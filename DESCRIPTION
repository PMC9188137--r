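Package: geoseed
Title: Alignment Seed Finding and Geometric Hashing Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seed finding for pairwise and multi-genome sequence comparison
    and fast filters on the resulting alignment anchors. Implements exact
    contiguous k-mer seeds, single and multiple spaced-seed pattern matching
    with per-k-mer subsampling and repeat-mask/ambiguity filtering, the
    neighbouring-matches diagonal filter, and geometric hashing: candidate
    seeds are mapped to diagonal tiles, tiles are scored by a normalized
    p-norm over sub-tile chunks and thresholded, with a two-step
    (coarse-to-fine) variant and a generalization to more than two genomes.
    Includes the corresponding evaluation statistics (CDS-support
    sensitivity, extrapolated false-positive rate, Poisson zero-count
    bound, maximal exon offset) and a synthetic-data generator for i.i.d.
    random genome pairs and planted orthologous gene pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
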
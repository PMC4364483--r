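Package: regioncoloc
Title: Colocalization Analysis of Genomic Region Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how strongly a set of genomic regions of interest
    (typically ChIP-seq peaks) colocates with genomic feature tracks.
    Regions are profiled in a fixed 100-bin window around their centers
    using per-chromosome binned occupancy indexes; the resulting density
    matrix is collapsed to a doubly normalized colocation histogram from
    which a dynamic background level, colocation peak height,
    above-mean integral (AMI), below-mean integral (BMI), and an empirical
    permutation p-value are computed. Includes a seeded synthetic fixture
    generator for region/feature pairs with controlled spatial structure
    and a command-line driver for batch analysis of feature libraries.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
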
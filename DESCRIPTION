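Package: loopkit
Title: Import, Annotation and Summarisation of Chromatin Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with chromatin interaction data such as Hi-C
    and ChIA-PET: an anchor-pair container built on GenomicRanges, readers and
    writers for bedpe, bed12, HOMER and ChIA-PET-tool interaction tables,
    paired-tag preprocessing including positional-duplicate removal and
    self-ligation threshold estimation, priority-ordered anchor annotation and
    promoter-enhancer interaction classification, feature-level interaction
    summaries, virtual 4C viewpoint profiles, arc diagrams, a seeded synthetic
    data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
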
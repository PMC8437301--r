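Package: juncture
Title: Breakpoint-Junction Analysis of Genome Rearrangements in Non-Dividing Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-split-read calling of DNA breakpoint junctions from
    alignment files, with microhomology signature classification,
    simulation-based null models, binned hotspot ratio matrices and
    per-mapped-read ageing metrics (JPMR/IPMR). Includes a synthetic-data
    module that generates toy genomes, plants rearrangements with controlled
    breakpoint signatures and emits split-read alignment fixtures with truth
    tables, so the whole pipeline can be exercised end to end without
    external sequencing data.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    jsonlite,
    optparse
Encoding: UTF-8
Config/testthat/edition: 3
RoxygenNote: 7.3.3
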
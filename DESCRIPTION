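Package: tilecgh
Title: Ultra-High-Density Tiling CGH Probe Design and Deletion Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of isothermal, uniqueness-filtered, staggered oligonucleotide
    probe sets over a reference sequence for array comparative genomic
    hybridization (CGH); closed-form coverage geometry relating probe stagger,
    probe length and deletion size; simulation of per-probe log2(mutant/control)
    ratio profiles under an empirically motivated noise model; deletion and
    duplication calling by log2-ratio thresholding with consecutive-probe and
    feature-fraction rules; and Monte-Carlo estimation of the probe density
    required to detect deletions of a given size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
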
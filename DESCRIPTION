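Package: pingpongr
Title: Ping-Pong Signature Analysis for Fetal piRNA Small RNA-Seq Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies piRNA biogenesis defects from small RNA sequencing
    libraries. Implements hierarchical read classification (miRNA/ncRNA,
    exact-match genome mapping with unique assignment to piRNA clusters,
    gapless transposon-consensus mapping allowing two mismatches),
    per-million-miRNA normalization and WT/KO fold-change tables,
    1U/10A nucleotide bias, 5'-5' overlap-distance (ping-pong) histograms,
    and the adjacency analysis linking 16/19-nt slicer byproducts to 26/29-nt
    guide piRNAs. Includes a synthetic-data generator that emulates paired
    wild-type/knockout fetal testis libraries with configurable depletion
    profiles so every stage is testable without deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
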
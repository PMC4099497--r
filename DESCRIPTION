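Package: minibar
Title: Design, Authentication and Delimitation with Mitochondrial DNA Mini-Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for working with very short diagnostic mitochondrial loci
    ("mini-barcodes") amplifiable from heavily degraded museum and ancient
    specimens. Scans aligned reference panels for hypervariable cores flanked
    by conserved primer sites, builds degenerate consensus primers, and scores
    designs for species-level haplotype uniqueness. Models fragment-length
    distributions of degraded extracts and the probability that an amplicon of
    a given length can be amplified at all. Authenticates amplicon sequences by
    strict replicate consensus across independent amplifications and sequencing
    directions. Identifies an unknown specimen against the panel by pairwise
    identity ranking and neighbor-joining trees with bootstrap support, and
    tests its species status by comparing its distance to the nearest relative
    against within-species and congeneric distance distributions with one-sided
    one-sample t-tests. Includes a synthetic-data generator that emulates the
    whole experimental regime for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    phangorn,
    phytools,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
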
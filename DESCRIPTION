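Package: ContigStretch
Title: Seeded Contig Extension for Viral Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iteratively extends seed contigs (for example metaSPAdes output)
    through a metagenomic read set by recruiting reads that overlap a contig
    terminus, calling a quality-squared-weighted consensus over the overhang,
    and branching by depth-first search when read support reveals strain-level
    heterogeneity. Detects cycles and circular genomes to terminate cleanly.
    Ships a shotgun read simulator (uniform binomial coverage, substitution
    errors, coverage spike-in peaks, circular genomes, two-strain mixtures)
    and an evaluation harness (gained length, largest contiguous aligned
    segment, chimera flagging) so the whole pipeline is testable without
    external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    Rsamtools,
    data.table,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
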
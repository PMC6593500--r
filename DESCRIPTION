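Package: magweave
Title: Strain and Mobile-Element Linking for Low-Complexity Long-Read Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links strains, plasmids and phages in low-complexity metagenomes
    sequenced with long reads. Provides coverage-based deconvolution of two
    sibling strains of one species, CRISPR spacer to protospacer matching
    against phage genomes under a mismatch budget, DNA methylation motif
    profiling and unique-motif plasmid-to-host assignment, and classification
    of junction-spanning reads at a prophage locus into integrated, absent and
    circular molecule states. Includes the read-length/quality filtering and
    GC/coverage/tetranucleotide binning diagnostics such analyses rest on, and
    a synthetic-community generator with complete ground truth so every stage
    is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
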
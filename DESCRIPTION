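Package: crispracq
Title: CRISPR Spacer Acquisition Assays, Protospacer Mapping, and
    Mobile-Element Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for CRISPR adaptation assays in prokaryotes,
    built around chronically infecting (pro)viral elements in haloarchaea.
    Parses repeat-spacer amplicon reads to detect newly inserted
    spacer-repeat units at the leader end of an array, classifies extracted
    spacers as duplications of existing spacers versus new acquisitions,
    maps new spacers to reference replicons under strict identity filters to
    locate protospacers and their PAM trinucleotides, detects replicating
    mobile elements from read-depth fold enrichment and types them as
    circular and/or integrated from junction-spanning reads, and summarises
    per-gene RPKM fold changes between conditions. A synthetic-data
    generator produces genomes, arrays, amplicon and whole-genome reads, and
    count tables with machine-readable ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
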
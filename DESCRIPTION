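Package: cidscope
Title: Copy Number, Repertoire Typing and Crossing-Type Association for the
    Wolbachia cidA-cidB Operon
Version: 0.1.0
Authors@R:
    person("cidscope", "developers", email = "cidscope@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing amplified, polymorphic copies of the
    Wolbachia cidA-cidB operon in Culex pipiens. Implements coverage-based
    amplification detection against single-copy marker genes, qPCR relative
    copy number, combinatorial variant-repertoire typing of cloned amplicons,
    in-silico PCR-RFLP screening with pattern-based variant calling,
    polymorphic-block and four-gamete recombination analysis, and the
    two-proportion (Yates-corrected chi-square) association between variant
    signatures and crossing types. A seeded synthetic-data module generates
    reference genomes, multi-copy sample genomes, reads, clones, qPCR tables
    and line panels so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
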
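Package: ighrepsel
Title: Simulation and Analysis of Heavy-Chain Repertoire Selection and
    VH-Replacement Excision Circles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generative model of immunoglobulin heavy-chain VDJ
    recombination and early B-cell developmental selection (D-mu arrest,
    surrogate-light-chain pairing, VH-replacement with excision-circle
    emission, allelic exclusion), together with read-level emitters for
    J-anchored capture and framework-3 run-off libraries, a simplified
    rearrangement annotator (segment assignment, UMI deduplication,
    productivity, CDR3 extraction, D reading frames), repertoire-level
    selection statistics, and a detector for VH-replacement excision
    circles based on back-to-back cryptic/conventional heptamer signal
    joints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
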
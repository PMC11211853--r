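Package: msdbsearch
Title: Peptide Database Search with Pluggable and Learned PSM Score Functions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale tandem mass spectrometry database search engine
    with a pluggable peptide-spectrum-match (PSM) score-function interface.
    Implements in-silico tryptic digestion with proline suppression, static,
    variable and N-terminal modifications, shuffled decoy generation, and a
    mass-indexed candidate store; three classic score functions (XCorr,
    Hyperscore, Andromeda); a teacher-forced autoregressive scorer that
    aggregates per-residue next-token probabilities by their geometric mean;
    peptide-level target-decoy competition FDR with q-values and target match
    percentage; MGF input, mzTab and Percolator PIN output; and a seeded
    synthetic spectrum simulator for ground-truthed evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
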
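Package: operonr
Title: Operon Prediction from Metagenomic Scaftigs by Intergenic Distance
    and Promoter Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts bacterial operons on assembled metagenomic scaftigs or
    whole genomes. Co-directional genes are first clustered into proximons
    using an intergenic-distance threshold, then transcription unit
    boundaries are refined from promoter evidence supplied by an external
    promoter-prediction file, a built-in sigma70 position weight matrix
    scanner, or a planted-truth oracle. Includes pair-level evaluation
    against reference operon maps with a six-way configuration taxonomy
    (perfect match, subset, superset, bridge-1, bridge-2, novel), and a
    synthetic prokaryotic genome simulator that plants operons, promoter
    motifs, and decoy genes with a full ground-truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
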
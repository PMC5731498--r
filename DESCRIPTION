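Package: ppisite
Title: Knowledge-Based Prediction of Protein-Protein Interaction Interface Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which residues of a protein structure belong to a
    protein-protein interaction interface. Protein complexes are converted
    into residue contact graphs (alpha-carbon distance cutoff), each
    residue's structural neighborhood is encoded as a fixed-length hashed
    pairwise fingerprint, and a residue is scored by how often its
    nearest-neighbor fingerprints in a knowledge base built from labeled
    complexes belong to interface residues. Includes relative solvent
    accessibility computation, tie-inclusive nearest-neighbor search over a
    binary on-disk knowledge base, Matthews-correlation-based evaluation
    with surface-residue masks, and a deterministic synthetic-structure
    generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    igraph,
    purrr,
    rlang,
    tibble,
    tidyr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
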
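Package: eccontacts
Title: Evaluating Evolutionary Couplings Against Alternative Residue Contact Definitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking which definition of a "true" residue-residue
    contact best matches the pairs recovered by evolutionary coupling
    analysis of protein sequence alignments. Reads and cleans single-chain
    PDB structures; computes residue-residue distance matrices under five
    reference methods (C-alpha, C-beta, side-chain geometric center, and
    minimum heavy-atom distances over all atoms or side-chain atoms only);
    derives contact maps by fixed or count-matched cutoffs; classifies
    side-chain orientations of residue pairs; scores ranked couplings by
    positive predictive value at top L/2 and by average precision; and
    compares contact definitions with paired signed-rank tests. Includes a
    mutual-information scorer with average product correction and sequence
    reweighting, readers for externally computed coupling matrices, and a
    synthetic-data generator that plants pairwise covariation at the
    contacts of a toy 3D structure so that the full pipeline can be
    exercised and validated without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
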
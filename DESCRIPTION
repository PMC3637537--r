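Package: nsalign
Title: Non-Sequential Protein Structure Alignment via Geometric Hashing of
    Secondary-Structure Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns pairs of protein structures from C-alpha coordinates alone,
    without assuming that structurally equivalent regions occur in the same
    sequence order in the two chains. Secondary-structure elements are described
    by overlapping short-segment vector elements; geometric hashing over
    per-element reference frames proposes candidate rigid superpositions, and a
    stepwise greedy residue-level alignment with iterative refinement maximizes
    a TM-score-like objective. Handles multi-chain complexes, C-alpha-only
    models, reverse (inverse-direction) matches, and can report alternative
    sub-optimal alignments. Includes reference-dependent (Q-score) and
    reference-independent (RMSD, aligned-residue and gap counts, TM-score)
    evaluation statistics and a segment-permutation benchmark generator that
    produces non-sequential test pairs with known ground-truth mappings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
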
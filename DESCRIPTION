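Package: plastidpop
Title: Phylogeography of Uniparental Plastid Markers: Diversity, Structure,
    and Demography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Range-wide phylogeographic analysis of uniparentally inherited,
    non-recombining sequence markers such as chloroplast DNA fragments.
    Reads per-locus multiple sequence alignments and population metadata,
    collapses sequences into haplotypes, and computes haplotype and
    nucleotide diversity per population. Estimates population differentiation
    with Gst and Nst (Pons & Petit estimators, with a permutation test for
    phylogeographic structure), Hudson's Fst, and single-level AMOVA with
    Phi-st. Tests isolation by distance with the linearised-Fst regression on
    log geographic distance and a Mantel test, and correlates diversity with
    elevation. Runs Tajima's D and Fu's Fs neutrality tests with coalescent
    p-values, fits the sudden-expansion mismatch-distribution model with
    parametric-bootstrap goodness-of-fit tests, and estimates the
    mutation-to-seed-migration rate ratio from paired organelle
    differentiation coefficients under Wright's island model. A built-in
    structured-coalescent simulator generates study-like two-locus datasets
    for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
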
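Package: rnadirect
Title: RNA Tertiary Contact Prediction by Coupling Analysis Reweighted
    with a Learned Structural Contact Template
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tertiary (long-range) nucleotide-nucleotide contacts in
    structured RNAs by combining two complementary signals: direct-coupling
    analysis (mean-field Potts inference) of a multiple sequence alignment,
    and a structural contact-frequency template learned by a binary restricted
    Boltzmann machine trained with contrastive divergence on contact maps of
    related RNA structures. Direct-information scores are reweighted by the
    squared template weight, and ranked predictions are evaluated by positive
    predictive value with breakdowns by sequence range and secondary-structure
    category. Includes readers for PDB coordinates, FASTA/Stockholm alignments
    and dot-bracket strings, a synthetic-data generator producing RNA-like
    contact-map families and alignments with planted couplings, and an
    end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    ggplot2,
    generics,
    jsonlite,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
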
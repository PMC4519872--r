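Package: quenchbind
Title: Fluorescence Quenching, Binding Thermodynamics and FRET Analysis of
    Protein-Ligand Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of steady-state fluorescence titrations of a protein by a
    small-molecule quencher: inner-filter correction, Stern-Volmer quenching
    analysis with mechanism classification against the diffusion-controlled
    limit, double-logarithmic binding constant and stoichiometry estimation,
    Van't Hoff thermodynamics with intermolecular-force classification,
    Forster resonance energy transfer parameters (overlap integral, critical
    distance, donor-acceptor distance), synchronous-fluorescence peak-shift
    and fluorescence phase-diagram conformational analysis, and aggregation of
    externally produced MM-PBSA energy-component tables. Includes a seedable
    generator of synthetic titration spectra with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
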
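Package: hdxmap
Title: Differential Hydrogen-Deuterium Exchange Analysis for Protein
    Interaction Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peptide-level analysis of differential hydrogen-deuterium
    exchange mass spectrometry (HDX-MS) experiments comparing a free and a
    bound state of a protein. Computes per-peptide percent deuterium uptake
    (%HDX) from centroid mass shifts, the maximum-over-timepoints uptake
    difference (Delta-HDX), and a three-criterion significance call
    (effect size in %HDX, unpaired t-test, and an absolute mass-difference
    floor in Da); projects peptide-level differences onto residues,
    extracts contiguous protected or deprotected regions, and exports
    per-residue values into the B-factor column of a PDB file for
    structure coloring. Companion tools cover isotope-coded (d0/d4) BS3
    crosslink candidate enumeration and mass-doublet matching after
    in-silico tryptic digestion, and small-integer stoichiometry inference
    against SEC-MALS molar masses. A seeded synthetic-data generator
    produces two-state EX2-regime exchange kinetics with planted interface
    regions so the whole pipeline is testable end to end against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
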
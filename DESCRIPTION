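Package: confdiv
Title: Conformational Diversity and the Stability Effects of Amino Acid Substitutions
Version: 0.1.0
Authors@R:
    person("confdiv", "maintainers", email = "confdiv@example.org", role = c("aut", "cre"))
Description: Analysis of single amino acid substitution (SAS) stability effects
    across protein conformational ensembles. Parses multi-conformer PDB
    structures and computes Kabsch superposition RMSD and Shrake-Rupley
    solvent-accessible surface areas; aggregates per-conformer free-energy
    changes (ddG, kcal/mol) into per-substitution summaries; quantifies how
    often the stabilizing/neutral/destabilizing call for a substitution is
    ambiguous across conformers; and evaluates disease-versus-neutral
    discrimination from ddG under several conformer-selection strategies
    (global, minimum, maximum, average, random resampling baseline) with
    Matthews correlation coefficient, accuracy, specificity and sensitivity.
    Includes a calibrated synthetic-data generator emulating the statistical
    structure of curated human-variant ensembles so the whole pipeline is
    testable without external databases, plus a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
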
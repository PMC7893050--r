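Package: epstitrate
Title: Potentiometric Titration Analysis of Microbial-Mat Exopolymeric Substances
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for acid-base characterization of exopolymeric substances
    (EPS) from potentiometric titrations. Computes per-point charge excess from
    titrant additions and pH, inverts it into a discrete spectrum of monoprotic
    ligand concentrations on a pKa grid by L1-norm linear programming (the
    linear programming method, LPM), bins fitted sites into carboxyl,
    phosphoryl, amine and hydroxyl functional-group classes, and aggregates
    replicate titrations into summary tables. Includes a charge-balance
    equilibrium simulator that generates titration curves with known
    ground-truth ligand mixtures, so every stage of the pipeline can be
    validated by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
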
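Package: cysmsa
Title: Cysteine-Anchored Alignments and Structure-Model Evaluation for
    Disulfide-Rich Proteins
Version: 0.1.0
Authors@R:
    person("cysmsa", "maintainers", email = "cysmsa@example.org",
           role = c("aut", "cre"))
Description: Tools for preparing and evaluating structure predictions of
    small disulfide-rich proteins (defensin-like ligands such as SP11/SCR)
    and their receptor complexes. Builds cysteine-anchored multiple
    sequence alignments in which structurally homologous cysteines share
    columns (barcode/debarcode transforms plus an anchor-constrained
    center-star aligner), assembles paired a3m alignments for cognate
    receptor-ligand complex prediction, profiles alignment depth as the
    per-position number of effective sequences (Neff), and evaluates
    predicted models: mean pLDDT, pDockQ and pDockQ2 interface confidence,
    interchain atomic contacts, Kabsch superposition RMSD, and disulfide
    connectivity classification against a pattern catalog. Includes
    seedable generators of synthetic cysteine-rich families and toy dimer
    structures so the whole pipeline is testable offline, and a command
    line interface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
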
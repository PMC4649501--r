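Package: pefhand
Title: Structural Analysis of Penta-EF-Hand Calcium-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the calcium-driven conformational changes of
    penta-EF-hand (PEF) proteins such as Sorcin, PDCD6/Alg-2 and the calpain
    small-subunit dVI domain. Reads PDB/mmCIF coordinate files into tidy atom
    tables and provides helix-axis fitting, EF-hand opening angles and
    apo-to-holo delta tables, Kabsch superposition and per-region RMSD,
    calcium coordination-sphere extraction with pentagonal-bipyramidal
    geometry classification, Shrake-Rupley solvent-accessible surface areas
    with apo/holo exposure-change filtering, hydrophobic surface-patch
    clustering, peptide-interface burial, degenerate consensus-motif scanning
    of phage-display peptide sets, and 1:1 Langmuir SPR kinetics (simulation,
    global kinetic fitting, steady-state and Scatchard analysis). A synthetic
    fixture generator builds ideal helices, EF-hand pairs at prescribed
    angles, coordination polyhedra, motif-planted peptide sets and noisy
    sensorgrams so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
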
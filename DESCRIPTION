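Package: pdzdyn
Title: Trajectory and NMR Titration Analysis of Phosphorylated PDZ Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing phosphorylation-induced
    changes in protein dynamics, built around the Dishevelled-3 PDZ domain.
    Provides per-residue RMSF and delta-RMSF profiles across simulation
    replicas, atom-pair distance time series with contact-occurrence
    criteria (distance cutoff, minimum contiguous dwell, minimum occupancy),
    ion-mediated bridge detection, Kabsch-Sander style secondary-structure
    assignment with helix folding/unfolding event detection, leader-style
    RMSD clustering of loop conformations, and chemical-shift-perturbation
    analysis of NMR titration series with qualitative affinity ranking.
    Includes a synthetic-trajectory and synthetic-titration generator with
    planted, analytically known structure so every pipeline stage is
    testable without molecular-dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
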
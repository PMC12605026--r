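Package: probeconcord
Title: Concordance of RNA Chemical Probing Reactivity with 3D Structure
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joins per-nucleotide dimethyl sulfate (DMS) chemical probing
    reactivity tracks to structural features extracted from atomic
    coordinate models of RNA-protein complexes, and quantifies their
    agreement.  Implements per-atom Shrake-Rupley solvent-accessible
    surface area, distance-based hydrogen-bond detection, canonical
    Watson-Crick-Franklin base-pair annotation, protein-RNA contact
    counting, rigid-body superposition, condition-averaged differential
    reactivity, and ROC/AUC analysis of reactivity against single and
    Boolean-combined structural binaries.  A seeded synthetic-data
    generator builds idealized A-form duplex and hairpin models with
    decoy protein chains and simulates reactivity tracks from a known
    generative model, so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
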
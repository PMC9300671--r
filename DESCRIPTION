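Package: bipsim
Title: Coarse-Grained Simulation of Chromatin-Mediated Protein Phase Separation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Langevin-dynamics simulator for multi-domain chromatin-binding
    proteins, modelled as rigid seven-sphere dimers inspired by HP1, interacting
    with a bead-spring chromatin polymer. Implements two protein-protein
    interaction variants (weak multivalent attraction and strictly limited
    valence), the full observable suite used to characterise liquid-liquid and
    bridging-induced phase separation (separation depth, polymer radius of
    gyration, chromatin binding modes, bond-network decorrelation, droplet and
    cluster statistics), and reproducible experiment protocols (phase scans,
    protein-density scans, interaction-energy hysteresis ramps and quenches).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
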
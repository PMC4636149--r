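Package: scnet
Title: Surface Contact Networks for Protein Unfolding Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds residue-residue surface contact networks (SCN) from
    protein coordinates using dot-surface complementarity (S_m) and overlap
    (O_v) of side-chain van der Waals surfaces, and analyses their evolution
    over molecular-dynamics trajectory ensembles. Provides the network
    dissimilarity metric Disnet, fractional native contacts and links
    (Q, Q_L), link persistence and the derived epoch metrics persf and dlf,
    side-chain solvent accessibility of the hydrophobic core (SASC, SASCN),
    water-core interaction counts, secondary-structural content bookkeeping,
    Helmholtz free-energy landscapes over two order parameters, molten
    globule (DMG/WMG), transition-state and unfolded state classification,
    and classical multidimensional scaling of inter-snapshot network
    distances. Includes synthetic-geometry and stochastic-network generators
    for testing every stage without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
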
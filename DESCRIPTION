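Package: protacdyn
Title: Structural Dynamics of PROTAC-Induced Degradation Machinery Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling and analysing the structural dynamics of
    PROTAC-induced protein degradation machinery. Assembles ternary
    E3-PROTAC-target models onto CRL4A-like ligase scaffolds by rigid-body
    superposition with clash screening, interface-gap scaffold classification
    and a lysine-to-ubiquitin retention filter; quantifies trajectory dynamics
    through pseudo-dihedral angles, ubiquitination-competence criteria,
    circular dihedral statistics, dihedral Gibbs entropy, time-lagged
    correlation, thresholded pairwise-force interaction networks and backbone
    principal component analysis. A synthetic-data module generates toy
    complexes, trajectories, coupled angle/distance series and force matrices
    with planted ground truth so every analysis stage is testable without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
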
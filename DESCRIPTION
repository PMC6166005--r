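Package: mutnet
Title: Comparative Residue-Network and Free-Energy Analytics for Enzyme Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative structural analysis of wild-type versus
    mutant enzymes: residue interaction networks with typed, weighted edges
    (contacts, hydrogen bonds, van der Waals overlaps); weighted betweenness
    and closeness centrality, hub detection, k-clique enumeration,
    clique-percolation communities and MCODE-style clusters; MM-GB/SA
    binding free-energy bookkeeping with per-residue decomposition checks;
    staged steered-dynamics potential-of-mean-force estimation via
    Jarzynski averaging over trajectory swarms; and trajectory observables
    (hydrogen-bond occupancy, dihedral series, ring-centroid distances,
    PCA free-energy landscapes). A synthetic-data module generates toy
    folded polymers with a pocket ligand, perturbed trajectories,
    steered-Langevin work traces and energy-component tables so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
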
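Package: metabolon
Title: Permutation Statistics, Interface-Overlap Tests and Patchy-Particle
    Reaction-Diffusion Simulation for Transient Enzyme Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing split-fluorophore (BiFC) protein-protein
    interaction matrices of metabolic pathways: symmetrisation of
    two-orientation fluorescence measurements, interaction-strength
    classification, permutation-null cluster statistics, cross-matrix
    conditional tests and interaction graphs.  Quantifies sharing of
    protein interaction interfaces through a mean inter-surface contact
    statistic with a random-surface null, extracts interfaces from
    two-chain structures, and enumerates degenerate-codon mutagenesis
    libraries.  Includes a coarse-grained patchy-particle Langevin /
    Brownian reaction-diffusion simulator that converts a measured
    interaction matrix into metabolic-flux predictions for a sequential
    enzymatic pathway, plus seed-deterministic synthetic-data generators
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    bio3d,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
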
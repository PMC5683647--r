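Package: huihf
Title: Classification of HU/IHF Nucleoid-Associated Proteins and
    Quantitative Analysis of HU-DNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of bacterial histone-like
    HU/IHF proteins. Represents family members on a 90-column conserved
    core alignment frame and provides identity counting with explicit
    indel-event accounting, Fitch-similarity distances, principal-component
    embedding, position-specific score-matrix profiles for group and clade
    classification, and censuses of insertion hotspots and charged terminal
    extensions. A structural module measures HU dimer models (helix-axis
    angles, inter-chain C-alpha distances, superposition RMSD). A binding
    module implements the finite-lattice cooperative ligand-on-lattice
    (McGhee-von Hippel) model for electrophoretic mobility shift data:
    occupancy distributions, depletion-corrected titration fitting of the
    association constant and cooperativity, binding-site-size estimation
    from DNA-length ladders, and dsDNA-normalized affinity profiles.
    Branched-DNA constructs (junctions, forks, bulges, overhangs) are
    assembled from oligonucleotide sets and classified by topology.
    Seeded generators produce synthetic sequence families, dimer models
    and titrations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    seqinr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
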
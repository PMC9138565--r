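Package: scrsasa
Title: Solvent-Accessible Surface Area Fingerprints and Clustering of
    Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-residue solvent-accessible surface area (SASA) from 3-D
    coordinates by Shrake-Rupley sphere-point sampling, with
    backbone/side-chain and polar/apolar decomposition; residue burial
    classification (nucleus/surface/intermediate) against a Gly-X-Gly
    tripeptide reference ensemble; ProtParam-style sequence descriptors and
    Chou-Fasman secondary-structure prediction; extraction of SASA
    fingerprints over structurally conserved regions of a multiple
    alignment; and agglomerative Ward/Euclidean clustering of the resulting
    descriptor vectors with Newick dendrogram export. Includes an
    ideal-geometry peptide builder for generating synthetic test structures
    and families of related proteins with known group labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    bio3d
Config/testthat/edition: 3
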
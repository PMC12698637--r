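Package: opulink
Title: Integrated Genotype-Phenotype Characterization of Rhizosphere Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit linking taxonomic (16S amplicon sequence variant)
    and phenotypic (single-cell Raman) views of soil microbial communities.
    Provides single-cell Raman spectral quality control, preprocessing and
    clustering into operational phenotypic units (OPUs) with AIC-guided cutoff
    selection; community-structure statistics (rarefaction, coverage, core-taxon
    filtering, CLR, Bray-Curtis, NMDS, PERMANOVA); ALDEx-style Dirichlet
    Monte-Carlo compositional differential abundance; SparCC co-abundance
    networks with bootstrap pseudo p-values, Markov clustering and hub
    detection; and OPU-ASV integration via diversity-coupling regression,
    distance-based redundancy analysis, vector fitting and Spearman correlation
    maps. A joint synthetic-scene generator with recorded ground truth makes
    every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    signal,
    vegan,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
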
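Package: bcrforest
Title: B Cell Clonal Lineage Trees and Repertoire-Level Evolution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers germline-rooted B cell clonal lineage trees from
    immune-repertoire sequencing data (AIRR Rearrangement TSV) using
    distance-based (iterative minimum-distance, minimum spanning tree,
    neighbor joining) and alignment-based (maximum parsimony, maximum
    likelihood) algorithms, transforms bifurcating phylogenies into
    multifurcating lineage networks, and quantifies intra- and
    inter-repertoire evolution through tree topology metrics (Sackin index,
    Laplacian spectral density), tree-comparison distances (generalized
    branch length distance), protein-language-model likelihoods, and
    structural features (RMSD, pLDDT, interface composition). A bundled
    somatic-hypermutation simulator generates synthetic lineages with known
    ground truth for benchmarking every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    jsonlite,
    bio3d,
    seqinr,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
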
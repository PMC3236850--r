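Package: ConsensusPPI
Title: Consensus Integration of Protein-Protein Interaction Networks by
    k-Votes with Structural-Clustering Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates multiple protein-protein interaction (PPI)
    databases into a single consensus network with the k-votes rule: an
    interaction enters the integrated network when at least k of the n
    source networks contain it (k=1 is the classical union, k=n the
    intersection). Provides the full clustering-based framework used to
    pick the consensus level k: SCAN structural clustering (structural
    similarity of closed neighbourhoods, cores, hubs and outliers),
    Newman modularity and similarity-based modularity, a hypergeometric
    clustering score against a gene-set catalog, and an annotation-cosine
    enrichment measure, swept over the SCAN threshold epsilon for each
    candidate k. A planted-partition simulator generates ground-truth
    modular networks, noisy database replicates and matching annotation
    catalogs so the whole pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Clustering, NetworkInference,
    Pathways, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'network-core.R'
    'integration.R'
    'scan.R'
    'quality.R'
    'sweep.R'
    'synthetic.R'
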
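#' @import methods
#' @importFrom stats phyper runif setNames approx
#' @importFrom utils read.delim write.table head tail
NULL

#' InteractionNetwork: an undirected simple graph of gene identifiers
#'
#' The central data container: a named, undirected, simple (no self-loops,
#' no multi-edges) graph whose vertices are opaque gene/protein identifier
#' strings (Entrez-style IDs are typical but not enforced).  Edges are stored
#' canonically: each edge is an unordered pair kept with `u < v` under
#' lexicographic string ordering, so membership of (u,v) and (v,u) is the
#' same question.
#'
#' @slot name single character label for the network (e.g. the source
#'   database).
#' @slot vertices character vector of vertex IDs, sorted, unique.
#' @slot edges two-column character matrix (`u`, `v`), canonical order per
#'   row, rows sorted lexicographically, no duplicates.
#'
#' @seealso [readEdgeList()], [writeEdgeList()], [interactionNetwork()]
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
    representation(name = "character", vertices = "character",
                   edges = "matrix"))

setValidity("InteractionNetwork", function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name))
        msg <- c(msg, "'name' must be a single non-NA string")
    v <- object@vertices
    if (anyDuplicated(v)) msg <- c(msg, "duplicate vertex IDs")
    if (length(v) && (any(!nzchar(v)) || any(grepl("[[:space:]]", v))))
        msg <- c(msg, "vertex IDs must be non-empty and whitespace-free")
    e <- object@edges
    if (!is.character(e) || ncol(e) != 2L)
        msg <- c(msg, "'edges' must be a two-column character matrix")
    else if (nrow(e)) {
        if (any(e[, 1L] >= e[, 2L]))
            msg <- c(msg, "edges must be canonical (u < v) with no self-loops")
        if (anyDuplicated(paste(e[, 1L], e[, 2L])))
            msg <- c(msg, "duplicate edges")
        if (!all(c(e) %in% v))
            msg <- c(msg, "edge endpoints missing from vertex set")
    }
    if (length(msg)) msg else TRUE
})

#' NetworkEnsemble: the committee of networks to be integrated
#'
#' An ordered collection of [InteractionNetwork-class] objects with unique
#' names — the committee G1..Gn whose votes the k-votes rule counts.
#'
#' @slot networks list of `InteractionNetwork`, length >= 1.
#' @exportClass NetworkEnsemble
setClass("NetworkEnsemble", representation(networks = "list"))

setValidity("NetworkEnsemble", function(object) {
    nets <- object@networks
    if (!length(nets)) return("ensemble must contain at least one network")
    if (!all(vapply(nets, is, logical(1), "InteractionNetwork")))
        return("all members must be InteractionNetwork objects")
    nms <- vapply(nets, function(x) x@name, character(1))
    if (anyDuplicated(nms)) return("member names must be unique")
    TRUE
})

#' VoteTable: per-edge vote counts across an ensemble
#'
#' @slot votes data.frame with columns `u`, `v` (canonical edge) and
#'   `votes` (integer in 1..n), sorted by edge.
#' @slot n integer ensemble size the counts were taken over.
#' @exportClass VoteTable
setClass("VoteTable", representation(votes = "data.frame", n = "integer"))

setValidity("VoteTable", function(object) {
    df <- object@votes
    if (!all(c("u", "v", "votes") %in% names(df)))
        return("votes must have columns u, v, votes")
    if (nrow(df) && (any(df$votes < 1L) || any(df$votes > object@n)))
        return("vote counts must lie in [1, n]")
    TRUE
})

#' IntegratedNetwork: a k-votes consensus network
#'
#' An [InteractionNetwork-class] whose edges were retained by the k-votes
#' rule, annotated with the consensus level and the source committee.
#'
#' @slot k integer consensus threshold used.
#' @slot sourceEnsemble character vector of member network names.
#' @exportClass IntegratedNetwork
setClass("IntegratedNetwork", contains = "InteractionNetwork",
    representation(k = "integer", sourceEnsemble = "character"))

#' ScanParams: SCAN tuning parameters
#'
#' @slot epsilon structural-similarity threshold in (0, 1].
#' @slot mu minimum epsilon-neighbourhood size (closed, i.e. counting the
#'   vertex itself) for a vertex to be a core; integer >= 2.
#' @exportClass ScanParams
setClass("ScanParams", representation(epsilon = "numeric", mu = "integer"))

setValidity("ScanParams", function(object) {
    if (length(object@epsilon) != 1L || object@epsilon <= 0 ||
        object@epsilon > 1)
        return("epsilon must be a single value in (0, 1]")
    if (length(object@mu) != 1L || object@mu < 2L)
        return("mu must be a single integer >= 2")
    TRUE
})

#' Clustering: a SCAN clustering result
#'
#' Disjoint clusters of vertices plus the unclassified vertices labelled
#' `hub` (adjacent to two or more clusters) or `outlier`.  Clusters are
#' numbered canonically by their lexicographically smallest member, so the
#' result is independent of vertex visit order.
#'
#' @slot clusters list of character vectors (sorted vertex IDs), pairwise
#'   disjoint, each of size >= 2.
#' @slot unclassified named character vector; names are vertex IDs, values
#'   `"hub"` or `"outlier"`.
#' @slot params the [ScanParams-class] that produced the clustering.
#' @slot networkRef name of the clustered network.
#' @exportClass Clustering
setClass("Clustering",
    representation(clusters = "list", unclassified = "character",
                   params = "ScanParams", networkRef = "character"))

setValidity("Clustering", function(object) {
    cl <- object@clusters
    msg <- character()
    if (length(cl)) {
        if (any(vapply(cl, length, integer(1)) < 2L))
            msg <- c(msg, "clusters must have at least two members")
        memb <- unlist(cl, use.names = FALSE)
        if (anyDuplicated(memb))
            msg <- c(msg, "clusters must be pairwise disjoint")
        if (any(memb %in% names(object@unclassified)))
            msg <- c(msg, "a vertex cannot be both clustered and unclassified")
    }
    if (length(object@unclassified) &&
        !all(object@unclassified %in% c("hub", "outlier")))
        msg <- c(msg, "unclassified labels must be 'hub' or 'outlier'")
    if (length(msg)) msg else TRUE
})

#' AnnotationCatalog: a term -> gene-set map (GMT-style)
#'
#' Holds a gene-set catalog (e.g. KEGG pathways read from a GMT file) and
#' its induced binary annotation vector per gene: gene g's vector has a 1
#' exactly at the terms containing g.  The `universe` (union of all term
#' gene sets) is the default background for hypergeometric tests.
#'
#' @slot terms named list; each element a character vector of gene IDs.
#' @slot universe sorted character vector, union of all term gene sets.
#' @exportClass AnnotationCatalog
setClass("AnnotationCatalog",
    representation(terms = "list", universe = "character"))

setValidity("AnnotationCatalog", function(object) {
    if (!length(object@terms)) return("catalog must contain at least one term")
    if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
        return("terms must be uniquely named")
    if (any(vapply(object@terms, length, integer(1)) == 0L))
        return("terms must be non-empty")
    if (!setequal(object@universe, unique(unlist(object@terms))))
        return("universe must equal the union of all term gene sets")
    TRUE
})

#' QualityProfile: the four quality measures along an epsilon grid
#'
#' One row per epsilon value of a sweep over a single network: number of
#' clusters, number of clustered vertices, modularity (Q_N, unclipped),
#' similarity-based modularity (Q_S), clustering score, raw enrichment and
#' min-max-normalised enrichment.
#'
#' @slot networkName name of the swept network.
#' @slot k consensus level of the network (NA when not an integrated
#'   network).
#' @slot rows data.frame with columns `epsilon`, `nClusters`, `nClustered`,
#'   `qN`, `qS`, `clusteringScore`, `enrichmentRaw`, `enrichmentNorm`.
#' @exportClass QualityProfile
setClass("QualityProfile",
    representation(networkName = "character", k = "integer",
                   rows = "data.frame"))

#' KSelection: the Table-2-style consensus-level evaluation
#'
#' Per-k node/edge counts and presence-of-optimum flags for the four
#' quality measures, the selected consensus level, and the decision rule
#' that selected it.
#'
#' @slot summary data.frame, one row per k, with columns `k`, `nNodes`,
#'   `nEdges`, presence flags (`optQN`, `optQS`, `optScore`, `optEnrich`)
#'   and the corresponding argmax epsilons.
#' @slot profiles list of [QualityProfile-class], one per k (NULL where the
#'   integrated network was empty).
#' @slot chosenK selected consensus level.
#' @slot rationale human-readable description of the rule branch applied.
#' @exportClass KSelection
setClass("KSelection",
    representation(summary = "data.frame", profiles = "list",
                   chosenK = "integer", rationale = "character"))

#' PlantedTruth: a ground-truth modular network
#'
#' A planted-partition random graph together with its module assignment
#' and the generator parameters, used as the known answer when benchmarking
#' the integration + clustering pipeline.
#'
#' @slot network the true [InteractionNetwork-class].
#' @slot modules list of character vectors partitioning the vertex set.
#' @slot params list with `moduleSizes`, `pIn`, `pOut`, `seed`.
#' @exportClass PlantedTruth
setClass("PlantedTruth",
    representation(network = "InteractionNetwork", modules = "list",
                   params = "list"))

setValidity("PlantedTruth", function(object) {
    memb <- unlist(object@modules, use.names = FALSE)
    if (anyDuplicated(memb)) return("modules must be disjoint")
    if (!setequal(memb, object@network@vertices))
        return("modules must partition the vertex set")
    TRUE
})
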
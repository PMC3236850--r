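#' @include network-core.R
NULL

## Sparse pattern matrix of the closed adjacency (A + I) for a network.
closedAdjacency <- function(net) {
    verts <- vertices(net)
    n <- length(verts)
    e <- edges(net)
    ui <- match(e[, 1L], verts); vi <- match(e[, 2L], verts)
    Matrix::sparseMatrix(i = c(ui, vi, seq_len(n)),
                         j = c(vi, ui, seq_len(n)),
                         x = 1, dims = c(n, n))
}

#' Structural similarity between two vertices
#'
#' SCAN's structural similarity of a vertex pair, computed from common
#' neighbours with the geometric-mean normalisation:
#' \deqn{\sigma(u,v) = \frac{|\Gamma(u) \cap \Gamma(v)|}
#'   {\sqrt{|\Gamma(u)|\,|\Gamma(v)|}}}
#' where \eqn{\Gamma(x)} is the closed neighbourhood \eqn{N(x) \cup \{x\}}.
#' Symmetric, bounded in \eqn{[0,1]}, and \eqn{\sigma(u,u) = 1}.
#'
#' @param net an [InteractionNetwork-class].
#' @param u,v vertex IDs present in `net`.
#' @return similarity in `[0, 1]`.
#' @examples
#' tri <- interactionNetwork(c("a", "a", "b"), c("b", "c", "c"))
#' structuralSimilarity(tri, "a", "b")  # 1: identical closed neighbourhoods
#' @export
structuralSimilarity <- function(net, u, v) {
    verts <- vertices(net)
    if (!(u %in% verts) || !(v %in% verts))
        stop("unknown vertex: ", paste(setdiff(c(u, v), verts), collapse = ", "))
    if (u == v) return(1)
    adj <- adjacencyIndex(net)
    ui <- match(u, verts); vi <- match(v, verts)
    gu <- c(adj[[ui]], ui); gv <- c(adj[[vi]], vi)
    length(intersect(gu, gv)) / sqrt(length(gu) * length(gv))
}

#' Structural similarity of every edge
#'
#' Computes \eqn{\sigma(u,v)} for all adjacent pairs at once (the only
#' pairs SCAN thresholds, and the pairs entering similarity-based
#' modularity).  Exposed because a single pass here feeds every epsilon of
#' a sweep: \eqn{\sigma} does not depend on \eqn{\epsilon}.
#'
#' @param net an [InteractionNetwork-class].
#' @return numeric vector aligned with the rows of `edges(net)`.
#' @export
edgeSimilarities <- function(net) {
    e <- edges(net)
    if (!nrow(e)) return(numeric())
    verts <- vertices(net)
    A <- closedAdjacency(net)
    common <- A %*% A    # (i,j) entry: |closed(i) ∩ closed(j)|
    ui <- match(e[, 1L], verts); vi <- match(e[, 2L], verts)
    dclosed <- Matrix::colSums(A)
    as.numeric(common[cbind(ui, vi)]) / sqrt(dclosed[ui] * dclosed[vi])
}

#' Epsilon-neighbourhood of a vertex
#'
#' The members of the closed neighbourhood whose structural similarity
#' with `v` reaches the threshold:
#' \eqn{N_\epsilon(v) = \{w \in \Gamma(v) : \sigma(v,w) \ge \epsilon\}}.
#' Always contains `v` itself (\eqn{\sigma(v,v)=1}).
#'
#' @param net an [InteractionNetwork-class].
#' @param v a vertex ID.
#' @param epsilon similarity threshold in (0, 1].
#' @return character vector of vertex IDs, sorted.
#' @export
epsNeighborhood <- function(net, v, epsilon) {
    verts <- vertices(net)
    if (!(v %in% verts)) stop("unknown vertex: ", v)
    adj <- adjacencyIndex(net)
    nb <- verts[adj[[match(v, verts)]]]
    sims <- vapply(nb, function(w) structuralSimilarity(net, v, w),
                   numeric(1))
    sort(unique(c(v, nb[sims >= epsilon])), method = "radix")
}

## minimal union-find
ufFind <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
}

#' SCAN structural clustering
#'
#' The Structural Clustering Algorithm for Networks.  A vertex is a *core*
#' when its epsilon-neighbourhood (closed, so counting the vertex itself)
#' has at least `mu` members.  Clusters are the connected components of
#' direct structure reachability seeded from cores: two cores joined by an
#' edge with \eqn{\sigma \ge \epsilon} share a cluster, and a non-core
#' vertex in a core's epsilon-neighbourhood joins that core's cluster
#' (*border* vertex).  Remaining vertices are unclassified: *hubs* when
#' adjacent to two or more distinct clusters, *outliers* otherwise.
#'
#' Determinism: a border vertex reachable from cores of several clusters
#' is assigned to the cluster of the lexicographically smallest reaching
#' core, and clusters are numbered by their lexicographically smallest
#' member, so the result never depends on vertex visit order.
#'
#' @param net an [InteractionNetwork-class].
#' @param epsilon similarity threshold in (0, 1]; the comparison is
#'   \eqn{\sigma \ge \epsilon}, so `epsilon = 1` still matches identical
#'   closed neighbourhoods.
#' @param mu minimum epsilon-neighbourhood size for a core (default 2,
#'   the customary SCAN setting).
#' @param sigma optional pre-computed [edgeSimilarities()] vector for
#'   `net`, to avoid recomputation across an epsilon grid.
#' @param adj optional pre-computed adjacency index (internal reuse
#'   across an epsilon grid).
#' @return a [Clustering-class].
#' @examples
#' cliq <- function(ids) t(combn(ids, 2))
#' e <- rbind(cliq(paste0("a", 1:5)), cliq(paste0("b", 1:5)))
#' net <- interactionNetwork(e[, 1], e[, 2])
#' scanCluster(net, epsilon = 0.7)   # recovers the two cliques
#' @export
scanCluster <- function(net, epsilon, mu = 2L, sigma = NULL, adj = NULL) {
    params <- new("ScanParams", epsilon = epsilon, mu = as.integer(mu))
    validObject(params)
    verts <- vertices(net)
    n <- length(verts)
    e <- edges(net)
    if (is.null(sigma)) sigma <- edgeSimilarities(net)
    if (nrow(e) && length(sigma) != nrow(e))
        stop("sigma must align with edges(net)")

    clustersOut <- list()
    unclassified <- character()
    if (n) {
        ui <- match(e[, 1L], verts); vi <- match(e[, 2L], verts)
        strong <- which(sigma >= epsilon)
        ## closed eps-neighbourhood sizes: 1 (self) + strong incident edges
        nbSize <- tabulate(c(ui[strong], vi[strong]), nbins = n) + 1L
        core <- nbSize >= mu

        parent <- seq_len(n)
        for (s in strong) {
            a <- ui[s]; b <- vi[s]
            if (core[a] && core[b]) {
                ra <- ufFind(parent, a); rb <- ufFind(parent, b)
                if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
            }
        }
        root <- vapply(seq_len(n), function(i)
            if (core[i]) ufFind(parent, i) else NA_integer_, integer(1))

        ## borders: non-core endpoints of strong edges incident to a core;
        ## deterministic tie-break — the smallest reaching core (canonical
        ## vertex order) decides the cluster
        assign <- root
        borderCore <- rep(NA_integer_, n)
        for (s in strong) {
            a <- ui[s]; b <- vi[s]
            if (core[a] && !core[b] &&
                (is.na(borderCore[b]) || a < borderCore[b]))
                borderCore[b] <- a
            if (core[b] && !core[a] &&
                (is.na(borderCore[a]) || b < borderCore[a]))
                borderCore[a] <- b
        }
        takeBorder <- !core & !is.na(borderCore)
        assign[takeBorder] <- root[borderCore[takeBorder]]

        member <- which(!is.na(assign))
        if (length(member)) {
            groups <- split(member, assign[member])
            ## canonical numbering: order by smallest member index
            groups <- groups[order(vapply(groups, min, integer(1)))]
            clustersOut <- lapply(unname(groups), function(ix) verts[ix])
        }

        rest <- which(is.na(assign))
        if (length(rest)) {
            clusterOf <- rep(NA_integer_, n)
            for (ci in seq_along(clustersOut))
                clusterOf[match(clustersOut[[ci]], verts)] <- ci
            if (is.null(adj)) adj <- adjacencyIndex(net)
            lab <- vapply(rest, function(i) {
                nbcl <- unique(clusterOf[adj[[i]]])
                nbcl <- nbcl[!is.na(nbcl)]
                if (length(nbcl) >= 2L) "hub" else "outlier"
            }, character(1))
            unclassified <- setNames(lab, verts[rest])
            unclassified <- unclassified[order(names(unclassified),
                                               method = "radix")]
        }
    }
    new("Clustering", clusters = clustersOut, unclassified = unclassified,
        params = params, networkRef = networkName(net))
}

#' Construct a Clustering by hand
#'
#' Builds a [Clustering-class] from explicit cluster membership, e.g. to
#' evaluate an externally produced partition with the quality measures.
#'
#' @param clusterList list of character vectors (disjoint, each >= 2
#'   members).
#' @param unclassified named character vector of `"hub"`/`"outlier"`
#'   labels for the remaining vertices (may be empty).
#' @param epsilon,mu the parameters to record (defaults are placeholders
#'   for hand-made clusterings).
#' @param networkRef name of the clustered network.
#' @return a [Clustering-class].
#' @export
clustering <- function(clusterList, unclassified = character(),
                       epsilon = 0.5, mu = 2L, networkRef = "manual") {
    clusterList <- lapply(clusterList, function(g)
        sort(as.character(g), method = "radix"))
    ord <- order(vapply(clusterList, `[`, character(1), 1L),
                 method = "radix")
    new("Clustering", clusters = clusterList[ord],
        unclassified = unclassified,
        params = new("ScanParams", epsilon = epsilon, mu = as.integer(mu)),
        networkRef = networkRef)
}

#' @rdname accessors
setMethod("clusters", "Clustering", function(x) x@clusters)

#' @rdname accessors
setMethod("unclassified", "Clustering", function(x) x@unclassified)

#' @rdname accessors
setMethod("scanParams", "Clustering", function(x) x@params)

#' @rdname accessors
#' @export
numClusters <- function(x) length(clusters(x))

setMethod("show", "Clustering", function(object) {
    sizes <- vapply(object@clusters, length, integer(1))
    cat(sprintf(
        "SCAN Clustering of '%s' (epsilon=%.3g, mu=%d): %d clusters (%d vertices), %d hubs, %d outliers\n",
        object@networkRef, object@params@epsilon, object@params@mu,
        length(sizes), sum(sizes),
        sum(object@unclassified == "hub"),
        sum(object@unclassified == "outlier")))
})

#' Cluster membership as a named vector
#'
#' @param clustering a [Clustering-class].
#' @return named character vector over all vertices: cluster number as a
#'   string for clustered vertices, `"hub"`/`"outlier"` otherwise.
#' @export
membershipVector <- function(clustering) {
    out <- character()
    for (i in seq_along(clustering@clusters))
        out[clustering@clusters[[i]]] <- as.character(i)
    u <- clustering@unclassified
    out[names(u)] <- u
    out[order(names(out), method = "radix")]
}

#' Write a clustering as TSV (vertex, assignment)
#'
#' @param clustering a [Clustering-class].
#' @param path file to write.
#' @return invisibly, `path`.
#' @export
writeClustering <- function(clustering, path) {
    m <- membershipVector(clustering)
    write.table(data.frame(vertex = names(m), assignment = unname(m)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
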
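#' @include network-core.R
NULL

#' Build a NetworkEnsemble
#'
#' @param ... [InteractionNetwork-class] objects, or a single list of them.
#' @return a [NetworkEnsemble-class].
#' @export
networkEnsemble <- function(...) {
    nets <- list(...)
    if (length(nets) == 1L && is.list(nets[[1L]]) &&
        !is(nets[[1L]], "InteractionNetwork"))
        nets <- nets[[1L]]
    new("NetworkEnsemble", networks = nets)
}

#' @rdname accessors
#' @param i member index or name.
#' @export
ensembleMember <- function(x, i) x@networks[[i]]

#' @rdname accessors
#' @export
ensembleSize <- function(x) length(x@networks)

#' @rdname accessors
#' @export
ensembleNames <- function(x)
    vapply(x@networks, networkName, character(1))

setMethod("show", "NetworkEnsemble", function(object) {
    cat(sprintf("NetworkEnsemble of %d networks: %s\n",
                ensembleSize(object),
                paste(ensembleNames(object), collapse = ", ")))
})

#' Count committee votes per interaction
#'
#' Every distinct canonical edge across the ensemble is mapped to the
#' number of member networks that contain it.  Votes are counted per
#' unordered protein pair, so a member listing both (a,b) and (b,a)
#' contributes a single vote (edges are already canonical within each
#' member).
#'
#' @param ensemble a [NetworkEnsemble-class].
#' @return a [VoteTable-class].
#' @export
countVotes <- function(ensemble) {
    stopifnot(is(ensemble, "NetworkEnsemble"))
    keys <- unlist(lapply(ensemble@networks, edgeKeys), use.names = FALSE)
    if (!length(keys)) {
        tab <- data.frame(u = character(), v = character(),
                          votes = integer(), stringsAsFactors = FALSE)
        return(new("VoteTable", votes = tab,
                   n = as.integer(ensembleSize(ensemble))))
    }
    counts <- table(keys)
    uv <- do.call(rbind, strsplit(names(counts), "\t", fixed = TRUE))
    tab <- data.frame(u = uv[, 1L], v = uv[, 2L],
                      votes = as.integer(counts),
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$u, tab$v, method = "radix"), , drop = FALSE]
    rownames(tab) <- NULL
    new("VoteTable", votes = tab, n = as.integer(ensembleSize(ensemble)))
}

#' @rdname accessors
setMethod("voteCounts", "VoteTable", function(x) x@votes)

setMethod("show", "VoteTable", function(object) {
    cat(sprintf("VoteTable: %d distinct edges over %d networks\n",
                nrow(object@votes), object@n))
})

#' Write a VoteTable as three-column TSV (u, v, votes)
#'
#' @param votes a [VoteTable-class].
#' @param path file to write.
#' @return invisibly, `path`.
#' @export
writeVoteTable <- function(votes, path) {
    write.table(voteCounts(votes), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Integrate an ensemble with the k-votes consensus rule
#'
#' An edge (and its two endpoints) enters the integrated network if and
#' only if at least `k` of the `n` member networks contain it.  `k = 1` is
#' the classical union of all members; `k = n` is the edge-set
#' intersection.  Vertices with no surviving incident edge are excluded,
#' so node counts are derived from the retained edges.
#'
#' @param ensemble a [NetworkEnsemble-class] (or a [VoteTable-class]
#'   already counted from one, via `votes`).
#' @param k consensus threshold, integer in `[1, n]`.
#' @param votes optional pre-computed [VoteTable-class] to avoid
#'   recounting across several `k`.
#' @return an [IntegratedNetwork-class] named `"G_k<k>"`.
#' @examples
#' g1 <- interactionNetwork(c("a", "b"), c("b", "c"), name = "db1")
#' g2 <- interactionNetwork(c("a", "c"), c("b", "d"), name = "db2")
#' ens <- networkEnsemble(g1, g2)
#' numEdges(integrateKVotes(ens, 1))  # union: 3 edges
#' numEdges(integrateKVotes(ens, 2))  # intersection: 1 edge
#' @export
integrateKVotes <- function(ensemble, k, votes = NULL) {
    stopifnot(is(ensemble, "NetworkEnsemble"))
    n <- ensembleSize(ensemble)
    if (length(k) != 1L || is.na(k) || k < 1L || k > n)
        stop(sprintf("k must lie in [1, %d]", n))
    k <- as.integer(k)
    if (is.null(votes)) votes <- countVotes(ensemble)
    tab <- voteCounts(votes)
    keep <- tab$votes >= k
    net <- interactionNetwork(tab$u[keep], tab$v[keep],
                              name = sprintf("G_k%d", k))
    new("IntegratedNetwork", net, k = k,
        sourceEnsemble = ensembleNames(ensemble))
}

setMethod("show", "IntegratedNetwork", function(object) {
    cat(sprintf("IntegratedNetwork (k=%d over %d sources): %d vertices, %d edges\n",
                object@k, length(object@sourceEnsemble),
                numVertices(object), numEdges(object)))
})

#' @rdname accessors
#' @export
consensusK <- function(x) x@k

#' Node/edge counts of the consensus family
#'
#' Builds the nested family of integrated networks for `k = 1..n` and
#' tabulates their sizes.  Edge sets are nested (each `k+1` network's
#' edges are a subset of the `k` network's), so both counts are
#' non-increasing in `k`.
#'
#' @param ensemble a [NetworkEnsemble-class].
#' @return data.frame with columns `k`, `nNodes`, `nEdges`.
#' @export
nestingReport <- function(ensemble) {
    stopifnot(is(ensemble, "NetworkEnsemble"))
    n <- ensembleSize(ensemble)
    votes <- countVotes(ensemble)
    rows <- lapply(seq_len(n), function(k) {
        g <- integrateKVotes(ensemble, k, votes = votes)
        data.frame(k = k, nNodes = numVertices(g), nEdges = numEdges(g))
    })
    do.call(rbind, rows)
}
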
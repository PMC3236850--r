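#' @include AllGenerics.R
NULL

## Canonicalize raw endpoint pairs: drop self-loops, order each pair
## lexicographically, deduplicate, sort.  Returns a 2-column character
## matrix with columns u, v.
canonicalEdges <- function(u, v) {
    u <- as.character(u); v <- as.character(v)
    keep <- u != v
    u <- u[keep]; v <- v[keep]
    swap <- u > v
    tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
    key <- paste(u, v, sep = "\t")
    keep <- !duplicated(key)
    u <- u[keep]; v <- v[keep]
    ord <- order(u, v, method = "radix")
    cbind(u = u[ord], v = v[ord])
}

#' Construct an InteractionNetwork from endpoint vectors
#'
#' Builds a canonical undirected simple network: self-loops are dropped,
#' duplicate and reversed pairs are collapsed, edges are stored with
#' `u < v` and sorted.  The vertex set defaults to the endpoints of the
#' surviving edges; isolated vertices exist only if supplied explicitly.
#'
#' @param u,v character vectors of interacting partners (recycled pairwise).
#' @param name label for the network.
#' @param vertices optional explicit vertex universe; must contain every
#'   edge endpoint.  Allows isolated vertices.
#' @return an [InteractionNetwork-class].
#' @examples
#' net <- interactionNetwork(c("7157", "7157"), c("4193", "1026"), name = "toy")
#' numEdges(net)
#' @export
interactionNetwork <- function(u = character(), v = character(),
                               name = "network", vertices = NULL) {
    stopifnot(length(u) == length(v))
    em <- canonicalEdges(u, v)
    verts <- sort(unique(c(em)), method = "radix")
    if (!is.null(vertices)) {
        vertices <- sort(unique(as.character(vertices)), method = "radix")
        if (!all(verts %in% vertices))
            stop("explicit vertex list is missing edge endpoints")
        verts <- vertices
    }
    new("InteractionNetwork", name = name, vertices = verts, edges = em)
}

#' @rdname accessors
#' @aliases vertices,InteractionNetwork-method
setMethod("vertices", "InteractionNetwork", function(x, ...) x@vertices)

#' @rdname accessors
setMethod("edges", "InteractionNetwork", function(x, ...) x@edges)

#' @rdname accessors
setMethod("numVertices", "InteractionNetwork",
          function(x) length(x@vertices))

#' @rdname accessors
setMethod("numEdges", "InteractionNetwork", function(x) nrow(x@edges))

#' @rdname accessors
setMethod("networkName", "InteractionNetwork", function(x) x@name)

#' @rdname accessors
setMethod("vertexDegree", "InteractionNetwork", function(x, v = NULL) {
    deg <- setNames(integer(length(x@vertices)), x@vertices)
    if (nrow(x@edges)) {
        tab <- table(c(x@edges))
        deg[names(tab)] <- as.integer(tab)
    }
    if (is.null(v)) return(deg)
    if (!all(v %in% x@vertices))
        stop("unknown vertex: ", paste(setdiff(v, x@vertices), collapse = ", "))
    if (length(v) == 1L) unname(deg[v]) else deg[v]
})

setMethod("show", "InteractionNetwork", function(object) {
    cat(sprintf("%s '%s': %d vertices, %d edges\n",
                class(object), object@name, numVertices(object),
                numEdges(object)))
})

#' Does the network contain an edge?
#'
#' Membership is by unordered pair: `hasEdge(net, u, v)` and
#' `hasEdge(net, v, u)` always agree.
#'
#' @param net an [InteractionNetwork-class].
#' @param u,v vertex IDs (vectorised pairwise).
#' @return logical vector.
#' @export
hasEdge <- function(net, u, v) {
    u <- as.character(u); v <- as.character(v)
    swap <- u > v
    tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
    paste(u, v, sep = "\t") %in% edgeKeys(net)
}

edgeKeys <- function(net) {
    e <- edges(net)
    if (!nrow(e)) character() else paste(e[, 1L], e[, 2L], sep = "\t")
}

#' Read an interaction network from an edge-list or SIF file
#'
#' TSV dialect: tab-separated, first two columns are the interacting pair,
#' extra columns ignored; lines starting with `#` are skipped and a single
#' header line is detected (and skipped) when its first two fields are
#' `protein_a`/`protein_b`.  SIF dialect: `u <relation> v [v2 ...]`; the
#' relation token is ignored and multi-target rows are expanded to pairs.
#' Self-loops are dropped and duplicate edges collapsed on ingest.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param name network label; defaults to the file base name.
#' @param vertices optional explicit vertex universe (allows isolated
#'   vertices).
#' @return an [InteractionNetwork-class].
#' @export
readEdgeList <- function(path, format = c("tsv", "sif"), name = NULL,
                         vertices = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    lineno <- seq_along(lines)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    lines <- lines[keep]; lineno <- lineno[keep]
    if (!length(lines))
        return(interactionNetwork(name = name, vertices = vertices))
    fields <- strsplit(lines, if (format == "tsv") "\t" else "[ \t]+")
    bad <- vapply(fields, length, integer(1)) < if (format == "tsv") 2L else 3L
    ## header detection (tsv only): a first row naming the two columns
    if (format == "tsv" && !bad[1L] &&
        all(tolower(fields[[1L]][1:2]) %in%
            c("protein_a", "protein_b", "u", "v", "source", "target"))) {
        fields <- fields[-1L]; bad <- bad[-1L]; lineno <- lineno[-1L]
        if (!length(fields))
            return(interactionNetwork(name = name, vertices = vertices))
    }
    if (any(bad))
        stop(sprintf("malformed row at line %d of %s (need at least %d fields)",
                     lineno[which(bad)[1L]], path,
                     if (format == "tsv") 2L else 3L))
    if (format == "tsv") {
        u <- vapply(fields, `[`, character(1), 1L)
        v <- vapply(fields, `[`, character(1), 2L)
    } else {
        pairs <- lapply(fields, function(f) {
            targets <- f[-(1:2)]
            cbind(rep(f[1L], length(targets)), targets)
        })
        pairs <- do.call(rbind, pairs)
        u <- pairs[, 1L]; v <- pairs[, 2L]
    }
    interactionNetwork(u, v, name = name, vertices = vertices)
}

#' Write an interaction network as a canonical two-column edge list
#'
#' One canonical edge per line, two tab-separated fields, lexicographically
#' sorted; reading the file back with [readEdgeList()] reproduces the
#' network exactly (round-trip identity), up to isolated vertices which a
#' bare edge list cannot carry.
#'
#' @param net an [InteractionNetwork-class].
#' @param path file to write.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(net, path) {
    e <- edges(net)
    writeLines(if (nrow(e)) paste(e[, 1L], e[, 2L], sep = "\t") else character(),
               path)
    invisible(path)
}

#' Read a two-column ID-mapping table
#'
#' @param path TSV file with columns (source_id, unified_id); `#` comments
#'   skipped.
#' @return named character vector: `names` are source IDs, values unified
#'   IDs.
#' @export
readIdMapping <- function(path) {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     colClasses = "character")
    if (ncol(df) < 2L) stop("mapping file needs two columns")
    setNames(df[[2L]], df[[1L]])
}

#' Re-key a network through an ID mapping
#'
#' Translates vertex IDs (e.g. database-native accessions to unified Entrez
#' IDs), re-canonicalises, and deduplicates.  Edges that become self-loops
#' after mapping (two endpoints mapping to one ID) are removed.
#'
#' @param net an [InteractionNetwork-class].
#' @param mapping named character vector (source -> unified), single-valued.
#' @param unmappedPolicy `"drop"` removes vertices without a mapping (and
#'   their edges); `"keep"` passes their original IDs through.
#' @return a re-keyed [InteractionNetwork-class].
#' @export
applyIdMapping <- function(net, mapping,
                           unmappedPolicy = c("drop", "keep")) {
    unmappedPolicy <- match.arg(unmappedPolicy)
    if (anyDuplicated(names(mapping)))
        stop("mapping has duplicate source keys")
    e <- edges(net)
    if (!nrow(e))
        return(interactionNetwork(name = networkName(net)))
    translate <- function(ids) {
        out <- unname(mapping[ids])
        miss <- is.na(out)
        if (unmappedPolicy == "keep") out[miss] <- ids[miss]
        out
    }
    u <- translate(e[, 1L]); v <- translate(e[, 2L])
    keep <- !is.na(u) & !is.na(v)
    interactionNetwork(u[keep], v[keep], name = networkName(net))
}

## internal: adjacency list as integer indices into vertices(net)
adjacencyIndex <- function(net) {
    verts <- vertices(net)
    n <- length(verts)
    e <- edges(net)
    adj <- vector("list", n)
    if (nrow(e)) {
        ui <- match(e[, 1L], verts)
        vi <- match(e[, 2L], verts)
        adj <- split(c(vi, ui), factor(c(ui, vi), levels = seq_len(n)))
        adj <- lapply(adj, function(x) sort(unname(x)))
    } else adj <- rep(list(integer()), n)
    names(adj) <- verts
    adj
}

## internal: igraph view of a network (vertex names preserved)
asIgraph <- function(net) {
    igraph::graph_from_data_frame(
        as.data.frame(edges(net), stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = vertices(net),
                              stringsAsFactors = FALSE))
}
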
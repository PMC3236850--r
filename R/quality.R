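#' @include scan.R
NULL

#' Construct an AnnotationCatalog
#'
#' @param terms named list of character vectors (term -> gene IDs).
#'   Gene sets are deduplicated; the universe is their union.
#' @return an [AnnotationCatalog-class].
#' @export
annotationCatalog <- function(terms) {
    terms <- lapply(terms, function(g) sort(unique(as.character(g)),
                                            method = "radix"))
    new("AnnotationCatalog", terms = terms,
        universe = sort(unique(unlist(terms, use.names = FALSE)),
                        method = "radix"))
}

#' @rdname accessors
setMethod("geneSets", "AnnotationCatalog", function(x) x@terms)

#' @rdname accessors
setMethod("universe", "AnnotationCatalog", function(x) x@universe)

setMethod("show", "AnnotationCatalog", function(object) {
    cat(sprintf("AnnotationCatalog: %d terms over %d genes\n",
                length(object@terms), length(object@universe)))
})

#' Read a GMT gene-set file
#'
#' Gene Matrix Transposed dialect: tab-separated; column 1 is the term
#' name, column 2 a description (ignored), columns 3+ the member gene IDs.
#'
#' @param path file to read.
#' @return an [AnnotationCatalog-class].
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty GMT file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nms <- vapply(fields, `[`, character(1), 1L)
    sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    empty <- lengths(sets) == 0L
    if (any(empty)) {
        warning("skipping ", sum(empty), " term(s) with no genes: ",
                paste(head(nms[empty], 5L), collapse = ", "))
        sets <- sets[!empty]; nms <- nms[!empty]
    }
    if (!length(sets)) stop("GMT file contains no usable gene sets: ", path)
    if (anyDuplicated(nms))
        stop("duplicate term names in GMT: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    annotationCatalog(setNames(sets, nms))
}

#' Write an AnnotationCatalog as GMT
#'
#' @param catalog an [AnnotationCatalog-class].
#' @param path file to write.
#' @param descriptions optional character vector of term descriptions.
#' @return invisibly, `path`.
#' @export
writeGmt <- function(catalog, path, descriptions = NULL) {
    terms <- geneSets(catalog)
    if (is.null(descriptions)) descriptions <- rep("na", length(terms))
    writeLines(mapply(function(nm, d, genes)
        paste(c(nm, d, genes), collapse = "\t"),
        names(terms), descriptions, terms), path)
    invisible(path)
}

#' Upper tail of the hypergeometric distribution
#'
#' The probability of observing `m` or more annotated members in a cluster
#' of size `n` drawn from a background of `N` genes of which `M` carry the
#' annotation:
#' \deqn{p = \sum_{i=m}^{\min(n,M)} \frac{\binom{M}{i}\binom{N-M}{n-i}}
#'   {\binom{N}{n}}}
#' Evaluated through `stats::phyper`, whose log-space internals keep the
#' tail exact far below double underflow thresholds (p-values of order
#' 1e-24 are routine for tight functional modules).
#'
#' @param n cluster size (number of draws).
#' @param m observed annotated members; `m = 0` gives 1.
#' @param M annotated genes in the background.
#' @param N background size.
#' @return upper-tail probability in `[0, 1]`; vectorised.
#' @examples
#' hypergeomTail(10, 10, 29, 5197)   # 5.10e-24
#' @export
hypergeomTail <- function(n, m, M, N) {
    if (any(m > pmin(n, M)) || any(m < 0) || any(n > N) || any(M > N) ||
        any(n < 0) || any(M < 0))
        stop("require 0 <= m <= min(n, M), n <= N, M <= N")
    phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Most significant annotation of a cluster
#'
#' Scores a vertex set against every catalog term that contains at least
#' one of its members, with [hypergeomTail()], and returns the
#' minimum-p-value term.  `n` counts the cluster members present in the
#' background, `m` those annotated with the term, `M` the background genes
#' carrying the term, `N` the background size.
#'
#' @param cluster character vector of gene IDs.
#' @param catalog an [AnnotationCatalog-class].
#' @param background `"universe"` (default; the catalog's gene universe —
#'   the convention that reproduces pathway-table p-values) or
#'   `"network"` (the vertex set of `net`).
#' @param net required when `background = "network"`.
#' @param alpha significance level for the `significant` flag.
#' @param bonferroni if `TRUE`, p-values are multiplied by the number of
#'   terms tested for this cluster (capped at 1) before taking the
#'   minimum; off by default.
#' @return one-row data.frame: `bestTerm`, `n`, `m`, `M`, `N`, `pValue`,
#'   `significant`.  A cluster with no annotated member gets `pValue = 1`
#'   and `bestTerm = NA`.
#' @export
clusterMinPvalue <- function(cluster, catalog,
                             background = c("universe", "network"),
                             net = NULL, alpha = 0.05, bonferroni = FALSE) {
    background <- match.arg(background)
    if (!length(cluster)) stop("empty cluster")
    stopifnot(is(catalog, "AnnotationCatalog"))
    bg <- if (background == "universe") universe(catalog) else {
        if (is.null(net)) stop("background='network' requires 'net'")
        vertices(net)
    }
    N <- length(bg)
    inBg <- intersect(unique(cluster), bg)
    n <- length(inBg)
    terms <- geneSets(catalog)
    m <- vapply(terms, function(g) length(intersect(g, inBg)), integer(1))
    hit <- which(m > 0L)
    if (!length(hit) || n == 0L)
        return(data.frame(bestTerm = NA_character_, n = n, m = 0L,
                          M = NA_integer_, N = N, pValue = 1,
                          significant = FALSE, stringsAsFactors = FALSE))
    M <- vapply(terms[hit], function(g) length(intersect(g, bg)), integer(1))
    p <- hypergeomTail(n, m[hit], M, N)
    if (bonferroni) p <- pmin(1, p * length(hit))
    ## ties go to the first term in catalog order, for determinism
    best <- hit[which.min(p)]
    bi <- which.min(p)
    data.frame(bestTerm = names(terms)[best], n = n, m = m[best],
               M = M[bi], N = N, pValue = p[bi],
               significant = p[bi] < alpha, stringsAsFactors = FALSE)
}

#' Per-cluster significance report
#'
#' One row per cluster of a clustering, mirroring the usual
#' module-enrichment table: cluster ID, best term, cluster size, annotated
#' members, term size, p-value.
#'
#' @inheritParams clusterMinPvalue
#' @param clustering a [Clustering-class].
#' @return data.frame sorted by `pValue`.
#' @export
significanceReport <- function(clustering, catalog,
                               background = c("universe", "network"),
                               net = NULL, alpha = 0.05,
                               bonferroni = FALSE) {
    cl <- clusters(clustering)
    if (!length(cl))
        return(data.frame(clusterId = integer(), bestTerm = character(),
                          n = integer(), m = integer(), M = integer(),
                          N = integer(), pValue = numeric(),
                          significant = logical()))
    rows <- lapply(seq_along(cl), function(i)
        cbind(clusterId = i,
              clusterMinPvalue(cl[[i]], catalog, background, net,
                               alpha, bonferroni)))
    out <- do.call(rbind, rows)
    out[order(out$pValue), , drop = FALSE]
}

#' Clustering score: fraction of significant clusters
#'
#' A cluster is significant when its minimum hypergeometric p-value falls
#' below `alpha`; the score is \eqn{n_S / (n_S + n_I)}, the fraction of
#' significant clusters, in `[0, 1]`.  A clustering with no clusters
#' scores 0.
#'
#' @inheritParams significanceReport
#' @param alpha significance level (default 0.05).
#' @return score in `[0, 1]`.
#' @export
clusteringScore <- function(clustering, catalog, alpha = 0.05,
                            background = c("universe", "network"),
                            net = NULL, bonferroni = FALSE) {
    cl <- clusters(clustering)
    if (!length(cl)) return(0)
    rep <- significanceReport(clustering, catalog, background, net,
                              alpha, bonferroni)
    nS <- sum(rep$pValue < alpha)
    scoreFromCounts(nS, nrow(rep) - nS)
}

#' Clustering score from significance counts
#'
#' The score in its counts form, \eqn{n_S / (n_S + n_I)}: the fraction of
#' clusters found significant.  Zero clusters score 0.
#'
#' @param nSignificant,nInsignificant cluster counts.
#' @return score in `[0, 1]`.
#' @examples
#' scoreFromCounts(97, 61)  # 0.6139...
#' @export
scoreFromCounts <- function(nSignificant, nInsignificant) {
    stopifnot(nSignificant >= 0, nInsignificant >= 0)
    tot <- nSignificant + nInsignificant
    if (tot == 0) return(0)
    nSignificant / tot
}

## genes x terms sparse binary membership matrix
geneTermMatrix <- function(catalog, genes) {
    terms <- geneSets(catalog)
    gi <- unlist(lapply(terms, function(g) match(intersect(g, genes), genes)),
                 use.names = FALSE)
    ti <- rep(seq_along(terms),
              vapply(terms, function(g) length(intersect(g, genes)),
                     integer(1)))
    Matrix::sparseMatrix(i = gi, j = ti, x = 1,
                         dims = c(length(genes), length(terms)),
                         dimnames = list(genes, names(terms)))
}

## dense pairwise annotation-cosine matrix over a gene vector
annotationCosineMatrix <- function(catalog, genes) {
    B <- geneTermMatrix(catalog, genes)
    nrm <- sqrt(Matrix::rowSums(B))
    C <- as.matrix(Matrix::tcrossprod(B))
    denom <- outer(nrm, nrm)
    out <- matrix(0, length(genes), length(genes),
                  dimnames = list(genes, genes))
    pos <- denom > 0
    out[pos] <- C[pos] / denom[pos]
    out
}

#' Annotation cosine similarity between two genes
#'
#' Cosine of the binary annotation vectors induced by the catalog:
#' \eqn{A_i \cdot A_j / (\lVert A_i\rVert\,\lVert A_j\rVert)}, i.e. the
#' number of shared terms over the geometric mean of the term counts.
#' Returns 0 when either gene is unannotated.
#'
#' @param gi,gj gene IDs.
#' @param catalog an [AnnotationCatalog-class].
#' @return similarity in `[0, 1]`.
#' @export
annotationCosine <- function(gi, gj, catalog) {
    terms <- geneSets(catalog)
    ti <- names(terms)[vapply(terms, function(g) gi %in% g, logical(1))]
    tj <- names(terms)[vapply(terms, function(g) gj %in% g, logical(1))]
    if (!length(ti) || !length(tj)) return(0)
    length(intersect(ti, tj)) / sqrt(length(ti) * length(tj))
}

#' Annotation enrichment of a clustering
#'
#' The average annotation-cosine similarity over all unordered pairs that
#' share a cluster (pooled across clusters, so larger clusters weigh
#' more), divided by the average over all unordered vertex pairs of the
#' network.  Unannotated genes participate with similarity 0.  Values
#' above 1 mean co-clustered genes are more functionally coherent than
#' the network at large.
#'
#' @param clustering a [Clustering-class] over `net`.
#' @param net the clustered [InteractionNetwork-class] (>= 2 vertices).
#' @param catalog an [AnnotationCatalog-class].
#' @param cosine optional pre-computed [annotationCosineMatrix] over
#'   `vertices(net)` (internal reuse across an epsilon sweep).
#' @return enrichment ratio >= 0; `NA` when the clustering has no
#'   within-cluster pair.
#' @export
annotationEnrichment <- function(clustering, net, catalog, cosine = NULL) {
    verts <- vertices(net)
    if (length(verts) < 2L) stop("network must have at least two vertices")
    if (is.null(cosine)) cosine <- annotationCosineMatrix(catalog, verts)
    total <- (sum(cosine) - sum(diag(cosine))) / 2
    nPairs <- choose(length(verts), 2)
    denom <- total / nPairs
    if (denom <= 0) stop("no annotated pair in the network")
    cl <- clusters(clustering)
    sizes <- vapply(cl, length, integer(1))
    cl <- cl[sizes >= 2L]
    if (!length(cl)) return(NA_real_)
    num <- 0; cnt <- 0
    for (g in cl) {
        ix <- match(g, verts)
        sub <- cosine[ix, ix, drop = FALSE]
        num <- num + (sum(sub) - sum(diag(sub))) / 2
        cnt <- cnt + choose(length(ix), 2)
    }
    (num / cnt) / denom
}

#' Min-max normalisation of a series
#'
#' Rescales a non-negative series (typically the raw enrichment values
#' along an epsilon grid) to `[0, 1]`: \eqn{(x - \min)/(\max - \min)}.
#' A constant series maps to all zeros; `NA`s are preserved and ignored
#' when locating the extremes.
#'
#' @param values numeric vector.
#' @return numeric vector in `[0, 1]` (with `NA`s where the input had
#'   them).
#' @export
normalizeSeries <- function(values) {
    if (!length(values)) stop("empty series")
    fin <- values[!is.na(values)]
    if (!length(fin)) return(values)
    lo <- min(fin); hi <- max(fin)
    if (hi == lo) return(ifelse(is.na(values), NA_real_, 0))
    (values - lo) / (hi - lo)
}

## integer cluster membership over vertices(net); NA = unclassified
clusterIndex <- function(net, clustering) {
    verts <- vertices(net)
    memb <- rep(NA_integer_, length(verts))
    cl <- clusters(clustering)
    for (i in seq_along(cl)) {
        ix <- match(cl[[i]], verts)
        if (anyNA(ix)) stop("clustering refers to vertices absent from net")
        memb[ix] <- i
    }
    memb
}

#' Newman-style modularity of a clustering
#'
#' \deqn{Q_N = \sum_{s=1}^{NC}\left[\frac{l_s}{L} -
#'   \left(\frac{d_s}{2L}\right)^2\right]}
#' with `L` the edge count of the network, \eqn{l_s} the number of edges
#' within cluster `s`, and \eqn{d_s} the degree sum of its vertices
#' (degrees taken in the full network).  Unclassified (hub/outlier)
#' vertices contribute to `L` and to degrees but belong to no cluster.
#' Grouping everything into a single cluster gives exactly 0, as does a
#' random assignment in expectation; the value can be negative for
#' assignments worse than random.
#'
#' @param net an [InteractionNetwork-class] with at least one edge.
#' @param clustering a [Clustering-class] over `net`.
#' @return modularity value (unclipped).
#' @export
networkModularity <- function(net, clustering) {
    L <- numEdges(net)
    if (L == 0L) stop("modularity undefined on an empty edge set")
    memb <- clusterIndex(net, clustering)
    nc <- length(clusters(clustering))
    if (nc == 0L) return(0)
    verts <- vertices(net)
    e <- edges(net)
    cu <- memb[match(e[, 1L], verts)]
    cv <- memb[match(e[, 2L], verts)]
    within <- !is.na(cu) & !is.na(cv) & cu == cv
    ls <- tabulate(cu[within], nbins = nc)
    deg <- vertexDegree(net)
    ds <- vapply(seq_len(nc), function(i) sum(deg[memb %in% i]), numeric(1))
    sum(ls / L - (ds / (2 * L))^2)
}

#' Similarity-based modularity of a clustering
#'
#' The modularity analogue with edge counts replaced by summed structural
#' similarities, which mitigates the resolution-limit problem of plain
#' modularity:
#' \deqn{Q_S = \sum_{i=1}^{NC}\left[\frac{IS_i}{TS} -
#'   \left(\frac{DS_i}{2\,TS}\right)^2\right]}
#' where \eqn{IS_i} sums \eqn{\sigma(u,v)} over within-cluster edges of
#' cluster `i`, \eqn{DS_i} sums \eqn{\sigma} over all edges incident to
#' the cluster's vertices (each within-cluster edge counted from both
#' ends), and `TS` sums \eqn{\sigma} over every edge of the network.
#' Similarities are taken over adjacent pairs only.  With \eqn{\sigma
#' \equiv 1} the expression reduces exactly to [networkModularity()].
#'
#' @param net an [InteractionNetwork-class] with at least one edge.
#' @param clustering a [Clustering-class] over `net`.
#' @param sigma optional per-edge similarity vector aligned with
#'   `edges(net)` (defaults to [edgeSimilarities()]).
#' @return similarity-based modularity value.
#' @export
similarityModularity <- function(net, clustering, sigma = NULL) {
    if (numEdges(net) == 0L)
        stop("similarity modularity undefined on an empty edge set")
    if (is.null(sigma)) sigma <- edgeSimilarities(net)
    stopifnot(length(sigma) == numEdges(net))
    memb <- clusterIndex(net, clustering)
    nc <- length(clusters(clustering))
    if (nc == 0L) return(0)
    TS <- sum(sigma)
    if (TS <= 0) stop("total structural similarity is zero")
    verts <- vertices(net)
    e <- edges(net)
    ui <- match(e[, 1L], verts); vi <- match(e[, 2L], verts)
    cu <- memb[ui]; cv <- memb[vi]
    within <- !is.na(cu) & !is.na(cv) & cu == cv
    IS <- vapply(seq_len(nc), function(i) sum(sigma[within & cu == i]),
                 numeric(1))
    ## per-vertex incident similarity sums
    vs <- rep(0, length(verts))
    acc <- tapply(c(sigma, sigma), c(ui, vi), sum)
    vs[as.integer(names(acc))] <- as.numeric(acc)
    DS <- vapply(seq_len(nc), function(i) sum(vs[memb %in% i]), numeric(1))
    sum(IS / TS - (DS / (2 * TS))^2)
}
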
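#' @include quality.R
NULL

#' Build an epsilon grid
#'
#' @param start,stop,step grid bounds and spacing; all values must fall in
#'   (0, 1).  The default fine grid 0.01..0.99 resolves optima that a
#'   coarse 0.1-step grid would miss.
#' @return numeric vector of strictly increasing epsilon values.
#' @export
epsilonGrid <- function(start = 0.01, stop = 0.99, step = 0.01) {
    vals <- seq(start, stop, by = step)
    vals <- round(vals, 10)
    if (any(vals <= 0) || any(vals >= 1))
        stop("epsilon grid must lie strictly inside (0, 1)")
    vals
}

#' Sweep SCAN over an epsilon grid and profile clustering quality
#'
#' For each epsilon: run [scanCluster()], then compute modularity,
#' similarity-based modularity, the hypergeometric clustering score and
#' raw annotation enrichment; after the sweep, min-max-normalise the
#' enrichment column over the grid.  Structural similarities and the
#' annotation-cosine matrix are computed once and shared across the grid
#' (neither depends on epsilon).  A measure that fails at some epsilon is
#' recorded as `NA` for that row rather than aborting the sweep.
#'
#' @param net an [InteractionNetwork-class].
#' @param grid numeric vector of epsilon values (see [epsilonGrid()]).
#' @param catalog an [AnnotationCatalog-class].
#' @param mu SCAN core threshold (default 2).
#' @param alpha significance level for the clustering score.
#' @param background background policy for [clusterMinPvalue()].
#' @return a [QualityProfile-class].
#' @export
epsilonSweep <- function(net, grid, catalog, mu = 2L, alpha = 0.05,
                         background = c("universe", "network")) {
    background <- match.arg(background)
    stopifnot(is(net, "InteractionNetwork"),
              is(catalog, "AnnotationCatalog"), length(grid) >= 1L)
    ## epsilon-independent precomputations, shared across the whole grid
    verts <- vertices(net)
    nV <- length(verts)
    e <- edges(net)
    L <- nrow(e)
    sigma <- edgeSimilarities(net)
    adj <- adjacencyIndex(net)
    ui <- match(e[, 1L], verts); vi <- match(e[, 2L], verts)
    deg <- unname(vertexDegree(net))
    vsig <- rep(0, nV)                       # incident-sigma sums
    if (L) {
        acc <- tapply(c(sigma, sigma), c(ui, vi), sum)
        vsig[as.integer(names(acc))] <- as.numeric(acc)
    }
    TS <- sum(sigma)
    bg <- if (background == "universe") universe(catalog) else verts
    N <- length(bg)
    inBg <- verts %in% bg
    B <- geneTermMatrix(catalog, verts)      # vertices x terms incidence
    Mvec <- vapply(geneSets(catalog), function(g)
        length(intersect(g, bg)), integer(1))
    cosine <- if (nV >= 2L) annotationCosineMatrix(catalog, verts) else NULL
    cosTotal <- if (is.null(cosine)) NA_real_ else
        (sum(cosine) - sum(diag(cosine))) / 2
    netMean <- if (is.null(cosine)) NA_real_ else cosTotal / choose(nV, 2)

    rows <- lapply(grid, function(eps) {
        cl <- scanCluster(net, eps, mu, sigma = sigma, adj = adj)
        idx <- lapply(clusters(cl), match, verts)
        sizes <- lengths(idx)
        nc <- length(idx)
        qN <- qS <- 0
        score <- if (nc) NA_real_ else 0
        enrich <- NA_real_
        if (nc && L) {
            memb <- rep(NA_integer_, nV)
            for (i in seq_len(nc)) memb[idx[[i]]] <- i
            cu <- memb[ui]; cv <- memb[vi]
            within <- !is.na(cu) & !is.na(cv) & cu == cv
            ls <- tabulate(cu[within], nbins = nc)
            ds <- vapply(seq_len(nc), function(i)
                sum(deg[idx[[i]]]), numeric(1))
            qN <- sum(ls / L - (ds / (2 * L))^2)
            IS <- vapply(seq_len(nc), function(i)
                sum(sigma[within & cu == i]), numeric(1))
            DS <- vapply(seq_len(nc), function(i)
                sum(vsig[idx[[i]]]), numeric(1))
            qS <- if (TS > 0) sum(IS / TS - (DS / (2 * TS))^2) else NA_real_
            ## hypergeometric clustering score
            minp <- vapply(idx, function(ix) {
                n <- sum(inBg[ix])
                if (n == 0L) return(1)
                m <- Matrix::colSums(B[ix, , drop = FALSE])
                hit <- m > 0 & Mvec > 0
                if (!any(hit)) return(1)
                min(hypergeomTail(n, m[hit], Mvec[hit], N))
            }, numeric(1))
            score <- mean(minp < alpha)
            ## pooled within-cluster annotation cosine vs network mean
            if (!is.null(cosine) && netMean > 0) {
                num <- 0; cnt <- 0
                for (ix in idx[sizes >= 2L]) {
                    sub <- cosine[ix, ix, drop = FALSE]
                    num <- num + (sum(sub) - sum(diag(sub))) / 2
                    cnt <- cnt + choose(length(ix), 2)
                }
                if (cnt > 0) enrich <- (num / cnt) / netMean
            }
        }
        data.frame(
            epsilon = eps,
            nClusters = nc,
            nClustered = sum(sizes),
            maxClusterSize = if (nc) max(sizes) else 0L,
            qN = qN, qS = qS, clusteringScore = score,
            enrichmentRaw = enrich)
    })
    rows <- do.call(rbind, rows)
    rows$enrichmentNorm <- normalizeSeries(rows$enrichmentRaw)
    k <- if (is(net, "IntegratedNetwork")) net@k else NA_integer_
    new("QualityProfile", networkName = networkName(net), k = k,
        rows = rows)
}

#' @rdname accessors
setMethod("profileRows", "QualityProfile", function(x) x@rows)

setMethod("show", "QualityProfile", function(object) {
    cat(sprintf("QualityProfile of '%s'%s: %d epsilon values in [%.3g, %.3g]\n",
                object@networkName,
                if (is.na(object@k)) "" else sprintf(" (k=%d)", object@k),
                nrow(object@rows), min(object@rows$epsilon),
                max(object@rows$epsilon)))
})

#' Detect a non-edge (interior) optimum in a quality series
#'
#' A quality measure "possesses an optimum" when its maximum over the
#' interior of the epsilon grid — excluding the first and last
#' `boundaryFraction` of grid points, since epsilon values close to 0 or
#' 1 yield only trivial modules — is a strict local maximum and strictly
#' exceeds every value in the excluded boundary regions.  Because nearby
#' epsilon values often produce the *same* clustering on a discrete
#' network, consecutive equal values are collapsed into runs first: a run
#' is a strict local maximum when both flanking runs are lower, and the
#' reported argmax is the smallest epsilon of the run (ties toward the
#' smallest epsilon).  Downtrending, uptrending and flat series therefore
#' have no optimum.  `NA` values mark epsilon values with no meaningful
#' clustering (failed or trivial rows): a missing run can never host an
#' optimum, and a peak flanked by a missing run is not accepted either —
#' an optimum must be supported by meaningful clusterings on both sides.
#' The verdict is invariant to positive affine transformation of the
#' values.
#'
#' A detected optimum must additionally be *prominent*: the peak value
#' has to clear the values at both ends of the meaningful window (the
#' first and last non-missing runs) by at least `prominence` times the
#' window's value range.  This separates a genuine interior maximum from
#' sampling jitter riding on an up- or downtrend, which on a fine grid
#' otherwise produces spurious one-step local maxima.
#'
#' @param epsilon increasing numeric vector (>= 5 points).
#' @param values numeric vector aligned with `epsilon`.
#' @param boundaryFraction fraction of grid points excluded at each end
#'   (default 0.1); at least one point is always excluded per side.
#' @param prominence required clearance over the window-edge values, as a
#'   fraction of the window's value range (default 0.1).
#' @return list with `present` (logical) and `argmax` (epsilon of the
#'   optimum, or `NA`).
#' @export
detectInteriorOptimum <- function(epsilon, values, boundaryFraction = 0.1,
                                  prominence = 0.1) {
    n <- length(values)
    if (n < 5L) stop("need at least 5 grid points")
    stopifnot(length(epsilon) == n, !is.unsorted(epsilon, strictly = TRUE),
              boundaryFraction > 0, boundaryFraction < 0.5,
              prominence >= 0, prominence < 1)
    v <- ifelse(is.na(values), -Inf, values)
    nExcl <- max(1L, floor(n * boundaryFraction))
    interior <- (nExcl + 1L):(n - nExcl)
    i <- interior[which.max(v[interior])]   # first index on ties
    if (!is.finite(v[i]))
        return(list(present = FALSE, argmax = NA_real_))
    ## collapse the plateau (run of equal values) containing i
    lo <- i; hi <- i
    while (lo > 1L && v[lo - 1L] == v[i]) lo <- lo - 1L
    while (hi < n && v[hi + 1L] == v[i]) hi <- hi + 1L
    strictLocal <- lo > 1L && hi < n &&
        is.finite(v[lo - 1L]) && is.finite(v[hi + 1L]) &&
        v[i] > v[lo - 1L] && v[i] > v[hi + 1L]
    outside <- v[setdiff(c(seq_len(nExcl), (n - nExcl + 1L):n), lo:hi)]
    beatsBoundary <- !length(outside) || all(v[i] > outside)
    ## prominence over the meaningful window's edge values
    win <- which(is.finite(v))
    vmin <- min(v[win]); rng <- v[i] - vmin
    edgeHi <- max(v[win[1L]], v[win[length(win)]])
    prominent <- rng > 0 && (v[i] - edgeHi) >= prominence * rng
    if (strictLocal && beatsBoundary && prominent)
        list(present = TRUE, argmax = epsilon[lo])
    else list(present = FALSE, argmax = NA_real_)
}

#' Select the consensus level from a presence matrix
#'
#' The decision rule applied to the Table-2-style presence flags: the
#' chosen k is the smallest k whose profile shows at least one
#' statistical optimum (modularity or similarity-based modularity) AND
#' both biological optima (clustering score and enrichment).  If no k
#' qualifies, the k with the largest number of present optima wins,
#' smallest k on ties.
#'
#' @param presence data.frame with columns `k`, `optQN`, `optQS`,
#'   `optScore`, `optEnrich` (logical flags).
#' @return list with `chosenK` and `rationale`.
#' @export
selectConsensusK <- function(presence) {
    stopifnot(all(c("k", "optQN", "optQS", "optScore", "optEnrich") %in%
                  names(presence)))
    presence <- presence[order(presence$k), , drop = FALSE]
    qualifies <- (presence$optQN | presence$optQS) &
        presence$optScore & presence$optEnrich
    if (any(qualifies)) {
        k <- presence$k[which(qualifies)[1L]]
        return(list(chosenK = as.integer(k), rationale = sprintf(
            "k=%d is the smallest consensus level with a statistical optimum (modularity or similarity-based modularity) and both biological optima (clustering score and enrichment)",
            k)))
    }
    counts <- presence$optQN + presence$optQS + presence$optScore +
        presence$optEnrich
    k <- presence$k[which.max(counts)]   # smallest k on ties
    list(chosenK = as.integer(k), rationale = sprintf(
        "no consensus level shows both statistical and biological optima; k=%d maximises the number of present optima (%d of 4, smallest k on ties)",
        k, max(counts)))
}

#' Evaluate every consensus level of an ensemble
#'
#' The full selection framework: for each `k = 1..n`, build the k-votes
#' integrated network, sweep SCAN over the epsilon grid, profile the four
#' quality measures, and test each for an interior optimum; then select
#' the consensus level with [selectConsensusK()].  A `k` whose integrated
#' network has no edges is recorded with zero counts and all-false
#' presence flags rather than aborting (sparse high-k networks are
#' expected).
#'
#' Epsilon values yielding only trivial clusterings are not considered
#' when locating optima: a row is trivial when it has fewer than two
#' clusters, when its largest cluster swallows more than
#' `trivialDominance` of the network's vertices (the all-vertices-in-one-
#' module regime where modularity degenerates to 0), or when fewer than
#' `trivialMinClustered` of the vertices are clustered at all (only
#' fragments remain).  Trivial rows are masked as missing before
#' [detectInteriorOptimum()], which also refuses peaks adjacent to masked
#' rows, so an optimum must sit inside a window of meaningful
#' clusterings.  In addition, a network whose non-trivial window covers
#' less than `minWindowFraction` of the grid is declared optimum-free for
#' all four measures: a transient flicker of small clusters while a
#' hairball collapses is not convergence to an optimal epsilon.
#'
#' @param ensemble a [NetworkEnsemble-class] with >= 2 members.
#' @param grid epsilon grid (see [epsilonGrid()]).
#' @param catalog an [AnnotationCatalog-class].
#' @param mu SCAN core threshold.
#' @param alpha significance level for the clustering score.
#' @param boundaryFraction see [detectInteriorOptimum()].
#' @param trivialDominance largest-cluster fraction above which a
#'   clustering is trivial (default 0.9).
#' @param trivialMinClustered minimum fraction of vertices that must be
#'   clustered for a non-trivial row (default 0.05).
#' @param minWindowFraction minimum fraction of grid points that must be
#'   non-trivial before optima are interpreted (default 0.25).
#' @param prominence see [detectInteriorOptimum()].
#' @param background background policy for the clustering score.
#' @param verbose log one line per k to `message()`.
#' @return a [KSelection-class].
#' @export
evaluateKRange <- function(ensemble, grid = epsilonGrid(), catalog,
                           mu = 2L, alpha = 0.05, boundaryFraction = 0.1,
                           trivialDominance = 0.9,
                           trivialMinClustered = 0.05,
                           minWindowFraction = 0.25, prominence = 0.1,
                           background = c("universe", "network"),
                           verbose = FALSE) {
    background <- match.arg(background)
    stopifnot(is(ensemble, "NetworkEnsemble"), ensembleSize(ensemble) >= 2L)
    n <- ensembleSize(ensemble)
    votes <- countVotes(ensemble)
    profiles <- vector("list", n)
    rows <- vector("list", n)
    for (k in seq_len(n)) {
        g <- integrateKVotes(ensemble, k, votes = votes)
        if (verbose)
            message(sprintf("k=%d: %d vertices, %d edges", k,
                            numVertices(g), numEdges(g)))
        if (numEdges(g) == 0L) {
            rows[[k]] <- data.frame(k = k, nNodes = 0L, nEdges = 0L,
                optQN = FALSE, optQS = FALSE, optScore = FALSE,
                optEnrich = FALSE, epsQN = NA_real_, epsQS = NA_real_,
                epsScore = NA_real_, epsEnrich = NA_real_)
            next
        }
        prof <- epsilonSweep(g, grid, catalog, mu = mu, alpha = alpha,
                             background = background)
        profiles[[k]] <- prof
        pr <- profileRows(prof)
        nV <- numVertices(g)
        trivial <- pr$nClusters < 2L |
            pr$maxClusterSize > trivialDominance * nV |
            pr$nClustered < trivialMinClustered * nV
        windowOk <- mean(!trivial) >= minWindowFraction
        det <- lapply(pr[c("qN", "qS", "clusteringScore", "enrichmentNorm")],
                      function(v) {
                          if (!windowOk)
                              return(list(present = FALSE,
                                          argmax = NA_real_))
                          v[trivial] <- NA_real_
                          detectInteriorOptimum(pr$epsilon, v,
                                                boundaryFraction,
                                                prominence)
                      })
        rows[[k]] <- data.frame(k = k, nNodes = numVertices(g),
            nEdges = numEdges(g),
            optQN = det$qN$present, optQS = det$qS$present,
            optScore = det$clusteringScore$present,
            optEnrich = det$enrichmentNorm$present,
            epsQN = det$qN$argmax, epsQS = det$qS$argmax,
            epsScore = det$clusteringScore$argmax,
            epsEnrich = det$enrichmentNorm$argmax)
    }
    summary <- do.call(rbind, rows)
    sel <- selectConsensusK(summary)
    new("KSelection", summary = summary, profiles = profiles,
        chosenK = sel$chosenK, rationale = sel$rationale)
}

#' @rdname accessors
setMethod("chosenK", "KSelection", function(x) x@chosenK)

#' @rdname accessors
#' @export
kSummary <- function(x) x@summary

#' @rdname accessors
#' @export
kProfiles <- function(x) x@profiles

#' @rdname accessors
#' @export
selectionRationale <- function(x) x@rationale

setMethod("show", "KSelection", function(object) {
    cat("KSelection over", nrow(object@summary), "consensus levels\n")
    print(object@summary, row.names = FALSE)
    cat("chosen k:", object@chosenK, "\n")
    cat(strwrap(object@rationale, width = 78), sep = "\n")
})

#' Write a KSelection report (JSON plus flat CSV)
#'
#' JSON carries per-k blocks: node/edge counts, presence flags, argmax
#' epsilons, and the full per-epsilon profile; the CSV flattens every
#' profile row for plotting.
#'
#' @param selection a [KSelection-class].
#' @param jsonPath,csvPath output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
writeKSelectionReport <- function(selection, jsonPath = NULL,
                                  csvPath = NULL) {
    flat <- do.call(rbind, lapply(selection@profiles, function(p) {
        if (is.null(p)) return(NULL)
        cbind(k = p@k, network = p@networkName, profileRows(p))
    }))
    if (!is.null(jsonPath)) {
        payload <- list(summary = kSummary(selection),
                        chosenK = chosenK(selection),
                        rationale = selectionRationale(selection),
                        profiles = flat)
        jsonlite::write_json(payload, jsonPath, dataframe = "rows",
                             auto_unbox = TRUE, digits = NA, na = "null")
    }
    if (!is.null(csvPath) && !is.null(flat))
        write.table(flat, csvPath, sep = ",", quote = FALSE,
                    row.names = FALSE)
    invisible(list(json = jsonPath, csv = csvPath))
}
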
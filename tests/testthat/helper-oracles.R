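## Shared fixtures and independent brute-force oracles.

## all unordered pairs of a clique over the given IDs
cliquePairs <- function(ids) t(combn(ids, 2))

## quick network from a 2-column matrix of endpoints
netFromPairs <- function(pairs, name = "net", vertices = NULL)
    interactionNetwork(pairs[, 1], pairs[, 2], name = name,
                       vertices = vertices)

## the three-member toy committee used throughout the integration tests
toyEnsemble <- function() {
    networkEnsemble(
        interactionNetwork(c("a", "b"), c("b", "c"), name = "E1"),
        interactionNetwork(c("a", "c"), c("b", "d"), name = "E2"),
        interactionNetwork(c("a", "b", "d"), c("b", "c", "e"), name = "E3"))
}

## Erdos-Renyi random network on nv vertices
randomNetwork <- function(nv, p, seed, prefix = "v") {
    verts <- sprintf("%s%03d", prefix, seq_len(nv))
    pairs <- cliquePairs(verts)
    set.seed(seed)
    keep <- runif(nrow(pairs)) < p
    interactionNetwork(pairs[keep, 1], pairs[keep, 2], vertices = verts)
}

## ---- brute-force SCAN oracle: materialises the full sigma matrix and
## computes structure reachability by naive closure.  Shares nothing with
## the package implementation beyond the edge list.
bruteScan <- function(net, eps, mu = 2) {
    verts <- vertices(net)
    n <- length(verts)
    A <- matrix(FALSE, n, n)
    e <- edges(net)
    for (r in seq_len(nrow(e))) {
        i <- match(e[r, 1], verts); j <- match(e[r, 2], verts)
        A[i, j] <- TRUE; A[j, i] <- TRUE
    }
    closed <- lapply(seq_len(n), function(i) sort(c(i, which(A[i, ]))))
    S <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        S[i, j] <- length(intersect(closed[[i]], closed[[j]])) /
            sqrt(length(closed[[i]]) * length(closed[[j]]))
    Neps <- lapply(seq_len(n), function(i)
        Filter(function(j) (i == j || A[i, j]) && S[i, j] >= eps,
               seq_len(n)))
    core <- vapply(Neps, length, integer(1)) >= mu
    ## components of the core graph under direct reachability
    reach <- matrix(FALSE, n, n)
    for (i in which(core)) for (j in Neps[[i]])
        if (core[j]) reach[i, j] <- TRUE
    comp <- seq_len(n); comp[!core] <- NA_integer_
    repeat {
        changed <- FALSE
        for (i in which(core)) for (j in which(core))
            if (reach[i, j] && comp[j] != comp[i]) {
                m <- min(comp[i], comp[j])
                comp[comp %in% c(comp[i], comp[j])] <- m
                changed <- TRUE
            }
        if (!changed) break
    }
    ## borders: non-core in some core's eps-neighbourhood; smallest core wins
    for (j in which(!core)) {
        reachers <- Filter(function(i) core[i] && j %in% Neps[[i]],
                           seq_len(n))
        if (length(reachers)) comp[j] <- comp[min(reachers)]
    }
    memberIdx <- which(!is.na(comp))
    clusters <- split(memberIdx, comp[memberIdx])
    clusters <- clusters[order(vapply(clusters, min, integer(1)))]
    clusters <- lapply(unname(clusters), function(ix) verts[ix])
    rest <- setdiff(seq_len(n), memberIdx)
    labels <- setNames(character(), character())
    clusterOf <- rep(NA_integer_, n)
    for (ci in seq_along(clusters))
        clusterOf[match(clusters[[ci]], verts)] <- ci
    for (i in rest) {
        nb <- unique(clusterOf[which(A[i, ])])
        nb <- nb[!is.na(nb)]
        labels[verts[i]] <- if (length(nb) >= 2) "hub" else "outlier"
    }
    if (length(labels)) labels <- labels[order(names(labels))]
    list(clusters = clusters, unclassified = labels)
}

## compare a package Clustering with the brute oracle result
expectScanMatchesOracle <- function(net, eps, mu = 2) {
    got <- scanCluster(net, eps, mu)
    want <- bruteScan(net, eps, mu)
    expect_identical(clusters(got), want$clusters)
    gotLab <- unclassified(got); wantLab <- want$unclassified
    expect_identical(sort(paste(names(gotLab), gotLab)),
                     sort(paste(names(wantLab), wantLab)))
}

## ---- hypergeometric upper tail by direct factorial summation
bruteTail <- function(n, m, M, N) {
    i <- seq(from = m, to = min(n, M))
    if (m == 0 && length(i) == 0) return(1)
    sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

## random disjoint partition of a network's vertices into >= 2-member
## clusters plus leftover outliers, as a Clustering object
randomClustering <- function(net, nClusters, seed) {
    set.seed(seed)
    verts <- sample(vertices(net))
    sizes <- rep(2L, nClusters)
    extra <- length(verts) - sum(sizes)
    if (extra < 0) stop("too many clusters for this network")
    if (extra > 0 && nClusters > 0) {
        add <- table(sample.int(nClusters, max(0, extra - 1),
                                replace = TRUE))
        sizes[as.integer(names(add))] <- sizes[as.integer(names(add))] +
            as.integer(add)
    }
    cl <- split(verts[seq_len(sum(sizes))],
                rep(seq_len(nClusters), sizes))
    leftover <- verts[-seq_len(sum(sizes))]
    uncl <- setNames(rep("outlier", length(leftover)), leftover)
    clustering(unname(cl), unclassified = uncl, networkRef = networkName(net))
}
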
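makeCatalog <- function(...) annotationCatalog(list(...))

test_that("GMT files round-trip and are validated", {
    f <- withr::local_tempfile()
    writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg3\tg4"), f)
    cat <- readGmt(f)
    expect_length(geneSets(cat), 2L)
    expect_setequal(universe(cat), paste0("g", 1:4))
    f2 <- withr::local_tempfile()
    writeGmt(cat, f2)
    expect_identical(geneSets(readGmt(f2)), geneSets(cat))
    writeLines(c("setA\tdesc\tg1", "setA\tdesc\tg2"), f)
    expect_error(readGmt(f), "duplicate term names")
    writeLines(c("setA\tdesc\tg1", "empty\tdesc"), f)
    expect_warning(cat2 <- readGmt(f), "no genes")
    expect_length(geneSets(cat2), 1L)
    writeLines(character(), f)
    expect_error(readGmt(f), "empty GMT")
})

test_that("hypergeometric tails match the published module p-values", {
    ## background: the 5197-gene pathway universe
    expect_equal(hypergeomTail(10, 10, 29, 5197), 5.10e-24,
                 tolerance = 1e-2)
    expect_equal(hypergeomTail(17, 12, 48, 5197), 5.22e-22,
                 tolerance = 1e-2)
    expect_equal(hypergeomTail(12, 11, 114, 5197), 4.09e-18,
                 tolerance = 1e-2)
    expect_equal(hypergeomTail(5, 0, 10, 100), 1)
    expect_error(hypergeomTail(5, 6, 10, 100), "require")
    expect_error(hypergeomTail(5, 2, 101, 100), "require")
})

test_that("hypergeomTail agrees with direct factorial enumeration and is monotone", {
    for (N in c(8, 15, 23, 30)) {
        for (M in 0:N) for (n in 0:N) {
            ms <- 0:min(n, M)
            got <- hypergeomTail(n, ms, M, N)
            want <- vapply(ms, bruteTail, numeric(1), n = n, M = M, N = N)
            expect_equal(got, want, tolerance = 1e-12)
            expect_true(all(diff(got) <= 1e-12))
        }
    }
})

test_that("cluster minimum p-values find the best term", {
    ## a 29-gene term inside a 5197-gene universe, cluster fully annotated
    genes <- sprintf("e%04d", 1:5197)
    cat <- makeCatalog(path = genes[1:29], rest = genes[30:5197])
    sig <- clusterMinPvalue(genes[1:10], cat)
    expect_identical(sig$bestTerm, "path")
    expect_equal(sig$m, 10L)
    expect_equal(sig$pValue, 5.10e-24, tolerance = 1e-2)
    expect_true(sig$significant)
    ## a cluster with no annotated member
    none <- clusterMinPvalue(c("zz1", "zz2"), cat)
    expect_equal(none$pValue, 1)
    expect_false(none$significant)
    expect_true(is.na(none$bestTerm))
})

test_that("minimum p-values match exhaustive enumeration on small catalogs", {
    for (seed in 1:10) {
        set.seed(seed)
        genes <- sprintf("g%02d", 1:25)
        terms <- lapply(1:4, function(i) sample(genes, sample(3:10, 1)))
        names(terms) <- paste0("t", 1:4)
        cat <- annotationCatalog(terms)
        cluster <- sample(universe(cat), 6)
        got <- clusterMinPvalue(cluster, cat)
        bg <- universe(cat)
        inBg <- intersect(cluster, bg)
        ps <- vapply(terms, function(g) {
            m <- length(intersect(g, inBg))
            if (m == 0) return(NA_real_)
            bruteTail(length(inBg), m, length(intersect(g, bg)), length(bg))
        }, numeric(1))
        expect_equal(got$pValue, min(ps, na.rm = TRUE), tolerance = 1e-12)
    }
})

test_that("network background changes N as documented", {
    net <- interactionNetwork(c("g1", "g2"), c("g2", "g3"))
    cat <- makeCatalog(t1 = c("g1", "g2", "g9", "g8"))
    u <- clusterMinPvalue(c("g1", "g2"), cat, background = "universe")
    expect_equal(u$N, 4L)
    expect_equal(u$n, 2L)   # members present in the universe
    nw <- clusterMinPvalue(c("g1", "g2"), cat, background = "network",
                           net = net)
    expect_equal(nw$N, 3L)
    expect_equal(nw$M, 2L)  # term members present in the network
})

test_that("clustering score is the fraction of significant clusters", {
    expect_equal(scoreFromCounts(97, 61), 97 / 158)
    expect_equal(round(scoreFromCounts(97, 61), 4), 0.6139)
    expect_equal(scoreFromCounts(0, 5), 0)
    expect_equal(scoreFromCounts(3, 0), 1)
    genes <- sprintf("e%04d", 1:500)
    cat <- makeCatalog(a = genes[1:20], b = genes[21:40],
                       rest = genes[41:500])
    cl <- clustering(list(genes[1:10], genes[21:30]))
    expect_equal(clusteringScore(cl, cat), 1)
    junk <- clustering(list(c("x1", "x2"), c("x3", "x4")))
    expect_equal(clusteringScore(junk, cat), 0)
    empty <- clustering(list(), unclassified = c(x1 = "outlier"))
    expect_equal(clusteringScore(empty, cat), 0)
})

test_that("annotation cosine follows the binary-vector definition", {
    cat <- makeCatalog(t1 = c("a", "b"), t2 = c("a", "c"),
                       t3 = c("b", "d"))
    expect_equal(annotationCosine("a", "a", cat), 1)
    expect_equal(annotationCosine("c", "d", cat), 0)   # disjoint terms
    ## a in {t1,t2}, b in {t1,t3}: 1/sqrt(2*2)
    expect_equal(annotationCosine("a", "b", cat), 0.5)
    expect_equal(annotationCosine("a", "unannotated", cat), 0)
})

test_that("modularity reproduces closed forms", {
    twoTri <- interactionNetwork(c("a", "a", "b", "x", "x", "y"),
                                 c("b", "c", "c", "y", "z", "z"))
    asCliques <- clustering(list(c("a", "b", "c"), c("x", "y", "z")))
    expect_equal(networkModularity(twoTri, asCliques), 0.5)
    allInOne <- clustering(list(vertices(twoTri)))
    expect_equal(networkModularity(twoTri, allInOne), 0)
    expect_equal(similarityModularity(twoTri, allInOne), 0)
    ## inside disjoint triangles every sigma is 1, so Q_S = Q_N there
    expect_equal(similarityModularity(twoTri, asCliques), 0.5)
    empty <- interactionNetwork(vertices = c("a", "b"))
    expect_error(networkModularity(empty, allInOne), "empty edge set")
})

test_that("Q_S with unit similarity reduces exactly to Q_N", {
    for (seed in 1:20) {
        net <- randomNetwork(12, 0.35, seed + 100)
        if (numEdges(net) == 0) next
        cl <- randomClustering(net, sample(2:4, 1), seed)
        expect_equal(similarityModularity(net, cl,
                                          sigma = rep(1, numEdges(net))),
                     networkModularity(net, cl), tolerance = 1e-12)
    }
})

test_that("random assignments have modularity near zero on average", {
    ## the finite-size bias of E[Q_N] decays like 1/(n-1); at n=100 it is
    ## below 0.01, so the random-assignment mean should sit near zero
    net <- randomNetwork(100, 0.08, 11)
    qs <- vapply(1:150, function(s)
        networkModularity(net, randomClustering(net, 4, s)), numeric(1))
    expect_lt(abs(mean(qs)), 0.02)
})

test_that("enrichment compares within-cluster to network-wide similarity", {
    genes <- sprintf("g%02d", 1:12)
    cat <- makeCatalog(t1 = genes[1:6], t2 = genes[7:12])
    net <- netFromPairs(rbind(cliquePairs(genes[1:6]),
                              cliquePairs(genes[7:12])))
    allInOne <- clustering(list(genes))
    expect_equal(annotationEnrichment(allInOne, net, cat), 1)
    blocks <- clustering(list(genes[1:6], genes[7:12]))
    e <- annotationEnrichment(blocks, net, cat)
    ## each block is annotation-pure: within mean 1; network mean < 1
    netMean <- (2 * choose(6, 2)) / choose(12, 2)
    expect_equal(e, 1 / netMean)
    expect_gt(e, 1)
    bare <- makeCatalog(t1 = c("zz1", "zz2"))
    expect_error(annotationEnrichment(blocks, net, bare),
                 "no annotated pair")
})

test_that("random clusterings have enrichment near one on average", {
    net <- randomNetwork(20, 0.4, 5)
    genes <- vertices(net)
    set.seed(3)
    terms <- lapply(1:4, function(i) sample(genes, 8))
    names(terms) <- paste0("t", 1:4)
    cat <- annotationCatalog(terms)
    es <- vapply(1:150, function(s)
        annotationEnrichment(randomClustering(net, 4, s), net, cat),
        numeric(1))
    expect_lt(abs(mean(es) - 1), 0.05)
})

test_that("min-max normalisation is bounded, order-preserving, NA-safe", {
    expect_equal(normalizeSeries(c(2, 4, 6)), c(0, 0.5, 1))
    expect_equal(normalizeSeries(c(3, 3, 3)), c(0, 0, 0))
    expect_equal(normalizeSeries(c(1, NA, 3)), c(0, NA, 1))
    for (seed in 1:10) {
        set.seed(seed)
        x <- runif(20, 0, 10)
        y <- normalizeSeries(x)
        expect_true(all(y >= 0 & y <= 1))
        expect_identical(order(x), order(y))
    }
})
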
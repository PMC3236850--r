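test_that("degenerate probabilities give cliques or nothing", {
    two <- plantedPartition(c(4L, 4L), pIn = 1, pOut = 0, seed = 1)
    expect_equal(numEdges(truthNetwork(two)), 12L)   # 2 * C(4,2)
    mods <- truthModules(two)
    expect_length(mods, 2L)
    for (m in mods)
        expect_true(all(hasEdge(truthNetwork(two),
                                cliquePairs(m)[, 1], cliquePairs(m)[, 2])))
    none <- plantedPartition(c(4L, 4L), pIn = 0, pOut = 0, seed = 1)
    expect_equal(numEdges(truthNetwork(none)), 0L)
    expect_error(plantedPartition(c(4L, 4L), pIn = 1.5, pOut = 0, seed = 1),
                 "probabilities")
    expect_error(plantedPartition(c(1L, 4L), 0.5, 0, 1), "sizes")
})

test_that("fixed seeds reproduce networks bit-identically; modules partition", {
    a <- plantedPartition(rep(10L, 3), 0.4, 0.02, seed = 7)
    b <- plantedPartition(rep(10L, 3), 0.4, 0.02, seed = 7)
    expect_identical(edges(truthNetwork(a)), edges(truthNetwork(b)))
    c <- plantedPartition(rep(10L, 3), 0.4, 0.02, seed = 8)
    expect_false(identical(edges(truthNetwork(a)), edges(truthNetwork(c))))
    expect_setequal(unlist(truthModules(a)), vertices(truthNetwork(a)))
})

test_that("edge counts match the binomial expectation", {
    counts <- vapply(1:50, function(s)
        numEdges(truthNetwork(plantedPartition(c(50L, 50L), 0.3, 0.01,
                                               seed = s))), numeric(1))
    expected <- 2 * choose(50, 2) * 0.3 + 2500 * 0.01
    varPer <- 2 * choose(50, 2) * 0.3 * 0.7 + 2500 * 0.01 * 0.99
    se <- sqrt(varPer / 50)
    expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("noiseless observation is the truth; zero sensitivity is empty", {
    truth <- plantedPartition(rep(8L, 3), 0.5, 0.01, seed = 3)
    same <- observeDatabase(truth, sensitivity = 1, fpRate = 0, seed = 1)
    expect_identical(edges(same), edges(truthNetwork(truth)))
    gone <- observeDatabase(truth, sensitivity = 0, fpRate = 0, seed = 1)
    expect_equal(numEdges(gone), 0L)
})

test_that("observation recall matches its binomial expectation", {
    truth <- plantedPartition(c(15L, 15L), 0.5, 0.05, seed = 11)
    E <- numEdges(truthNetwork(truth))
    trueKeys <- ConsensusPPI:::edgeKeys(truthNetwork(truth))
    hits <- vapply(1:100, function(s) {
        obs <- observeDatabase(truth, 0.8, 0, seed = s)
        sum(ConsensusPPI:::edgeKeys(obs) %in% trueKeys)
    }, numeric(1))
    se <- sqrt(E * 0.8 * 0.2 / 100)
    expect_lt(abs(mean(hits) - 0.8 * E), 3 * se)
})

test_that("ensembles carry db names and recover the degenerate cases", {
    truth <- plantedPartition(rep(8L, 2), 1, 0, seed = 5)
    ens <- makeEnsemble(truth, n = 3, sensitivity = 1, fpRate = 0)
    expect_identical(ensembleNames(ens), c("db1", "db2", "db3"))
    for (k in 1:3)
        expect_identical(edges(integrateKVotes(ens, k)),
                         edges(truthNetwork(truth)))
    one <- makeEnsemble(truth, n = 1, sensitivity = 0.7, fpRate = 0,
                        seed = 9)
    expect_identical(edges(integrateKVotes(one, 1)),
                     edges(ensembleMember(one, 1)))
})

test_that("the false-positive fraction converts to a sensible per-pair rate", {
    truth <- plantedPartition(rep(10L, 4), 0.5, 0.01, seed = 2)
    expect_equal(fpRateForFraction(truth, 0.6, 0), 0)
    r <- fpRateForFraction(truth, 0.6, 0.3)
    nNon <- choose(40, 2) - numEdges(truthNetwork(truth))
    expFalse <- r * nNon
    expTrue <- 0.6 * numEdges(truthNetwork(truth))
    expect_equal(expFalse / (expFalse + expTrue), 0.3, tolerance = 1e-10)
})

test_that("pure annotations make every true module maximally significant", {
    truth <- plantedPartition(rep(10L, 4), 0.6, 0.01, seed = 13)
    cat <- synthAnnotations(truth, purity = 1, nBackgroundTerms = 0L,
                            seed = 1)
    expect_setequal(universe(cat), vertices(truthNetwork(truth)))
    mods <- truthModules(truth)
    for (m in mods) {
        sig <- clusterMinPvalue(m, cat)
        term <- geneSets(cat)[[sig$bestTerm]]
        expect_true(all(m %in% term))
        ## the pure-overlap closed form of the tail
        expect_equal(sig$pValue,
                     bruteTail(length(m), length(m), length(term),
                               length(universe(cat))), tolerance = 1e-9)
    }
    trueClusters <- clustering(unname(mods))
    expect_equal(clusteringScore(trueClusters, cat), 1)
})

test_that("random-ish annotation gives enrichment near one for random clusters", {
    truth <- plantedPartition(rep(10L, 4), 0.5, 0.02, seed = 21)
    net <- truthNetwork(truth)
    cat <- synthAnnotations(truth, purity = 0.5, termSize = 15,
                            nBackgroundTerms = 6L, seed = 2)
    es <- vapply(1:60, function(s)
        annotationEnrichment(randomClustering(net, 4, s), net, cat),
        numeric(1))
    expect_lt(abs(mean(es) - 1), 0.1)
})

test_that("SCAN recovers noiseless planted modules exactly (ARI 1)", {
    skip_if_not_installed("mclust")
    truth <- plantedPartition(pIn = 1, pOut = 0, seed = 4)
    cl <- scanCluster(truthNetwork(truth), 0.7, 2)
    expect_length(unclassified(cl), 0L)
    want <- rep(seq_along(truthModules(truth)),
                lengths(truthModules(truth)))
    names(want) <- unlist(truthModules(truth))
    got <- membershipVector(cl)
    ari <- mclust::adjustedRandIndex(got, want[names(got)])
    expect_equal(ari, 1)
})

test_that("simulateStudy writes the documented files and is reproducible", {
    dir <- withr::local_tempdir()
    sim <- simulateStudy(moduleSizes = rep(8L, 3), nDatabases = 3,
                         seed = 6, outDir = dir)
    expect_true(all(file.exists(file.path(dir,
        c("truth.tsv", "truth_modules.tsv", "annotations.gmt",
          paste0("db", 1:3, ".tsv"))))))
    back <- readEdgeList(file.path(dir, "db2.tsv"))
    expect_identical(edges(back), edges(ensembleMember(sim$ensemble, 2)))
    cat2 <- readGmt(file.path(dir, "annotations.gmt"))
    expect_identical(geneSets(cat2), geneSets(sim$catalog))
    sim2 <- simulateStudy(moduleSizes = rep(8L, 3), nDatabases = 3,
                          seed = 6)
    expect_identical(edges(truthNetwork(sim2$truth)),
                     edges(truthNetwork(sim$truth)))
})
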
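test_that("epsilon grids are validated", {
    g <- epsilonGrid(0.1, 0.9, 0.1)
    expect_length(g, 9L)
    expect_true(all(diff(g) > 0))
    expect_error(epsilonGrid(0, 0.9, 0.1), "inside")
    expect_error(epsilonGrid(0.5, 1.0, 0.1), "inside")
})

test_that("interior optima: downtrend, uptrend and flat series have none", {
    eps <- seq(0.1, 0.9, by = 0.1)
    down <- detectInteriorOptimum(eps, seq(9, 1))
    expect_false(down$present)
    expect_true(is.na(down$argmax))
    up <- detectInteriorOptimum(eps, seq(1, 9))
    expect_false(up$present)
    flat <- detectInteriorOptimum(eps, rep(2, 9))
    expect_false(flat$present)
})

test_that("a unimodal series has its peak detected at the right epsilon", {
    eps <- seq(0.1, 0.9, by = 0.1)
    vals <- c(0.1, 0.2, 0.4, 0.7, 1.0, 0.7, 0.4, 0.2, 0.1)
    got <- detectInteriorOptimum(eps, vals)
    expect_true(got$present)
    expect_equal(got$argmax, 0.5)
})

test_that("plateau maxima count once, argmax at the smallest epsilon", {
    eps <- seq(0.1, 1, length.out = 10)
    vals <- c(0.1, 0.3, 0.8, 0.8, 0.8, 0.3, 0.2, 0.1, 0.1, 0.05)
    got <- detectInteriorOptimum(eps, vals)
    expect_true(got$present)
    expect_equal(got$argmax, eps[3])
})

test_that("peaks flanked by missing rows are refused", {
    eps <- seq(0.1, 0.9, by = 0.1)
    vals <- c(NA, NA, NA, 0.2, 1.0, NA, NA, NA, NA)
    expect_false(detectInteriorOptimum(eps, vals)$present)
    allNA <- rep(NA_real_, 9)
    expect_false(detectInteriorOptimum(eps, allNA)$present)
})

test_that("weak bumps riding a trend fail the prominence requirement", {
    eps <- seq(0.05, 0.95, by = 0.1)
    vals <- c(0.1, 0.3, 0.5, 0.7, 0.92, 0.90, 0.96, 0.95, 0.9, 0.88)
    expect_false(detectInteriorOptimum(eps, vals)$present)
    expect_true(detectInteriorOptimum(eps, vals, prominence = 0)$present)
})

test_that("optimum detection is invariant to positive affine transformations", {
    eps <- seq(0.1, 0.9, length.out = 15)
    for (seed in 1:10) {
        set.seed(seed)
        vals <- runif(15)
        a <- runif(1, 0.5, 20); b <- runif(1, -5, 5)
        d1 <- detectInteriorOptimum(eps, vals)
        d2 <- detectInteriorOptimum(eps, a * vals + b)
        expect_identical(d1$present, d2$present)
        expect_identical(d1$argmax, d2$argmax)
    }
    expect_error(detectInteriorOptimum(c(0.2, 0.4, 0.6), c(1, 2, 1)),
                 "at least 5")
})

twoCliqueSim <- function() {
    a <- paste0("a", 1:5); b <- paste0("b", 1:5)
    net <- netFromPairs(rbind(cliquePairs(a), cliquePairs(b)))
    cat <- annotationCatalog(list(pathA = a, pathB = b))
    list(net = net, cat = cat)
}

test_that("sweeping two annotated cliques scores 1 wherever both are found", {
    fx <- twoCliqueSim()
    grid <- seq(0.3, 0.9, by = 0.1)
    prof <- epsilonSweep(fx$net, grid, fx$cat)
    pr <- profileRows(prof)
    found <- pr$nClusters == 2L
    expect_true(any(found))
    expect_true(all(pr$clusteringScore[found] == 1))
    expect_true(all(pr$enrichmentNorm >= 0 & pr$enrichmentNorm <= 1,
                    na.rm = TRUE))
    ## determinism: an identical second run
    expect_identical(profileRows(epsilonSweep(fx$net, grid, fx$cat)), pr)
})

test_that("a one-point grid degenerates to zero normalised enrichment", {
    fx <- twoCliqueSim()
    pr <- profileRows(epsilonSweep(fx$net, 0.7, fx$cat))
    expect_equal(pr$enrichmentNorm, 0)
})

test_that("the consensus-level rule prefers the smallest fully qualified k", {
    ## presence pattern shaped like the published seven-network comparison:
    ## only k=2 couples a similarity-modularity optimum with both
    ## biological optima
    presence <- data.frame(
        k = 1:7,
        optQN     = c(FALSE, FALSE, TRUE,  TRUE,  TRUE,  FALSE, FALSE),
        optQS     = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE),
        optScore  = c(FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE),
        optEnrich = c(FALSE, TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE))
    sel <- selectConsensusK(presence)
    expect_equal(sel$chosenK, 2L)
    expect_match(sel$rationale, "smallest consensus level")
    ## no qualifying k: fall back to the most optima, smallest k on ties
    none <- presence
    none$optScore <- FALSE
    none$optEnrich <- FALSE
    sel2 <- selectConsensusK(none)   # k=3..5 tie at 2 optima; smallest wins
    expect_equal(sel2$chosenK, 3L)
    expect_match(sel2$rationale, "maximises")
})

test_that("evaluateKRange on identical members picks k=1 and keeps nesting", {
    fx <- twoCliqueSim()
    nets <- lapply(1:3, function(i) {
        x <- fx$net; x@name <- sprintf("db%d", i); x
    })
    sel <- evaluateKRange(networkEnsemble(nets), seq(0.3, 0.9, 0.05),
                          fx$cat)
    expect_equal(chosenK(sel), 1L)
    s <- kSummary(sel)
    expect_equal(s$nEdges, rep(numEdges(fx$net), 3))
    expect_true(all(diff(s$nEdges) <= 0))
    expect_true(all(diff(s$nNodes) <= 0))
})

test_that("empty integrated networks are recorded, not fatal", {
    n1 <- interactionNetwork("a", "b", name = "d1")
    n2 <- interactionNetwork("c", "d", name = "d2")
    sel <- evaluateKRange(networkEnsemble(n1, n2), seq(0.3, 0.9, 0.1),
                          annotationCatalog(list(t = c("a", "b", "c"))))
    s <- kSummary(sel)
    expect_equal(s$nEdges[2], 0L)
    expect_false(any(unlist(s[2, c("optQN", "optQS", "optScore",
                                   "optEnrich")])))
})

test_that("selection reports serialise to JSON and CSV", {
    fx <- twoCliqueSim()
    nets <- lapply(1:2, function(i) {
        x <- fx$net; x@name <- sprintf("db%d", i); x
    })
    sel <- evaluateKRange(networkEnsemble(nets), seq(0.3, 0.9, 0.1),
                          fx$cat)
    fj <- withr::local_tempfile(fileext = ".json")
    fc <- withr::local_tempfile(fileext = ".csv")
    writeKSelectionReport(sel, fj, fc)
    parsed <- jsonlite::read_json(fj)
    expect_equal(parsed$chosenK, 1L)
    expect_true(file.exists(fc))
})
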
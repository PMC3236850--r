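#' @include integration.R
NULL

## Run expr with a local RNG seed, restoring global RNG state afterwards.
withSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)
    old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

## all unordered vertex-index pairs of 1..n as a 2-column matrix
allPairs <- function(n) {
    j <- rep.int(seq_len(n), rep.int(n, n))
    i <- rep.int(seq_len(n), n)
    keep <- i < j
    cbind(i[keep], j[keep])
}

#' Generate a planted-partition ground-truth network
#'
#' The classical planted-partition (two-parameter stochastic block)
#' model: vertices are split into modules of the given sizes; each
#' within-module pair becomes an edge independently with probability
#' `pIn`, each between-module pair with probability `pOut`.  With
#' `pIn = 1, pOut = 0` the result is a disjoint union of cliques.
#'
#' @param moduleSizes integer vector of module sizes (each >= 2).
#' @param pIn,pOut within/between-module edge probabilities in `[0, 1]`.
#' @param seed integer RNG seed; fixed seeds give identical networks.
#' @return a [PlantedTruth-class].  Vertex IDs are zero-padded (`g0001`,
#'   ...) so lexicographic and numeric order agree; modules are named
#'   `m01`, `m02`, ...
#' @export
plantedPartition <- function(moduleSizes = rep(20L, 10L), pIn = 0.35,
                             pOut = 0.005, seed = 1L) {
    if (any(moduleSizes < 2L)) stop("module sizes must be >= 2")
    if (pIn < 0 || pIn > 1 || pOut < 0 || pOut > 1)
        stop("edge probabilities must lie in [0, 1]")
    n <- sum(moduleSizes)
    verts <- sprintf("g%04d", seq_len(n))
    modIdx <- rep(seq_along(moduleSizes), moduleSizes)
    pairs <- allPairs(n)
    sameMod <- modIdx[pairs[, 1L]] == modIdx[pairs[, 2L]]
    p <- ifelse(sameMod, pIn, pOut)
    keep <- withSeed(seed, runif(nrow(pairs)) < p)
    net <- interactionNetwork(verts[pairs[keep, 1L]],
                              verts[pairs[keep, 2L]],
                              name = "truth", vertices = verts)
    modules <- split(verts, modIdx)
    names(modules) <- sprintf("m%02d", seq_along(modules))
    new("PlantedTruth", network = net, modules = modules,
        params = list(moduleSizes = as.integer(moduleSizes), pIn = pIn,
                      pOut = pOut, seed = as.integer(seed)))
}

#' @rdname accessors
#' @export
truthNetwork <- function(x) x@network

#' @rdname accessors
#' @export
truthModules <- function(x) x@modules

setMethod("show", "PlantedTruth", function(object) {
    cat(sprintf("PlantedTruth: %d modules, %d vertices, %d edges (pIn=%g, pOut=%g, seed=%d)\n",
                length(object@modules), numVertices(object@network),
                numEdges(object@network), object@params$pIn,
                object@params$pOut, object@params$seed))
})

#' Simulate one noisy database observation of a truth network
#'
#' Each true edge is reported with probability `sensitivity` (incomplete
#' coverage); each absent pair is reported as a spurious interaction with
#' probability `fpRate` (false positives).  Errors are independent per
#' pair, so repeated observations behave like independent experts.
#'
#' @param truth a [PlantedTruth-class].
#' @param sensitivity probability a true edge is observed, in `[0, 1]`.
#' @param fpRate probability a non-edge pair appears, in `[0, 1]`; see
#'   [fpRateForFraction()] for the "fraction of observed edges"
#'   parameterisation.
#' @param seed integer RNG seed.
#' @param name label for the observed network.
#' @return an [InteractionNetwork-class] (vertices: endpoints of observed
#'   edges only, as in a real interaction database dump).
#' @export
observeDatabase <- function(truth, sensitivity, fpRate = 0, seed = 1L,
                            name = "observed") {
    if (sensitivity < 0 || sensitivity > 1 || fpRate < 0 || fpRate > 1)
        stop("sensitivity and fpRate must lie in [0, 1]")
    tnet <- truthNetwork(truth)
    verts <- vertices(tnet)
    trueKeys <- edgeKeys(tnet)
    pairs <- allPairs(length(verts))
    keys <- paste(verts[pairs[, 1L]], verts[pairs[, 2L]], sep = "\t")
    isEdge <- keys %in% trueKeys
    obs <- withSeed(seed, {
        r <- runif(length(keys))
        (isEdge & r < sensitivity) | (!isEdge & r < fpRate)
    })
    interactionNetwork(verts[pairs[obs, 1L]], verts[pairs[obs, 2L]],
                       name = name)
}

#' Convert a false-edge fraction into a per-pair false-positive rate
#'
#' Databases are more naturally described by "what fraction of reported
#' edges is spurious" than by a per-non-edge probability.  Given the
#' truth and a sensitivity, solves for the `fpRate` at which the expected
#' number of false edges is `fraction` of the expected observed total:
#' false = fraction/(1-fraction) * sensitivity * |E_true|, divided by the
#' number of non-edge pairs.
#'
#' @param truth a [PlantedTruth-class].
#' @param sensitivity the observation sensitivity.
#' @param fraction expected fraction of observed edges that are false, in
#'   `[0, 1)`.
#' @return per-pair false-positive probability.
#' @export
fpRateForFraction <- function(truth, sensitivity, fraction) {
    if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
    tnet <- truthNetwork(truth)
    nPairs <- choose(numVertices(tnet), 2)
    nNon <- nPairs - numEdges(tnet)
    expFalse <- fraction / (1 - fraction) * sensitivity * numEdges(tnet)
    min(1, expFalse / nNon)
}

#' Simulate a committee of noisy database replicates
#'
#' Generates `n` independent observations of the truth, one per
#' "database", named `db1..dbn`.  The default noise model emulates a
#' heterogeneous committee of curated interaction databases at desk
#' scale: sensitivities spread from about 0.64 down to 0.26 (mirroring
#' the order-of-magnitude differences in coverage between real PPI
#' databases), and half of what each database reports is spurious.  The
#' noise level is calibrated — and then fixed — so that at a couple of
#' hundred vertices the union network reaches the same
#' hairball regime that a much lower false-positive fraction produces at
#' real proteome scale (the structural-similarity noise floor grows like
#' degree/\eqn{|V|}, so small networks need proportionally more noise for
#' the same qualitative effect).
#'
#' @param truth a [PlantedTruth-class].
#' @param n number of databases.
#' @param sensitivity scalar or length-`n` vector of sensitivities.
#' @param fpRate per-pair false-positive rate(s); when `NULL` (default)
#'   it is derived from `fpFraction` via [fpRateForFraction()].
#' @param fpFraction expected fraction of observed edges that are false.
#' @param seed integer master seed; member seeds are derived from it.
#' @return a [NetworkEnsemble-class].
#' @export
makeEnsemble <- function(truth, n = 7L,
                         sensitivity = defaultSensitivities(n),
                         fpRate = NULL, fpFraction = 0.5, seed = 1L) {
    sensitivity <- rep_len(sensitivity, n)
    if (is.null(fpRate))
        fpRate <- vapply(sensitivity, function(s)
            fpRateForFraction(truth, s, fpFraction), numeric(1))
    fpRate <- rep_len(fpRate, n)
    nets <- lapply(seq_len(n), function(i)
        observeDatabase(truth, sensitivity[i], fpRate[i],
                        seed = (as.integer(seed) * 1009L + i) %% 2147483647L,
                        name = sprintf("db%d", i)))
    networkEnsemble(nets)
}

#' Default per-database sensitivity profile
#'
#' The frozen committee profile: 0.85 times a linear-ish spread from 0.75
#' down to 0.30.  The spread emulates the heterogeneous coverage of real
#' interaction databases; the overall 0.85 scaling is the desk-scale
#' calibration of the simulation (see the methods vignette).  For `n`
#' other than 7 the profile is interpolated.
#'
#' @param n number of databases.
#' @return numeric vector of length `n`.
#' @export
defaultSensitivities <- function(n = 7L) {
    base <- c(0.75, 0.65, 0.55, 0.45, 0.40, 0.35, 0.30)
    0.85 * if (n == 7L) base else
        approx(seq(0, 1, length.out = 7L), base,
               xout = seq(0, 1, length.out = n))$y
}

#' Generate a synthetic annotation catalog matched to a planted truth
#'
#' Emulates a pathway catalog over the simulated proteome: one term per
#' planted module containing a `purity` fraction of the module's members
#' plus random filler genes up to a fixed term size, and
#' `nBackgroundTerms` random gene sets of the same size.  Every truth
#' vertex is guaranteed to be annotated (uncovered genes are distributed
#' over the background terms), so the catalog universe covers the whole
#' vertex set.
#'
#' The defaults emulate the granularity of a pathway catalog rather than
#' a module-perfect labelling: each term carries only 60% of its module
#' (annotation is incomplete and imperfectly aligned with network
#' modules) and is padded with unrelated filler genes to three times the
#' module size (real pathways are several-fold larger than the network
#' modules they contain — in published module tables, pathway sizes of
#' 29–138 stand against module sizes of 9–17).
#'
#' @param truth a [PlantedTruth-class].
#' @param purity fraction of each module carried by its term, in (0, 1]
#'   (default 0.6).
#' @param termSize fixed term size; defaults to three times the largest
#'   module size.
#' @param nBackgroundTerms number of unrelated random terms (default 10).
#' @param seed integer RNG seed.
#' @return an [AnnotationCatalog-class].
#' @export
synthAnnotations <- function(truth, purity = 0.6, termSize = NULL,
                             nBackgroundTerms = 10L, seed = 1L) {
    if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
    mods <- truthModules(truth)
    verts <- vertices(truthNetwork(truth))
    if (is.null(termSize))
        termSize <- 3L * max(vapply(mods, length, integer(1)))
    withSeed(seed, {
        terms <- lapply(mods, function(m) {
            nKeep <- max(1L, round(purity * length(m)))
            keep <- sort(sample(m, nKeep))
            fill <- setdiff(verts, m)
            nFill <- max(0L, termSize - nKeep)
            sort(c(keep, sample(fill, min(nFill, length(fill)))))
        })
        names(terms) <- paste0("pathway_", names(mods))
        if (nBackgroundTerms > 0L) {
            bg <- lapply(seq_len(nBackgroundTerms), function(i)
                sort(sample(verts, min(termSize, length(verts)))))
            names(bg) <- sprintf("background_%02d", seq_len(nBackgroundTerms))
            terms <- c(terms, bg)
        }
        uncovered <- setdiff(verts, unlist(terms, use.names = FALSE))
        if (length(uncovered)) {
            if (nBackgroundTerms > 0L) {
                slot <- sample.int(nBackgroundTerms, length(uncovered),
                                   replace = TRUE)
                for (i in unique(slot)) {
                    nm <- sprintf("background_%02d", i)
                    terms[[nm]] <- sort(c(terms[[nm]], uncovered[slot == i]))
                }
            } else terms$background_rest <- uncovered
        }
        annotationCatalog(terms)
    })
}

#' Edge precision of a network against a known truth
#'
#' Fraction of the network's edges present in the truth network — the
#' headline robustness comparison between consensus levels (a higher-k
#' consensus trades coverage for precision).
#'
#' @param net an [InteractionNetwork-class].
#' @param truth a [PlantedTruth-class] or [InteractionNetwork-class].
#' @return precision in `[0, 1]` (`NaN` for an edgeless network).
#' @export
edgePrecision <- function(net, truth) {
    tnet <- if (is(truth, "PlantedTruth")) truthNetwork(truth) else truth
    keys <- edgeKeys(net)
    if (!length(keys)) return(NaN)
    mean(keys %in% edgeKeys(tnet))
}

#' Simulate a full desk-scale study: truth, databases, annotations
#'
#' One call generating everything the evaluation framework consumes: a
#' planted-partition truth, a committee of noisy database replicates, and
#' a matched annotation catalog.  When `outDir` is given, writes
#' `db1.tsv..dbn.tsv`, `truth.tsv`, `truth_modules.tsv` and
#' `annotations.gmt` there.
#'
#' @param moduleSizes,pIn,pOut see [plantedPartition()].
#' @param nDatabases,sensitivity,fpFraction see [makeEnsemble()].
#' @param purity,termSize,nBackgroundTerms see [synthAnnotations()].
#' @param seed master seed for all stages.
#' @param outDir optional output directory.
#' @return (invisibly when writing) a list with elements `truth`,
#'   `ensemble`, `catalog`.
#' @export
simulateStudy <- function(moduleSizes = rep(20L, 10L), pIn = 0.35,
                          pOut = 0.005, nDatabases = 7L,
                          sensitivity = defaultSensitivities(nDatabases),
                          fpFraction = 0.5,
                          purity = 0.6, termSize = NULL,
                          nBackgroundTerms = 10L, seed = 1L,
                          outDir = NULL) {
    seed <- as.integer(seed)
    truth <- plantedPartition(moduleSizes, pIn, pOut, seed = seed)
    ens <- makeEnsemble(truth, n = nDatabases, sensitivity = sensitivity,
                        fpFraction = fpFraction, seed = seed + 1L)
    cat <- synthAnnotations(truth, purity = purity, termSize = termSize,
                            nBackgroundTerms = nBackgroundTerms,
                            seed = seed + 2L)
    out <- list(truth = truth, ensemble = ens, catalog = cat)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeEdgeList(truthNetwork(truth), file.path(outDir, "truth.tsv"))
        mods <- truthModules(truth)
        write.table(
            data.frame(vertex = unlist(mods, use.names = FALSE),
                       module = rep(names(mods), lengths(mods))),
            file.path(outDir, "truth_modules.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        for (i in seq_len(ensembleSize(ens)))
            writeEdgeList(ensembleMember(ens, i),
                          file.path(outDir, sprintf("db%d.tsv", i)))
        writeGmt(cat, file.path(outDir, "annotations.gmt"))
        return(invisible(out))
    }
    out
}
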
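test_that("a saturated edge budget forces the complete graph", {
    g <- makePlantedGraph(4, 6, seed = 1)
    expect_equal(edgeCount(g), 6L)
    expect_true(all(degreeSequence(g) == 3L))
})

test_that("infeasible generator requests are rejected with clear errors", {
    expect_error(makePlantedGraph(50, 0, seed = 1), "positive")
    expect_error(makePlantedGraph(5, 11, seed = 1), "infeasible")
    expect_error(makePlantedGraph(20, 10, nHubs = 2, hubDegree = 8,
                                  seed = 1), "infeasible")
    expect_error(makePlantedGraph(10, 5, nHubs = 1, hubDegree = 12,
                                  seed = 1), "nGenes")
})

test_that("planted hubs reach the requested degree within the budget", {
    g <- makePlantedGraph(100, 200, nHubs = 2, hubDegree = 30, seed = 1)
    expect_equal(edgeCount(g), 200L)
    deg <- degreeSequence(g)
    expect_true(all(deg[c("g001", "g002")] >= 30L))
    # deterministic given the seed
    g2 <- makePlantedGraph(100, 200, nHubs = 2, hubDegree = 30, seed = 1)
    expect_identical(edgePairs(g), edgePairs(g2))
    g3 <- makePlantedGraph(100, 200, nHubs = 2, hubDegree = 30, seed = 2)
    expect_false(identical(edgePairs(g), edgePairs(g3)))
})

test_that("rewiring retains exactly round(overlap * E) edges", {
    g <- makePlantedGraph(80, 500, seed = 3)
    for (o in c(0, 0.2, 0.5, 1)) {
        h <- rewireGraph(g, o, seed = 4)
        expect_equal(edgeCount(h), 500L)
        expect_identical(nodeIds(h), nodeIds(g))
        shared <- length(intersect(edgeKeySet(g), edgeKeySet(h)))
        expect_equal(shared, as.integer(floor(o * 500 + 0.5)))
    }
    expect_identical(edgePairs(rewireGraph(g, 1, seed = 9)),
                     edgePairs(g))
})

test_that("over-dense graphs cannot be rewired at low overlap", {
    g <- makePlantedGraph(4, 6, seed = 1)   # complete graph
    expect_error(rewireGraph(g, 0, seed = 2), "exhausted")
})

test_that("precision matrix realizes the planted graph exactly", {
    ids <- sprintf("g%03d", 1:5)
    empty <- mkPlanted(ids, NULL)
    expect_equal(graphToPrecision(empty, 0.3),
                 diag(5), ignore_attr = TRUE)
    # isolated edge keeps its full strength after unit-diagonal scaling
    single <- mkPlanted(ids, cbind("g001", "g002"))
    om <- graphToPrecision(single, 0.3)
    expect_equal(om["g001", "g002"], -0.3)
    expect_equal(sum(om[upper.tri(om)] != 0), 1L)
    # duality on a denser graph: zeros exactly on non-edges, edges
    # exactly -s before scaling, and positive definiteness throughout
    g <- makePlantedGraph(30, 60, nHubs = 1, hubDegree = 10, seed = 5)
    raw <- graphToPrecision(g, 0.45, scale = FALSE)
    keys <- edgeKeySet(g)
    idx <- which(upper.tri(raw), arr.ind = TRUE)
    isEdge <- paste(rownames(raw)[idx[, 1L]],
                    colnames(raw)[idx[, 2L]]) %in% keys
    expect_true(all(raw[idx[isEdge, , drop = FALSE]] == -0.45))
    expect_true(all(raw[idx[!isEdge, , drop = FALSE]] == 0))
    scaled <- graphToPrecision(g, 0.45)
    expect_gt(min(eigen(scaled, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    expect_equal(unname(diag(scaled)), rep(1, 30))
})

test_that("sampled covariance converges to the planted model", {
    truth <- makeSyntheticTruth(30, 40, nHubs = 1, hubDegree = 6,
                                overlap = 1, nShifted = 0, seed = 6)
    tc <- sampleExpression(truth, c(pre = 5000, mid = 4, post = 4),
                           partialStrength = 0.3, seed = 7)
    x <- exprMatrix(tc, "pre")
    sigma <- solve(graphToPrecision(truth@graphs$pre, 0.3))
    expect_lt(max(abs(stats::cov(t(x)) - sigma)), 0.1)
})

test_that("planted edges show strong first-order partial correlations", {
    ids <- c("g1", "g2", "g3")
    truth <- new("SyntheticTruth",
                 graphs = list(pre = mkPlanted(ids, cbind("g1", "g2"))),
                 overlapRequested = 1, shiftedGenes = character(),
                 shiftSize = 0, seed = 1L)
    tc <- sampleExpression(truth, c(pre = 500), partialStrength = 0.4,
                           seed = 8)
    cm <- spearmanMatrix(tc, "pre")
    rho <- firstOrderPartial(cm@r["g1", "g2"], cm@r["g1", "g3"],
                             cm@r["g2", "g3"])
    expect_gt(rho, 0.25)   # positive: negative precision entry convention
})

test_that("post-treatment mean shifts have the requested size", {
    truth <- makeSyntheticTruth(20, 20, nHubs = 0, nShifted = 4,
                                shiftSize = 2, seed = 9)
    tc <- sampleExpression(truth, c(pre = 500, mid = 4, post = 500),
                           partialStrength = 0.4, noiseSd = 1, seed = 10)
    pre <- exprMatrix(tc, "pre"); post <- exprMatrix(tc, "post")
    diffShift <- rowMeans(post)[truth@shiftedGenes] -
        rowMeans(pre)[truth@shiftedGenes]
    expect_true(all(abs(diffShift - 2) < 0.35))
    others <- setdiff(rownames(tc), truth@shiftedGenes)
    expect_true(all(abs(rowMeans(post)[others] -
                        rowMeans(pre)[others]) < 0.35))
})

test_that("identical seeds give bitwise-identical synthetic data", {
    s1 <- quickStudy(seed = 11)
    s2 <- quickStudy(seed = 11)
    expect_identical(exprMatrix(s1$tc), exprMatrix(s2$tc))
    expect_identical(edgePairs(s1$truth@graphs$mid),
                     edgePairs(s2$truth@graphs$mid))
    s3 <- quickStudy(seed = 12)
    expect_false(identical(exprMatrix(s1$tc), exprMatrix(s3$tc)))
})

test_that("synthetic truth respects the requested consecutive overlap", {
    truth <- makeSyntheticTruth(60, 100, nHubs = 2, hubDegree = 10,
                                overlap = 0.2, seed = 13)
    for (i in 1:2) {
        shared <- length(intersect(edgeKeySet(truth@graphs[[i]]),
                                   edgeKeySet(truth@graphs[[i + 1L]])))
        expect_equal(shared / 100, 0.2, tolerance = 1 / 100)
    }
})
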
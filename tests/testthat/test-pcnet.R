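test_that("the first-order partial recursion is exact arithmetic", {
    expect_equal(firstOrderPartial(0.8, 0.5, 0.5), 0.55 / 0.75)
    # conditioning on an uncorrelated gene changes nothing
    expect_equal(firstOrderPartial(0.37, 0, 0), 0.37)
    # a correlation fully explained by the conditioner vanishes
    expect_equal(firstOrderPartial(0.5 * 0.6, 0.5, 0.6), 0)
})

test_that("partials equal rank-residual regression correlations", {
    set.seed(10)
    for (rep in 1:50) {
        x <- rnorm(25); y <- rnorm(25) + 0.5 * x; z <- rnorm(25) + x
        rx <- rank(x); ry <- rank(y); rz <- rank(z)
        rho <- firstOrderPartial(cor(rx, ry), cor(rx, rz), cor(ry, rz))
        expect_equal(rho, residualPartial(x, y, z), tolerance = 1e-8)
    }
})

test_that("spearman matrix handles monotone, reversed and constant genes", {
    vals <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
                  g2 = c(2, 4, 9, 16, 30, 55),   # monotone in g1
                  g3 = -c(1, 2, 3, 4, 5, 6),     # negation of g1
                  g4 = rep(7, 6))                # constant
    colnames(vals) <- paste0("s", 1:6)
    tc <- TimecourseExperiment(vals, rep("pre", 6))
    expect_warning(cm <- spearmanMatrix(tc, "pre"), "constant gene")
    expect_equal(cm@r["g1", "g2"], 1)
    expect_equal(cm@r["g1", "g3"], -1)
    expect_true(all(cm@r["g4", c("g1", "g2", "g3")] == 0))
    expect_equal(diag(cm@r), rep(1, 4), ignore_attr = TRUE)
})

test_that("an indirect pair correlated through a confounder is pruned", {
    # planted chain g1 - g2 - g3: the g1/g3 association is explained by g2
    ids <- c("g1", "g2", "g3", "g4")
    chain <- mkPlanted(ids, rbind(c("g1", "g2"), c("g2", "g3")))
    truth <- new("SyntheticTruth", graphs = list(pre = chain),
                 overlapRequested = 1, shiftedGenes = character(),
                 shiftSize = 0, seed = 1L)
    tc <- sampleExpression(truth, c(pre = 200), partialStrength = 0.5,
                           seed = 21)
    net <- buildNetwork(tc, "pre")
    keys <- edgeKeySet(net)
    expect_true(all(c("g1 g2", "g2 g3") %in% keys))
    expect_false("g1 g3" %in% keys)
    # yet the zero-order correlation of the indirect pair is significant
    cm <- spearmanMatrix(tc, "pre")
    expect_gt(abs(cm@r["g1", "g3"]),
              netrewire:::.rhoCritical(200, 0L, 0.01))
})

test_that("edge decisions are symmetric and match the vectorized path", {
    s <- quickStudy(nGenes = 30, nEdges = 40, nHubs = 1, hubDegree = 6,
                    n = 50, seed = 31)
    net <- buildNetwork(s$tc, "pre")
    cm <- spearmanMatrix(s$tc, "pre")
    keys <- edgeKeySet(net)
    ids <- cm@geneIds
    for (i in 1:(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
        et <- edgeTest(ids[i], ids[j], cm)
        expect_identical(et$edge, paste(ids[i], ids[j]) %in% keys)
    }
    # symmetry, spot-checked on a handful of pairs
    for (pair in list(c(1, 2), c(3, 17), c(5, 30))) {
        a <- edgeTest(pair[1L], pair[2L], cm)
        b <- edgeTest(pair[2L], pair[1L], cm)
        expect_identical(a$edge, b$edge)
        expect_equal(a$min_abs_partial, b$min_abs_partial)
        expect_equal(a$max_p, b$max_p)
    }
})

test_that("first-order pruning only removes zero-order edges", {
    s <- quickStudy(nGenes = 40, nEdges = 60, nHubs = 2, hubDegree = 8,
                    n = 60, seed = 41)
    for (tp in c("pre", "post")) {
        net <- buildNetwork(s$tc, tp)
        cm <- spearmanMatrix(s$tc, tp)
        rc0 <- netrewire:::.rhoCritical(cm@nSamples, 0L, 0.01)
        zeroPairs <- which(abs(cm@r) > rc0 & upper.tri(cm@r),
                           arr.ind = TRUE)
        zeroKeys <- paste(cm@geneIds[zeroPairs[, 1L]],
                          cm@geneIds[zeroPairs[, 2L]])
        expect_true(all(edgeKeySet(net) %in% zeroKeys))
        expect_identical(net@zeroOrderCount, as.integer(nrow(zeroPairs)))
        expect_lte(edgeCount(net), nrow(zeroPairs))
    }
})

test_that("degree-1 planted edges are recovered nearly in full", {
    # matching graph: scaling leaves every edge at full strength 0.5
    g <- matchingGraph(100)
    truth <- new("SyntheticTruth", graphs = list(pre = g),
                 overlapRequested = 1, shiftedGenes = character(),
                 shiftSize = 0, seed = 1L)
    tc <- sampleExpression(truth, c(pre = 200), partialStrength = 0.5,
                           seed = 51)
    net <- buildNetwork(tc, "pre")
    recovered <- mean(edgeKeySet(g) %in% edgeKeySet(net))
    expect_gte(recovered, 0.9)
})

test_that("planted structure exceeds the permutation null", {
    g <- matchingGraph(40)
    truth <- new("SyntheticTruth", graphs = list(pre = g),
                 overlapRequested = 1, shiftedGenes = character(),
                 shiftSize = 0, seed = 1L)
    tc <- sampleExpression(truth, c(pre = 100), partialStrength = 0.5,
                           seed = 61)
    pn <- permutationNull(tc, "pre", nPermutations = 50L, seed = 62)
    expect_true(pn$exceeds_null)
    expect_length(pn$null_counts, 50L)
    expect_identical(pn$exceeds_null,
                     pn$observed_edge_count > pn$null_max)
    # reproducible under the same master seed
    pn2 <- permutationNull(tc, "pre", nPermutations = 50L, seed = 62)
    expect_identical(pn$null_counts, pn2$null_counts)
})

test_that("null data rarely exceeds its own permutation null", {
    flags <- vapply(1:5, function(rep) {
        set.seed(200 + rep)
        vals <- matrix(rnorm(15 * 30), 15,
                       dimnames = list(sprintf("g%02d", 1:15),
                                       sprintf("s%02d", 1:30)))
        tc <- TimecourseExperiment(vals, rep("pre", 30))
        permutationNull(tc, "pre", nPermutations = 30L,
                        seed = 300 + rep)$exceeds_null
    }, logical(1L))
    expect_gte(sum(!flags), 4L)
})

test_that("tiny node sets and tiny samples are rejected", {
    vals <- matrix(rnorm(8), 2, 4,
                   dimnames = list(c("a", "b"), paste0("s", 1:4)))
    tc <- TimecourseExperiment(vals, rep("pre", 4))
    expect_error(buildNetwork(tc, "pre"), "at least 3 genes")
    vals3 <- matrix(rnorm(9), 3, 3,
                    dimnames = list(c("a", "b", "c"), paste0("s", 1:3)))
    tc3 <- TimecourseExperiment(vals3, rep("pre", 3))
    expect_error(buildNetwork(tc3, "pre"), "at least 4 samples")
})
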
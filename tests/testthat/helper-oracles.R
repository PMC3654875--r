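# fixtures built in code and independent brute-force oracles

# construct a PlantedGraph directly from an edge matrix
mkPlanted <- function(nodes, edges, timepoint = "pre") {
    if (is.null(edges)) {
        em <- matrix(character(), 0L, 2L,
                     dimnames = list(NULL, c("gene_a", "gene_b")))
    } else {
        a <- pmin(edges[, 1L], edges[, 2L])
        b <- pmax(edges[, 1L], edges[, 2L])
        o <- order(a, b)
        em <- cbind(gene_a = a[o], gene_b = b[o])
    }
    new("PlantedGraph", nodeIds = nodes, edges = em,
        timepoint = timepoint)
}

# a perfect matching on nGenes nodes (nGenes/2 isolated edges): every
# node has degree <= 1, so planted partial strengths survive scaling
matchingGraph <- function(nGenes, timepoint = "pre") {
    fmt <- paste0("g%0", max(3L, nchar(nGenes)), "d")
    ids <- sprintf(fmt, seq_len(nGenes))
    mkPlanted(ids, cbind(ids[seq(1L, nGenes - 1L, 2L)],
                         ids[seq(2L, nGenes, 2L)]), timepoint)
}

# CoexpressionNetwork with dummy edge statistics, for topology tests
mkNet <- function(nodes, edges, timepoint = "pre") {
    if (is.null(edges) || nrow(edges) == 0L) {
        et <- data.frame(gene_a = character(), gene_b = character(),
                         r = numeric(), min_abs_partial = numeric(),
                         max_p = numeric(), stringsAsFactors = FALSE)
    } else {
        a <- pmin(edges[, 1L], edges[, 2L])
        b <- pmax(edges[, 1L], edges[, 2L])
        o <- order(a, b)
        et <- data.frame(gene_a = a[o], gene_b = b[o], r = 0.5,
                         min_abs_partial = 0.5, max_p = 0.001,
                         stringsAsFactors = FALSE)
    }
    new("CoexpressionNetwork", timepoint = timepoint, nodeIds = nodes,
        edgeTable = et, nSamples = 10L, alpha = 0.01,
        zeroOrderCount = nrow(et))
}

edgeKeySet <- function(x) {
    e <- edgePairs(x)
    if (nrow(e) == 0L) character() else paste(e[, 1L], e[, 2L])
}

# symmetric 0/1 adjacency matrix of a random simple graph
randAdj <- function(n, pEdge, seed) {
    set.seed(seed)
    a <- matrix(0L, n, n)
    up <- upper.tri(a)
    a[up] <- as.integer(stats::runif(sum(up)) < pEdge)
    a + t(a)
}

netFromAdj <- function(adj, timepoint = "pre") {
    n <- nrow(adj)
    ids <- sprintf("g%03d", seq_len(n))
    w <- which(adj == 1L & upper.tri(adj), arr.ind = TRUE)
    mkNet(ids, if (nrow(w)) cbind(ids[w[, 1L]], ids[w[, 2L]]) else NULL,
          timepoint)
}

# Floyd-Warshall all-pairs shortest path lengths
bruteDistances <- function(adj) {
    n <- nrow(adj)
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    d[adj == 1L] <- 1
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    d
}

# mean over unordered pairs of a connected node subset
bruteMeanPath <- function(adj, subset) {
    d <- bruteDistances(adj)[subset, subset, drop = FALSE]
    mean(d[upper.tri(d)])
}

# transitivity by explicit triangle and connected-triple counts
bruteTransitivity <- function(adj) {
    deg <- rowSums(adj)
    triples <- sum(choose(deg, 2))
    if (triples == 0) return(0)
    tri <- sum(diag(adj %*% adj %*% adj)) / 6
    3 * tri / triples
}

# betweenness by enumerating every shortest path
bruteBetweenness <- function(adj) {
    n <- nrow(adj)
    btw <- numeric(n)
    nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1L))
    d <- bruteDistances(adj)
    enumPaths <- function(s, t) {
        if (s == t) return(list(s))
        out <- list()
        for (u in nbrs[[t]])
            if (is.finite(d[s, u]) && d[s, u] == d[s, t] - 1)
                for (pp in enumPaths(s, u))
                    out[[length(out) + 1L]] <- c(pp, t)
        out
    }
    for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
        if (!is.finite(d[s, t]) || d[s, t] < 2) next
        paths <- enumPaths(s, t)
        inner <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
        tb <- table(inner)
        idx <- as.integer(names(tb))
        btw[idx] <- btw[idx] + as.numeric(tb) / length(paths)
    }
    btw
}

# partial correlation via rank-residual regression (the textbook route)
residualPartial <- function(x, y, z) {
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    ex <- stats::residuals(stats::lm(rx ~ rz))
    ey <- stats::residuals(stats::lm(ry ~ rz))
    stats::cor(ex, ey)
}

# quick three-timepoint synthetic experiment
quickStudy <- function(nGenes = 40, nEdges = 50, nHubs = 1, hubDegree = 8,
                       overlap = 0.2, nShifted = 8, shiftSize = 2,
                       n = 60, partialStrength = 0.5, noiseSd = 0,
                       seed = 1) {
    truth <- makeSyntheticTruth(nGenes, nEdges, nHubs, hubDegree,
                                overlap = overlap, nShifted = nShifted,
                                shiftSize = shiftSize, seed = seed)
    tc <- sampleExpression(truth,
                           nPerTimepoint = c(pre = n, mid = n, post = n),
                           partialStrength = partialStrength,
                           noiseSd = noiseSd, seed = seed + 1000L)
    list(truth = truth, tc = tc)
}
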
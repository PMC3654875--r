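# planted-graph generator and Gaussian graphical sampling

# linear index of pair (i, j), i < j, over 1..n
.pairIndex <- function(i, j, n) (i - 1L) * n - (i * (i + 1L)) %/% 2L + j

# inverse: pair matrix for linear indices
.pairFromIndex <- function(idx, n) {
    # cumulative pairs before row i: (i-1)*n - i*(i-1)/2
    i <- findInterval(idx - 1L, cumsum(c(0L, (n - 1L):1L)),
                      left.open = FALSE)
    offset <- (i - 1L) * n - (i * (i + 1L)) %/% 2L
    cbind(i, idx - offset)
}

#' Generate a planted graph with designated hub nodes
#'
#' Builds a simple undirected graph on `nGenes` nodes with exactly
#' `nEdges` edges. The first `nHubs` nodes are designated hubs: a star of
#' `hubDegree` edges is planted around each of them first, and the
#' remaining edge budget is filled by pairs drawn uniformly at random
#' without replacement from the unoccupied pairs. Hubs give the degree
#' distribution the heavy tail seen in real coexpression networks.
#'
#' @param nGenes number of genes (nodes), at least 2.
#' @param nEdges total number of edges, between 1 and
#'   `nGenes * (nGenes - 1) / 2`.
#' @param nHubs number of designated hub nodes (default 0).
#' @param hubDegree minimum degree planted for each hub; requires
#'   `nHubs * hubDegree <= nEdges`.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param geneIds optional character vector of gene identifiers; defaults
#'   to zero-padded `g001`, `g002`, ... so lexicographic order matches
#'   generation order.
#' @param timepoint label attached to the graph (default `"pre"`).
#' @return A [PlantedGraph-class] in which every hub has degree at least
#'   `hubDegree`.
#' @examples
#' g <- makePlantedGraph(20, 30, nHubs = 1, hubDegree = 8, seed = 1)
#' edgeCount(g)
#' @export
makePlantedGraph <- function(nGenes, nEdges, nHubs = 0L, hubDegree = 0L,
                             seed, geneIds = NULL, timepoint = "pre") {
    nGenes <- as.integer(nGenes); nEdges <- as.integer(nEdges)
    nHubs <- as.integer(nHubs); hubDegree <- as.integer(hubDegree)
    if (nGenes < 2L) stop("'nGenes' must be at least 2")
    maxE <- nGenes * (nGenes - 1L) / 2
    if (nEdges < 1L)
        stop("'nEdges' must be a positive integer")
    if (nEdges > maxE)
        stop("edge budget infeasible: ", nEdges, " edges requested but a ",
             nGenes, "-node simple graph can hold at most ", maxE)
    if (nHubs < 0L) stop("'nHubs' must be non-negative")
    if (nHubs > 0L) {
        if (hubDegree < 1L)
            stop("'hubDegree' must be positive when hubs are requested")
        if (hubDegree > nGenes - 1L)
            stop("'hubDegree' cannot exceed nGenes - 1")
        if (nHubs * hubDegree > nEdges)
            stop("edge budget infeasible: ", nHubs, " hubs of degree ",
                 hubDegree, " need at least ", nHubs * hubDegree,
                 " edges but only ", nEdges, " were requested")
    }
    if (is.null(geneIds)) {
        fmt <- paste0("g%0", max(3L, nchar(nGenes)), "d")
        geneIds <- sprintf(fmt, seq_len(nGenes))
    }
    stopifnot(length(geneIds) == nGenes, !anyDuplicated(geneIds))

    edges <- .withSeed(seed, {
        occupied <- logical(maxE)
        ei <- integer(0); ej <- integer(0)
        for (h in seq_len(nHubs)) {
            others <- setdiff(seq_len(nGenes), h)
            idx <- .pairIndex(pmin(h, others), pmax(h, others), nGenes)
            free <- others[!occupied[idx]]
            need <- hubDegree - sum(occupied[.pairIndex(
                pmin(h, others), pmax(h, others), nGenes)])
            if (need > 0L) {
                pick <- free[sample.int(length(free), need)]
                occupied[.pairIndex(pmin(h, pick), pmax(h, pick),
                                    nGenes)] <- TRUE
                ei <- c(ei, pmin(h, pick)); ej <- c(ej, pmax(h, pick))
            }
        }
        remaining <- nEdges - length(ei)
        if (remaining > 0L) {
            free <- which(!occupied)
            pick <- free[sample.int(length(free), remaining)]
            pm <- .pairFromIndex(pick, nGenes)
            ei <- c(ei, pm[, 1L]); ej <- c(ej, pm[, 2L])
        }
        .canonicalEdges(geneIds[ei], geneIds[ej])
    })
    new("PlantedGraph", nodeIds = geneIds, edges = edges,
        timepoint = timepoint)
}

#' Rewire a planted graph while retaining a requested edge overlap
#'
#' Produces a graph on the same node set with the same edge count in
#' which exactly `round(overlap * nEdges)` edges are retained from `g`
#' (chosen uniformly) and the remainder are replaced by pairs drawn
#' uniformly at random from the pairs absent from `g`. Used to plant a
#' known conserved-link fraction between consecutive time points.
#'
#' @param g a [PlantedGraph-class].
#' @param overlap fraction of edges to retain, in `[0, 1]`.
#' @param seed integer seed; deterministic given the seed.
#' @param timepoint label for the rewired graph; defaults to the label of
#'   `g`.
#' @return A [PlantedGraph-class] sharing exactly
#'   `round(overlap * edgeCount(g))` edges with `g`.
#' @examples
#' g1 <- makePlantedGraph(30, 40, seed = 1)
#' g2 <- rewireGraph(g1, overlap = 0.5, seed = 2, timepoint = "mid")
#' @export
rewireGraph <- function(g, overlap, seed, timepoint = timepointLabel(g)) {
    stopifnot(is(g, "PlantedGraph"))
    if (!is.numeric(overlap) || length(overlap) != 1L ||
        overlap < 0 || overlap > 1)
        stop("'overlap' must be a fraction in [0, 1]")
    n <- length(g@nodeIds)
    m <- nrow(g@edges)
    maxE <- n * (n - 1L) / 2
    nKeep <- as.integer(floor(overlap * m + 0.5))  # round half up
    nNew <- m - nKeep
    if (nNew > maxE - m)
        stop("replacement pairs exhausted: need ", nNew,
             " pairs outside the graph but only ", maxE - m,
             " are available (graph too dense)")
    idToIdx <- stats::setNames(seq_len(n), g@nodeIds)
    oldIdx <- .pairIndex(idToIdx[g@edges[, 1L]], idToIdx[g@edges[, 2L]], n)
    edges <- .withSeed(seed, {
        keep <- sort(sample.int(m, nKeep))
        occupied <- logical(maxE)
        occupied[oldIdx] <- TRUE   # new pairs must avoid ALL pairs of g
        free <- which(!occupied)
        pick <- if (nNew > 0L) free[sample.int(length(free), nNew)]
                else integer(0)
        pm <- .pairFromIndex(pick, n)
        .canonicalEdges(
            c(g@edges[keep, 1L], g@nodeIds[pm[, 1L]]),
            c(g@edges[keep, 2L], g@nodeIds[pm[, 2L]]))
    })
    new("PlantedGraph", nodeIds = g@nodeIds, edges = edges,
        timepoint = timepoint)
}

#' Precision matrix realizing a planted graph as conditional dependencies
#'
#' Encodes a planted graph as the precision (inverse covariance) matrix
#' of a Gaussian graphical model: every planted edge receives off-diagonal
#' entry `-partialStrength`, every non-edge exactly 0. The diagonal is
#' set per row to `max(1, dominance * partialStrength * degree)`, which
#' makes the matrix strictly diagonally dominant and therefore positive
#' definite for any planted graph (Gershgorin), and the result is then
#' symmetrically normalized to unit diagonal. With this row-wise rule a
#' node's edges are only damped in proportion to its own degree, so
#' low-degree parts of the graph keep their full conditional-dependence
#' strength no matter how connected the rest of the graph is.
#'
#' @param g a [PlantedGraph-class].
#' @param partialStrength edge strength in (0, 1); for an isolated edge
#'   the scaled off-diagonal is exactly `-partialStrength`.
#' @param dominance diagonal-dominance margin (> 1, default 1.05).
#' @param scale if `FALSE`, return the pre-scaling matrix (off-diagonals
#'   exactly `-partialStrength` on edges) instead of the unit-diagonal
#'   normalized one.
#' @return Symmetric positive-definite numeric matrix with dimnames
#'   `nodeIds(g)`. Its zero off-diagonal pattern matches the non-edges of
#'   `g` exactly.
#' @examples
#' g <- makePlantedGraph(10, 12, seed = 1)
#' omega <- graphToPrecision(g, 0.4)
#' min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
graphToPrecision <- function(g, partialStrength, dominance = 1.05,
                             scale = TRUE) {
    stopifnot(is(g, "PlantedGraph"))
    if (!is.numeric(partialStrength) || length(partialStrength) != 1L ||
        partialStrength <= 0 || partialStrength >= 1)
        stop("'partialStrength' must lie strictly between 0 and 1")
    if (dominance <= 1)
        stop("'dominance' must exceed 1 for strict diagonal dominance")
    n <- length(g@nodeIds)
    omega <- matrix(0, n, n, dimnames = list(g@nodeIds, g@nodeIds))
    if (nrow(g@edges) > 0L) {
        ia <- match(g@edges[, 1L], g@nodeIds)
        ib <- match(g@edges[, 2L], g@nodeIds)
        omega[cbind(ia, ib)] <- -partialStrength
        omega[cbind(ib, ia)] <- -partialStrength
    }
    deg <- rowSums(omega != 0)
    diag(omega) <- pmax(1, dominance * partialStrength * deg)
    if (scale)
        omega <- stats::cov2cor(omega)
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
        stop("precision matrix is not positive definite ",
             "(minimum eigenvalue ", format(ev), ")")
    omega
}

#' Bundle planted graphs for an ordered time course
#'
#' Convenience constructor for a three-timepoint synthetic study: plants
#' a pre-treatment graph, then rewires it twice with the requested
#' consecutive edge overlap, and samples a gene subset for a
#' pre-to-post mean shift (the differential-expression signal).
#'
#' The defaults emulate the study design this package targets: three
#' ordered biopsy time points whose networks share roughly 20% of their
#' links between consecutive time points, with a heavy-tailed degree
#' distribution induced by planted hubs.
#'
#' @param nGenes,nEdges,nHubs,hubDegree passed to [makePlantedGraph()].
#' @param overlap requested consecutive edge overlap (default 0.2).
#' @param nShifted number of genes given a pre-to-post mean shift.
#' @param shiftSize size of the shift in log-expression units.
#' @param seed integer master seed.
#' @param timepointLevels ordered labels, one graph per label.
#' @return A [SyntheticTruth-class].
#' @examples
#' truth <- makeSyntheticTruth(50, 60, nHubs = 2, hubDegree = 8, seed = 1)
#' truth
#' @export
makeSyntheticTruth <- function(nGenes = 100L, nEdges = 120L, nHubs = 3L,
                               hubDegree = 10L, overlap = 0.2,
                               nShifted = 20L, shiftSize = 2,
                               seed = 1L,
                               timepointLevels = c("pre", "mid", "post")) {
    seed <- as.integer(seed)
    if (nShifted > nGenes)
        stop("'nShifted' cannot exceed 'nGenes'")
    sub <- .withSeed(seed, sample.int(.Machine$integer.max,
                                      length(timepointLevels) + 1L))
    graphs <- vector("list", length(timepointLevels))
    names(graphs) <- timepointLevels
    graphs[[1L]] <- makePlantedGraph(nGenes, nEdges, nHubs, hubDegree,
                                     seed = sub[1L],
                                     timepoint = timepointLevels[1L])
    for (i in seq_along(timepointLevels)[-1L])
        graphs[[i]] <- rewireGraph(graphs[[i - 1L]], overlap,
                                   seed = sub[i],
                                   timepoint = timepointLevels[i])
    shifted <- if (nShifted > 0L)
        sort(.withSeed(sub[length(sub)],
                       sample(nodeIds(graphs[[1L]]), nShifted)))
    else character()
    new("SyntheticTruth", graphs = graphs,
        overlapRequested = as.numeric(overlap),
        shiftedGenes = shifted, shiftSize = as.numeric(shiftSize),
        seed = seed)
}

#' Sample expression data from a synthetic truth
#'
#' For each time point, draws samples from a zero-mean multivariate
#' normal whose covariance is the inverse of the planted graph's
#' precision matrix ([graphToPrecision()]), optionally adds independent
#' Gaussian measurement noise, and adds the truth's mean shift to its
#' shifted genes in the samples of the final (post) time point only --
#' matching a pre-versus-post differential-expression contrast.
#'
#' @param truth a [SyntheticTruth-class].
#' @param nPerTimepoint named integer vector of sample counts per time
#'   point (each at least 4, the minimum for a first-order partial
#'   correlation test with positive degrees of freedom). The default
#'   58/58/60 mirrors a three-point neoadjuvant biopsy series.
#' @param partialStrength edge strength passed to [graphToPrecision()].
#' @param noiseSd standard deviation of additional independent
#'   measurement noise (default 0; the graphical model itself already has
#'   unit-scale marginal variation).
#' @param seed integer seed; deterministic given the seed.
#' @param dominance passed to [graphToPrecision()].
#' @return A [TimecourseExperiment-class] with genes in rows and sample
#'   ids `<timepoint>_s<number>`.
#' @examples
#' truth <- makeSyntheticTruth(30, 35, nHubs = 1, hubDegree = 6, seed = 1)
#' tc <- sampleExpression(truth,
#'                        nPerTimepoint = c(pre = 20, mid = 20, post = 20),
#'                        partialStrength = 0.4, seed = 2)
#' dim(tc)
#' @export
sampleExpression <- function(truth,
                             nPerTimepoint = c(pre = 58L, mid = 58L,
                                               post = 60L),
                             partialStrength = 0.5, noiseSd = 0,
                             seed, dominance = 1.05) {
    stopifnot(is(truth, "SyntheticTruth"))
    tps <- names(truth@graphs)
    if (is.null(names(nPerTimepoint)))
        names(nPerTimepoint) <- tps
    if (!all(tps %in% names(nPerTimepoint)))
        stop("'nPerTimepoint' must name every timepoint: ",
             paste(tps, collapse = ", "))
    nPerTimepoint <- as.integer(nPerTimepoint[tps])
    if (any(nPerTimepoint < 4L))
        stop("at least 4 samples per timepoint are required for ",
             "first-order partial correlation testing")
    genes <- nodeIds(truth@graphs[[1L]])
    p <- length(genes)
    .withSeed(seed, {
        blocks <- lapply(seq_along(tps), function(i) {
            sigma <- solve(graphToPrecision(truth@graphs[[i]],
                                            partialStrength,
                                            dominance = dominance))
            x <- t(MASS::mvrnorm(nPerTimepoint[i], mu = rep(0, p),
                                 Sigma = sigma))
            if (noiseSd > 0)
                x <- x + matrix(stats::rnorm(length(x), sd = noiseSd),
                                nrow = p)
            rownames(x) <- genes
            colnames(x) <- sprintf("%s_s%02d", tps[i],
                                   seq_len(nPerTimepoint[i]))
            x
        })
        values <- do.call(cbind, blocks)
        labels <- rep(tps, nPerTimepoint)
        if (length(truth@shiftedGenes) && truth@shiftSize != 0) {
            post <- labels == tps[length(tps)]
            values[truth@shiftedGenes, post] <-
                values[truth@shiftedGenes, post] + truth@shiftSize
        }
        TimecourseExperiment(values, labels, timepointLevels = tps)
    })
}
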
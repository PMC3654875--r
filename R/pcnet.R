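# first-order Spearman partial-correlation network inference
#
# Edge rule: a pair (i, j) is linked iff its zero-order Spearman
# correlation is significant at alpha AND, for every other gene k in the
# node set, the first-order partial correlation rho_ij.k is significant
# at alpha. Significance of a partial correlation of order q uses the
# t approximation t = rho * sqrt((n - 2 - q) / (1 - rho^2)) with
# n - 2 - q degrees of freedom, two-sided.

# critical |rho| equivalent to two-sided p < alpha at the given order
.rhoCritical <- function(n, order, alpha) {
    df <- n - 2L - order
    tcrit <- stats::qt(1 - alpha / 2, df = df)
    tcrit / sqrt(df + tcrit^2)
}

.partialPValue <- function(rho, n, order) {
    df <- n - 2L - order
    tt <- abs(rho) * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
    2 * stats::pt(-tt, df = df)
}

#' Spearman rank correlation matrix for one time point
#'
#' Computes, within the samples of a single time point, the Pearson
#' correlation of the per-gene mid-ranks -- the Spearman rank correlation,
#' with ties handled by mid-ranks. A gene that is constant across the
#' time point's samples has undefined correlations; its row and column
#' are set to 0 (never significant) and a warning names the genes.
#'
#' @param expr a [TimecourseExperiment-class].
#' @param timepoint single time point label.
#' @param geneIds optional subset of genes (default: all genes).
#' @return A [CorrelationMatrix-class].
#' @examples
#' truth <- makeSyntheticTruth(20, 25, nHubs = 0, nShifted = 0, seed = 1)
#' tc <- sampleExpression(truth, c(pre = 20, mid = 20, post = 20),
#'                        partialStrength = 0.4, seed = 2)
#' cm <- spearmanMatrix(tc, "pre")
#' @export
spearmanMatrix <- function(expr, timepoint, geneIds = NULL) {
    stopifnot(is(expr, "TimecourseExperiment"))
    x <- exprMatrix(expr, timepoint)
    if (!is.null(geneIds)) {
        missing <- setdiff(geneIds, rownames(x))
        if (length(missing))
            stop("gene(s) not in the expression matrix: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        x <- x[geneIds, , drop = FALSE]
    }
    n <- ncol(x)
    if (n < 4L)
        stop("at least 4 samples are required at timepoint '",
             timepoint, "' (found ", n, ")")
    ranks <- t(apply(x, 1L, rank))          # mid-ranks for ties
    constant <- apply(ranks, 1L, function(z) max(z) == min(z))
    r <- suppressWarnings(stats::cor(t(ranks)))
    if (any(constant)) {
        warning("constant gene(s) at timepoint '", timepoint, "': ",
                paste(rownames(x)[constant], collapse = ", "),
                "; their correlations are set to 0")
        r[constant, ] <- 0
        r[, constant] <- 0
    }
    diag(r) <- 1
    new("CorrelationMatrix", geneIds = rownames(x), r = r,
        nSamples = as.integer(n))
}

#' First-order partial correlation from three pairwise correlations
#'
#' Removes the linear effect of a single conditioning gene `k` from the
#' correlation of genes `i` and `j` via the recursion
#' `rho_ij.k = (r_ij - r_ik * r_jk) / sqrt((1 - r_ik^2) * (1 - r_jk^2))`.
#' All arguments may be vectors (recycled).
#'
#' @param rIj,rIk,rJk pairwise (Spearman) correlations.
#' @return The first-order partial correlation(s). `NaN` where
#'   `|rIk| = 1` or `|rJk| = 1` (undefined; callers must skip such
#'   conditioners).
#' @examples
#' firstOrderPartial(0.8, 0.5, 0.5)   # 0.55 / 0.75
#' @export
firstOrderPartial <- function(rIj, rIk, rJk) {
    (rIj - rIk * rJk) / sqrt((1 - rIk^2) * (1 - rJk^2))
}

#' Test a single gene pair for a direct coexpression link
#'
#' Reference (pairwise-loop) implementation of the edge decision: the
#' pair is an edge iff the zero-order correlation is significant at
#' `alpha` and the first-order partial correlation given every other
#' gene in the node set is significant at `alpha`. Conditioners with
#' `|r| = 1` against either gene are skipped (the partial is undefined
#' there) with a message. [buildNetwork()] computes the same decision
#' algebraically from the correlation matrix; the two agree exactly.
#'
#' @param i,j gene identifiers (or integer indices into the node set).
#' @param corr a [CorrelationMatrix-class] over the node set.
#' @param alpha per-test significance threshold (default 0.01).
#' @return List with elements `edge` (logical), `r` (zero-order
#'   correlation), `min_abs_partial` (smallest `|rho_ij.k|` over
#'   conditioners) and `max_p` (largest p-value across the zero- and
#'   first-order tests).
#' @export
edgeTest <- function(i, j, corr, alpha = 0.01) {
    stopifnot(is(corr, "CorrelationMatrix"))
    p <- length(corr@geneIds)
    if (p < 3L) stop("the node set must contain at least 3 genes")
    n <- corr@nSamples
    if (n - 3L <= 0L)
        stop("too few samples (n = ", n,
             ") for first-order testing; need n > 3")
    if (is.character(i)) i <- match(i, corr@geneIds)
    if (is.character(j)) j <- match(j, corr@geneIds)
    stopifnot(!is.na(i), !is.na(j), i != j)
    r <- corr@r
    rij <- r[i, j]
    p0 <- .partialPValue(rij, n, 0L)
    ks <- setdiff(seq_len(p), c(i, j))
    usable <- abs(r[i, ks]) < 1 & abs(r[j, ks]) < 1
    if (any(!usable))
        message("skipping ", sum(!usable), " conditioner(s) with |r| = 1 ",
                "for pair (", corr@geneIds[i], ", ", corr@geneIds[j], ")")
    ks <- ks[usable]
    partials <- firstOrderPartial(rij, r[i, ks], r[j, ks])
    p1 <- .partialPValue(partials, n, 1L)
    maxP <- max(p0, p1)
    minAbs <- if (length(partials)) min(abs(partials)) else NA_real_
    list(edge = p0 < alpha && all(p1 < alpha),
         r = rij, min_abs_partial = minAbs, max_p = maxP)
}

# vectorized core shared by buildNetwork and permutationNull:
# takes a ranks-correlation matrix, returns edge matrix + per-pair stats
.networkCore <- function(r, n, alpha, stats = TRUE) {
    p <- nrow(r)
    rc0 <- .rhoCritical(n, 0L, alpha)
    rc1 <- .rhoCritical(n, 1L, alpha)
    minAbs <- matrix(Inf, p, p)
    for (k in seq_len(p)) {
        rk <- r[, k]
        den2 <- 1 - rk^2
        pk <- abs(r - outer(rk, rk)) / sqrt(outer(den2, den2))
        pk[k, ] <- Inf                 # k conditions no pair containing k
        pk[, k] <- Inf
        pk[!is.finite(pk)] <- Inf      # |r| = 1 conditioner: skip
        minAbs <- pmin(minAbs, pk)
    }
    zero <- abs(r) > rc0
    diag(zero) <- FALSE
    edge <- zero & minAbs > rc1
    out <- list(edge = edge, zeroOrderCount = sum(zero) / 2L)
    if (stats) out$minAbs <- minAbs
    out
}

#' Infer the coexpression network of one time point
#'
#' Applies the first-order partial-correlation edge rule (see
#' [edgeTest()]) to every unordered pair of the node set, using an
#' algebraically vectorized computation on the Spearman correlation
#' matrix; results are identical to the pairwise loop. Only pairs whose
#' zero-order correlation and all first-order partial correlations reach
#' significance at `alpha` become links, which excludes pairs whose
#' association is explained by a single common regulator.
#'
#' @param expr a [TimecourseExperiment-class].
#' @param timepoint single time point label.
#' @param nodeIds character vector of genes to use as the (shared) node
#'   set; default all genes. Must have at least 3 genes.
#' @param alpha per-test significance threshold (default 0.01).
#' @return A [CoexpressionNetwork-class].
#' @examples
#' truth <- makeSyntheticTruth(20, 20, nHubs = 0, nShifted = 0, seed = 1)
#' tc <- sampleExpression(truth, c(pre = 40, mid = 40, post = 40),
#'                        partialStrength = 0.5, seed = 2)
#' net <- buildNetwork(tc, "pre")
#' net
#' @export
buildNetwork <- function(expr, timepoint, nodeIds = NULL, alpha = 0.01) {
    corr <- spearmanMatrix(expr, timepoint, geneIds = nodeIds)
    p <- length(corr@geneIds)
    if (p < 3L) stop("the node set must contain at least 3 genes")
    n <- corr@nSamples
    if (n - 3L <= 0L)
        stop("too few samples (n = ", n,
             ") for first-order testing; need n > 3")
    if (alpha <= 0 || alpha >= 1)
        stop("'alpha' must lie strictly between 0 and 1")
    core <- .networkCore(corr@r, n, alpha)
    ut <- upper.tri(core$edge)
    hit <- which(core$edge & ut, arr.ind = TRUE)
    ids <- corr@geneIds
    if (nrow(hit)) {
        rij <- corr@r[hit]
        minAbs <- core$minAbs[hit]
        maxP <- pmax(.partialPValue(rij, n, 0L),
                     .partialPValue(minAbs, n, 1L))
        et <- data.frame(gene_a = ids[hit[, 1L]], gene_b = ids[hit[, 2L]],
                         r = rij, min_abs_partial = minAbs, max_p = maxP,
                         stringsAsFactors = FALSE)
        swap <- et$gene_a > et$gene_b
        tmp <- et$gene_a[swap]
        et$gene_a[swap] <- et$gene_b[swap]
        et$gene_b[swap] <- tmp
        et <- et[order(et$gene_a, et$gene_b), , drop = FALSE]
        rownames(et) <- NULL
    } else {
        et <- data.frame(gene_a = character(), gene_b = character(),
                         r = numeric(), min_abs_partial = numeric(),
                         max_p = numeric(), stringsAsFactors = FALSE)
    }
    new("CoexpressionNetwork", timepoint = timepoint,
        nodeIds = ids, edgeTable = et, nSamples = n,
        alpha = alpha, zeroOrderCount = as.integer(core$zeroOrderCount))
}

#' Permutation-null validation of a network's edge count
#'
#' Each replicate independently permutes every gene's values across the
#' time point's samples -- destroying all inter-gene association while
#' preserving the marginal distributions -- rebuilds the network under
#' the identical edge rule, and counts edges. The observed network is
#' validated when its edge count exceeds the maximum of the null
#' distribution.
#'
#' Replicate `r` draws its permutations under a seed derived from the
#' master seed (the master seed generates one sub-seed per replicate), so
#' results are reproducible and replicates are independent.
#'
#' @param expr a [TimecourseExperiment-class].
#' @param timepoint single time point label.
#' @param nodeIds node set (default all genes).
#' @param alpha per-test significance threshold (default 0.01).
#' @param nPermutations number of null replicates (default 1000).
#' @param seed integer master seed (required).
#' @return List with elements `observed_edge_count`, `null_counts`
#'   (length `nPermutations`), `null_max` and `exceeds_null`
#'   (`observed_edge_count > null_max`).
#' @export
permutationNull <- function(expr, timepoint, nodeIds = NULL, alpha = 0.01,
                            nPermutations = 1000L, seed) {
    stopifnot(is(expr, "TimecourseExperiment"), nPermutations >= 1L)
    corr <- spearmanMatrix(expr, timepoint, geneIds = nodeIds)
    n <- corr@nSamples
    observed <- .networkCore(corr@r, n, alpha, stats = FALSE)
    x <- exprMatrix(expr, timepoint)
    if (!is.null(nodeIds)) x <- x[nodeIds, , drop = FALSE]
    ranks <- t(apply(x, 1L, rank))
    repSeeds <- .withSeed(seed,
                          sample.int(.Machine$integer.max, nPermutations))
    nullCounts <- vapply(seq_len(nPermutations), function(b) {
        perm <- .withSeed(repSeeds[b], {
            t(apply(ranks, 1L, sample))
        })
        r <- suppressWarnings(stats::cor(t(perm)))
        r[!is.finite(r)] <- 0
        diag(r) <- 1
        core <- .networkCore(r, n, alpha, stats = FALSE)
        as.integer(sum(core$edge) / 2L)
    }, integer(1L))
    obsCount <- as.integer(sum(observed$edge) / 2L)
    list(observed_edge_count = obsCount,
         null_counts = nullCounts,
         null_max = max(nullCounts),
         exceeds_null = obsCount > max(nullCounts))
}
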
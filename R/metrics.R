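# network topology characterization

#' Pair capacity of a simple graph
#'
#' Number of unordered node pairs -- the maximum possible link count of a
#' simple undirected graph with `nNodes` nodes.
#'
#' @param nNodes number of nodes.
#' @return `nNodes * (nNodes - 1) / 2`.
#' @examples
#' maxLinks(1044)
#' @export
maxLinks <- function(nNodes) {
    nNodes <- as.numeric(nNodes)
    nNodes * (nNodes - 1) / 2
}

#' Degree sequence of a network
#'
#' @param net a [CoexpressionNetwork-class] or [PlantedGraph-class].
#' @return Named integer vector (one entry per node, including degree-0
#'   nodes), in node-set order. The sum equals twice the edge count.
#' @export
degreeSequence <- function(net) {
    g <- asIgraph(net)
    d <- igraph::degree(g)
    stats::setNames(as.integer(d), names(d))
}

#' Kolmogorov-Smirnov comparison of two degree distributions
#'
#' Two-sample KS test on the full degree sequences of two networks
#' (all nodes, including degree-0 nodes), with the asymptotic two-sided
#' p-value. Used to ask whether treatment shifts the overall connectivity
#' distribution between time points.
#'
#' @param netA,netB two [CoexpressionNetwork-class] objects (or anything
#'   accepted by [degreeSequence()]).
#' @return List with elements `D` and `p_value`.
#' @export
ksCompareDegrees <- function(netA, netB) {
    da <- degreeSequence(netA)
    db <- degreeSequence(netB)
    kt <- suppressWarnings(stats::ks.test(da, db, exact = FALSE))
    list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Largest connected component of a network
#'
#' @param net a [CoexpressionNetwork-class] or [PlantedGraph-class].
#' @return Sorted character vector of the member nodes of the
#'   maximum-cardinality connected component. Ties are broken by the
#'   lexicographically smallest member.
#' @export
largestComponent <- function(net) {
    g <- asIgraph(net)
    comp <- igraph::components(g)
    best <- which(comp$csize == max(comp$csize))
    if (length(best) > 1L) {
        firstMember <- vapply(best, function(b)
            min(names(comp$membership)[comp$membership == b]),
            character(1L))
        best <- best[order(firstMember)[1L]]
    }
    sort(names(comp$membership)[comp$membership == best])
}

#' Mean shortest path length within a node subset
#'
#' Unweighted breadth-first shortest paths, averaged over all unordered
#' pairs of the subset. The subset must be connected in the network;
#' pairs spanning components are never averaged with a sentinel distance.
#'
#' @param net a [CoexpressionNetwork-class] or [PlantedGraph-class].
#' @param within node subset to average over; defaults to the largest
#'   connected component.
#' @return Mean shortest path length, in links.
#' @export
meanShortestPath <- function(net, within = largestComponent(net)) {
    g <- asIgraph(net)
    if (length(within) < 2L)
        stop("'within' must contain at least 2 nodes")
    sub <- igraph::induced_subgraph(g, within)
    if (!igraph::is_connected(sub))
        stop("the node subset is not connected in the network")
    igraph::mean_distance(sub)
}

#' Global clustering coefficient (transitivity)
#'
#' Probability that two neighbors of a node are themselves neighbors:
#' three times the number of triangles divided by the number of connected
#' triples. Returns 0 when the network has no connected triples
#' (documented convention).
#'
#' @param net a [CoexpressionNetwork-class] or [PlantedGraph-class].
#' @return Transitivity in `[0, 1]`.
#' @export
globalClustering <- function(net) {
    tr <- igraph::transitivity(asIgraph(net), type = "global")
    if (is.nan(tr) || is.na(tr)) 0 else tr
}

#' One-row topology summary of a network
#'
#' @param net a [CoexpressionNetwork-class] or [PlantedGraph-class].
#' @return data.frame with columns `timepoint`, `n_nodes`, `n_links`,
#'   `lcc_size`, `mean_path_length` (NA when the largest component has
#'   fewer than 2 nodes) and `global_clustering`.
#' @export
topologySummary <- function(net) {
    lcc <- largestComponent(net)
    mpl <- if (length(lcc) >= 2L) meanShortestPath(net, lcc) else NA_real_
    data.frame(
        timepoint = timepointLabel(net),
        n_nodes = length(nodeIds(net)),
        n_links = edgeCount(net),
        lcc_size = length(lcc),
        mean_path_length = mpl,
        global_clustering = globalClustering(net),
        stringsAsFactors = FALSE)
}

#' Topology table for several networks
#'
#' @param nets list of networks (one per time point).
#' @return data.frame with one [topologySummary()] row per network.
#' @export
topologyTable <- function(nets) {
    do.call(rbind, lapply(nets, topologySummary))
}
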
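# hub / bottleneck classification by outlier fences on centrality scores

#' Betweenness centrality scores
#'
#' Unweighted betweenness for every node: the number of shortest paths
#' between other node pairs that pass through the node, with endpoints
#' excluded and fractional credit when several shortest paths tie
#' (Brandes accumulation). Raw, unnormalized counts are returned;
#' outlier fences are scale-equivariant, so normalization would not
#' change role categories. Computed on the full graph including all
#' components (isolated nodes simply score 0).
#'
#' @param net a [CoexpressionNetwork-class] or [PlantedGraph-class].
#' @return Named numeric vector in node-set order.
#' @examples
#' g <- makePlantedGraph(10, 9, nHubs = 1, hubDegree = 9, seed = 1)
#' betweennessScores(g)   # star center: choose(9, 2) = 36
#' @export
betweennessScores <- function(net) {
    g <- asIgraph(net)
    igraph::betweenness(g, directed = FALSE, weights = NULL,
                        normalized = FALSE)
}

#' Tukey upper outlier fence
#'
#' `Q3 + multiplier * IQR` with quartiles by linear interpolation
#' (`quantile` type 7 by default). A score strictly above the fence is a
#' statistical outlier. The multiplier and quartile method are exposed
#' so alternative outlier conventions can be matched.
#'
#' @param scores numeric vector (at least 4 values).
#' @param multiplier IQR multiplier (default 1.5, Tukey's fence).
#' @param quartileType quantile algorithm type (default 7, linear
#'   interpolation).
#' @return List with elements `fence` and `rule` (a descriptor recording
#'   the method, multiplier and quartile type, for auditability).
#' @examples
#' outlierFence(c(rep(1, 10), 10))$fence   # 1; only the 10 is an outlier
#' @export
outlierFence <- function(scores, multiplier = 1.5, quartileType = 7L) {
    if (length(scores) < 4L)
        stop("at least 4 scores are required to compute quartile fences")
    q <- stats::quantile(scores, c(0.25, 0.75), type = quartileType,
                         names = FALSE)
    list(fence = q[2L] + multiplier * (q[2L] - q[1L]),
         rule = list(method = "tukey_upper",
                     multiplier = multiplier,
                     quartile_type = as.integer(quartileType)))
}

#' Classify nodes into hub / bottleneck role categories
#'
#' Scores every node's degree and betweenness centrality, computes a
#' Tukey upper fence on each score distribution (from the same network),
#' and assigns each node exactly one of four categories: `HB`
#' (hub-bottleneck: both scores above their fences), `HNB`
#' (hub-nonbottleneck: only degree above), `NHB` (nonhub-bottleneck:
#' only betweenness above) and `NHNB` (neither).
#'
#' @param net a [CoexpressionNetwork-class] or [PlantedGraph-class].
#' @param multiplier,quartileType passed to [outlierFence()].
#' @return List with `records` (data.frame: `gene_id`, `timepoint`,
#'   `degree`, `betweenness`, `category`) and `fences` (the degree and
#'   betweenness fences with their rule descriptor).
#' @examples
#' g <- makePlantedGraph(30, 10, nHubs = 1, hubDegree = 10, seed = 1)
#' roles <- classifyNodes(g)
#' table(roles$records$category)
#' @export
classifyNodes <- function(net, multiplier = 1.5, quartileType = 7L) {
    deg <- degreeSequence(net)
    btw <- betweennessScores(net)
    fd <- outlierFence(deg, multiplier, quartileType)
    fb <- outlierFence(btw, multiplier, quartileType)
    isHub <- deg > fd$fence
    isBot <- btw > fb$fence
    category <- factor(ifelse(isHub & isBot, "HB",
                       ifelse(isHub, "HNB",
                       ifelse(isBot, "NHB", "NHNB"))),
                       levels = c("HB", "HNB", "NHB", "NHNB"))
    list(records = data.frame(
             gene_id = names(deg),
             timepoint = timepointLabel(net),
             degree = as.integer(deg),
             betweenness = unname(btw),
             category = category,
             row.names = NULL, stringsAsFactors = FALSE),
         fences = list(degree_fence = fd$fence,
                       betweenness_fence = fb$fence,
                       rule = fd$rule))
}
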
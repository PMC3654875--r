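#' Node identifiers of a graph-like object
#'
#' @param x a [PlantedGraph-class] or [CoexpressionNetwork-class].
#' @return Character vector of gene identifiers, in stored order.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Number of edges of a graph-like object
#'
#' @param x a [PlantedGraph-class] or [CoexpressionNetwork-class].
#' @return Integer edge count.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Edge pairs of a graph-like object
#'
#' @param x a [PlantedGraph-class] or [CoexpressionNetwork-class].
#' @return Character matrix with two columns (`gene_a`, `gene_b`), each
#'   row an unordered pair in canonical sorted form.
#' @export
setGeneric("edgePairs", function(x) standardGeneric("edgePairs"))

#' Convert a graph-like object to an igraph graph
#'
#' The returned graph is undirected and simple and carries the full node
#' set as vertices (including isolated nodes), so degree-0 genes are
#' preserved in every downstream topology computation.
#'
#' @param x a [PlantedGraph-class] or [CoexpressionNetwork-class].
#' @return An [igraph][igraph::graph_from_data_frame] object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Time point label of an object
#'
#' @param x a [PlantedGraph-class] or [CoexpressionNetwork-class].
#' @return Length-one character label.
#' @export
setGeneric("timepointLabel", function(x) standardGeneric("timepointLabel"))

#' Per-sample time point assignments
#'
#' @param x a [TimecourseExperiment-class].
#' @return Factor of time point labels, one per sample, with the ordered
#'   level vocabulary of the experiment.
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))
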
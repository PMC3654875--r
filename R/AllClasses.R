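#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# canonical edge matrix: character, 2 columns, each row sorted a < b,
# rows sorted lexicographically, no duplicates, no self loops
.validEdgeMatrix <- function(edges, nodeIds) {
    if (!is.character(edges) || !is.matrix(edges) || ncol(edges) != 2L)
        return("'edges' must be a character matrix with 2 columns")
    if (nrow(edges) > 0L) {
        if (any(edges[, 1L] == edges[, 2L]))
            return("self loops are not allowed")
        if (any(edges[, 1L] > edges[, 2L]))
            return("edge endpoints must be sorted within each row (a < b)")
        key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
        if (anyDuplicated(key))
            return("duplicate edges are not allowed")
        if (!all(edges %in% nodeIds))
            return("all edge endpoints must be in the node set")
    }
    TRUE
}

#' PlantedGraph: a known conditional-dependence graph for one time point
#'
#' Container for a simple undirected graph planted by the synthetic-data
#' generator. It stands in for the (unknown) true regulatory network that
#' the inferred coexpression networks estimate, so that downstream stages
#' can be validated against ground truth.
#'
#' @slot nodeIds character vector of gene identifiers (ordered, unique).
#' @slot edges character matrix with two columns; each row is an unordered
#'   gene pair stored in canonical form (first column lexicographically
#'   smaller, rows sorted). No self loops, no duplicates.
#' @slot timepoint length-one character label, e.g. `"pre"`.
#'
#' @seealso [makePlantedGraph()], [rewireGraph()], [graphToPrecision()]
#' @export
setClass("PlantedGraph",
    representation(nodeIds = "character", edges = "matrix",
                   timepoint = "character"),
    validity = function(object) {
        msgs <- character()
        if (anyDuplicated(object@nodeIds))
            msgs <- c(msgs, "node ids must be unique")
        if (length(object@timepoint) != 1L)
            msgs <- c(msgs, "'timepoint' must be a single label")
        v <- .validEdgeMatrix(object@edges, object@nodeIds)
        if (!isTRUE(v)) msgs <- c(msgs, v)
        if (length(msgs)) msgs else TRUE
    })

#' SyntheticTruth: planted graphs and perturbations for a simulated study
#'
#' Bundles one [PlantedGraph-class] per ordered time point together with
#' the requested inter-timepoint edge overlap, the genes given a
#' pre-to-post mean shift, the shift size, and the seed that produced
#' them. The consecutive graphs share an identical node set and their
#' realized shared-edge fraction equals `round(overlap * nEdges) / nEdges`
#' exactly.
#'
#' @slot graphs list of [PlantedGraph-class] objects, named by time point,
#'   in time order.
#' @slot overlapRequested requested fraction of edges shared between
#'   consecutive planted graphs, in `[0, 1]`.
#' @slot shiftedGenes character vector of gene ids receiving a mean shift
#'   in the last (post) group.
#' @slot shiftSize size of that shift, in log-expression units.
#' @slot seed integer seed used by the generator.
#'
#' @seealso [makeSyntheticTruth()], [sampleExpression()]
#' @export
setClass("SyntheticTruth",
    representation(graphs = "list", overlapRequested = "numeric",
                   shiftedGenes = "character", shiftSize = "numeric",
                   seed = "integer"),
    validity = function(object) {
        msgs <- character()
        if (!all(vapply(object@graphs, is, logical(1L), "PlantedGraph")))
            msgs <- c(msgs, "'graphs' must be a list of PlantedGraph objects")
        else {
            nodesets <- lapply(object@graphs, slot, "nodeIds")
            if (length(nodesets) > 1L &&
                !all(vapply(nodesets[-1L], identical, logical(1L),
                            nodesets[[1L]])))
                msgs <- c(msgs, "all graphs must share an identical node set")
            if (length(object@graphs) > 1L) {
                for (i in seq_len(length(object@graphs) - 1L)) {
                    e1 <- .edgeKeys(object@graphs[[i]])
                    e2 <- .edgeKeys(object@graphs[[i + 1L]])
                    m <- length(e1)
                    if (m > 0L) {
                        got <- length(intersect(e1, e2)) / m
                        if (abs(got - object@overlapRequested) > 1 / m + 1e-12)
                            msgs <- c(msgs, sprintf(
                                "realized edge overlap %.4f between graphs %d and %d is not within 1/%d of requested %.4f",
                                got, i, i + 1L, m, object@overlapRequested))
                    }
                }
            }
            if (length(object@shiftedGenes) &&
                !all(object@shiftedGenes %in% object@graphs[[1L]]@nodeIds))
                msgs <- c(msgs, "'shiftedGenes' must be a subset of the node set")
        }
        if (length(object@overlapRequested) != 1L ||
            object@overlapRequested < 0 || object@overlapRequested > 1)
            msgs <- c(msgs, "'overlapRequested' must be a fraction in [0, 1]")
        if (length(msgs)) msgs else TRUE
    })

#' TimecourseExperiment: expression matrix with ordered time point labels
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose columns (samples) each carry one label from an ordered vocabulary
#' of time points (default `pre`, `mid`, `post`). The single assay
#' `"exprs"` holds log-scale expression values with genes in rows; no
#' missing values are allowed, and gene and sample identifiers must be
#' unique.
#'
#' @seealso [TimecourseExperiment()], [readExpression()],
#'   [sampleExpression()]
#' @export
setClass("TimecourseExperiment",
    contains = "SummarizedExperiment",
    validity = function(object) {
        msgs <- character()
        cd <- SummarizedExperiment::colData(object)
        if (!"timepoint" %in% colnames(cd))
            return("colData must contain a 'timepoint' column")
        tp <- cd$timepoint
        if (!is.factor(tp))
            msgs <- c(msgs, "'timepoint' must be a factor with ordered levels")
        if (anyNA(tp))
            msgs <- c(msgs, "every sample must be assigned exactly one timepoint")
        if (!"exprs" %in% SummarizedExperiment::assayNames(object))
            return("assay 'exprs' is required")
        x <- SummarizedExperiment::assay(object, "exprs")
        if (anyNA(x))
            msgs <- c(msgs, "expression values must not contain missing values")
        if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
            msgs <- c(msgs, "gene ids (rownames) must be present and unique")
        if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
            msgs <- c(msgs, "sample ids (colnames) must be present and unique")
        if (length(msgs)) msgs else TRUE
    })

#' CorrelationMatrix: Spearman rank correlations for one time point
#'
#' Symmetric matrix of Spearman rank correlations between genes, computed
#' from the samples of a single time point, together with the sample count
#' used (which sets the degrees of freedom of all significance tests).
#'
#' @slot geneIds character vector of gene identifiers (row/column order).
#' @slot r symmetric numeric matrix of rank correlations, unit diagonal.
#' @slot nSamples number of samples used.
#'
#' @seealso [spearmanMatrix()], [edgeTest()]
#' @export
setClass("CorrelationMatrix",
    representation(geneIds = "character", r = "matrix",
                   nSamples = "integer"),
    validity = function(object) {
        msgs <- character()
        p <- length(object@geneIds)
        if (!is.numeric(object@r) || nrow(object@r) != p ||
            ncol(object@r) != p)
            return("'r' must be a numeric geneIds x geneIds matrix")
        if (max(abs(object@r - t(object@r))) > 1e-12)
            msgs <- c(msgs, "'r' must be symmetric")
        if (any(abs(object@r) > 1 + 1e-12))
            msgs <- c(msgs, "correlations must lie in [-1, 1]")
        if (max(abs(diag(object@r) - 1)) > 1e-12)
            msgs <- c(msgs, "'r' must have unit diagonal")
        if (length(msgs)) msgs else TRUE
    })

#' CoexpressionNetwork: significant direct correlations at one time point
#'
#' Undirected simple graph over a fixed node set for a single time point.
#' An edge records a gene pair whose zero-order Spearman correlation and
#' every first-order Spearman partial correlation (conditioning on each
#' other gene in the node set in turn) are significant at the configured
#' alpha. Per edge the zero-order correlation, the smallest absolute
#' first-order partial over conditioners, and the largest p-value across
#' all tests are stored.
#'
#' @slot timepoint length-one character label.
#' @slot nodeIds shared node set (ordered character vector).
#' @slot edgeTable data.frame with columns `gene_a`, `gene_b`, `r`,
#'   `min_abs_partial`, `max_p`; pairs in canonical sorted form.
#' @slot nSamples sample count behind the correlation matrix.
#' @slot alpha per-test significance threshold used.
#' @slot zeroOrderCount number of gene pairs whose zero-order correlation
#'   alone is significant at alpha (the first-order edge set is always a
#'   subset of these pairs).
#'
#' @seealso [buildNetwork()], [asIgraph()], [topologySummary()]
#' @export
setClass("CoexpressionNetwork",
    representation(timepoint = "character", nodeIds = "character",
                   edgeTable = "data.frame", nSamples = "integer",
                   alpha = "numeric", zeroOrderCount = "integer"),
    validity = function(object) {
        msgs <- character()
        et <- object@edgeTable
        need <- c("gene_a", "gene_b", "r", "min_abs_partial", "max_p")
        if (!all(need %in% colnames(et)))
            return(paste("edgeTable must have columns",
                         paste(need, collapse = ", ")))
        v <- .validEdgeMatrix(cbind(as.character(et$gene_a),
                                    as.character(et$gene_b)),
                              object@nodeIds)
        if (!isTRUE(v)) msgs <- c(msgs, v)
        if (anyDuplicated(object@nodeIds))
            msgs <- c(msgs, "node ids must be unique")
        p <- length(object@nodeIds)
        if (nrow(et) > p * (p - 1) / 2)
            msgs <- c(msgs, "edge count exceeds the pair capacity of the node set")
        if (length(object@alpha) != 1L || object@alpha <= 0 ||
            object@alpha >= 1)
            msgs <- c(msgs, "'alpha' must lie strictly between 0 and 1")
        if (length(msgs)) msgs else TRUE
    })
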
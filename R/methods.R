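# shared internals -----------------------------------------------------

# canonical "a\rb" keys for set arithmetic on edges
.edgeKeys <- function(x) {
    e <- if (is(x, "PlantedGraph")) x@edges else edgePairs(x)
    if (nrow(e) == 0L) character() else paste(e[, 1L], e[, 2L], sep = "\r")
}

# sort endpoints within rows, then sort rows; returns canonical matrix
.canonicalEdges <- function(a, b) {
    m <- cbind(pmin(a, b), pmax(a, b))
    colnames(m) <- c("gene_a", "gene_b")
    m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

# evaluate code under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    code
}

# accessors -------------------------------------------------------------

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "PlantedGraph", function(x) x@nodeIds)

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "CoexpressionNetwork", function(x) x@nodeIds)

#' @rdname edgeCount
#' @export
setMethod("edgeCount", "PlantedGraph", function(x) nrow(x@edges))

#' @rdname edgeCount
#' @export
setMethod("edgeCount", "CoexpressionNetwork",
          function(x) nrow(x@edgeTable))

#' @rdname edgePairs
#' @export
setMethod("edgePairs", "PlantedGraph", function(x) x@edges)

#' @rdname edgePairs
#' @export
setMethod("edgePairs", "CoexpressionNetwork", function(x) {
    m <- cbind(as.character(x@edgeTable$gene_a),
               as.character(x@edgeTable$gene_b))
    colnames(m) <- c("gene_a", "gene_b")
    m
})

#' @rdname timepointLabel
#' @export
setMethod("timepointLabel", "PlantedGraph", function(x) x@timepoint)

#' @rdname timepointLabel
#' @export
setMethod("timepointLabel", "CoexpressionNetwork", function(x) x@timepoint)

#' @rdname timepoints
#' @export
setMethod("timepoints", "TimecourseExperiment", function(x)
    SummarizedExperiment::colData(x)$timepoint)

#' Ordered time point vocabulary of an experiment
#'
#' @param x a [TimecourseExperiment-class].
#' @return Character vector of time point levels in time order.
#' @export
timepointLevels <- function(x) {
    stopifnot(is(x, "TimecourseExperiment"))
    levels(timepoints(x))
}

#' Extract the expression matrix, optionally for one time point
#'
#' @param x a [TimecourseExperiment-class].
#' @param timepoint optional single time point label; when given, only the
#'   samples of that time point are returned.
#' @return Numeric genes x samples matrix.
#' @export
exprMatrix <- function(x, timepoint = NULL) {
    stopifnot(is(x, "TimecourseExperiment"))
    m <- SummarizedExperiment::assay(x, "exprs")
    if (!is.null(timepoint)) {
        if (!timepoint %in% timepointLevels(x))
            stop("unknown timepoint '", timepoint, "'; allowed: ",
                 paste(timepointLevels(x), collapse = ", "))
        m <- m[, timepoints(x) == timepoint, drop = FALSE]
    }
    m
}

# igraph conversion -----------------------------------------------------

.igraphFromEdges <- function(edges, nodes) {
    igraph::graph_from_data_frame(
        data.frame(from = edges[, 1L], to = edges[, 2L],
                   stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
}

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "PlantedGraph", function(x)
    .igraphFromEdges(x@edges, x@nodeIds))

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "CoexpressionNetwork", function(x) {
    g <- .igraphFromEdges(edgePairs(x), x@nodeIds)
    if (edgeCount(x) > 0L) {
        igraph::E(g)$r <- x@edgeTable$r
        igraph::E(g)$min_abs_partial <- x@edgeTable$min_abs_partial
        igraph::E(g)$max_p <- x@edgeTable$max_p
    }
    g
})

# show methods ----------------------------------------------------------

setMethod("show", "PlantedGraph", function(object) {
    cat("PlantedGraph [", object@timepoint, "]: ",
        length(object@nodeIds), " nodes, ", nrow(object@edges),
        " edges\n", sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth: ", length(object@graphs),
        " planted graphs (", paste(names(object@graphs), collapse = " -> "),
        ")\n  requested consecutive edge overlap: ",
        object@overlapRequested, "\n  shifted genes: ",
        length(object@shiftedGenes), " (shift ", object@shiftSize,
        ")\n  seed: ", object@seed, "\n", sep = "")
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat("CorrelationMatrix: ", length(object@geneIds), " genes, n = ",
        object@nSamples, " samples\n", sep = "")
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork [", object@timepoint, "]: ",
        length(object@nodeIds), " nodes, ", nrow(object@edgeTable),
        " edges (alpha = ", object@alpha, ", n = ", object@nSamples,
        ")\n", sep = "")
})

# constructor -----------------------------------------------------------

#' Build a TimecourseExperiment from a matrix and time point labels
#'
#' @param values numeric genes x samples matrix with unique row and
#'   column names (log-scale expression).
#' @param timepoints character or factor of per-sample time point labels,
#'   one per column of `values`.
#' @param timepointLevels ordered vocabulary of allowed labels; defaults
#'   to the three-point treatment design `pre`, `mid`, `post`.
#' @return A [TimecourseExperiment-class].
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' tc <- TimecourseExperiment(m, c("pre", "pre", "post", "post"))
#' timepoints(tc)
#' @export
TimecourseExperiment <- function(values, timepoints,
                                 timepointLevels = c("pre", "mid", "post")) {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix (genes x samples)")
    timepoints <- as.character(timepoints)
    if (length(timepoints) != ncol(values))
        stop("need exactly one timepoint label per sample")
    bad <- setdiff(unique(timepoints), timepointLevels)
    if (length(bad))
        stop("unknown timepoint label(s) ", paste(bad, collapse = ", "),
             "; allowed labels: ", paste(timepointLevels, collapse = ", "))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(
            timepoint = factor(timepoints, levels = timepointLevels),
            row.names = colnames(values)))
    new("TimecourseExperiment", se)
}
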
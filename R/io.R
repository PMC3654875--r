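# file I/O (TSV / GraphML / JSON) and the end-to-end pipeline driver
#
# canonical tabular dialect: tab-separated, UTF-8, '.' decimal; numeric
# columns are written with 17 significant digits so write-then-read
# round-trips reproduce doubles exactly

.fmtNum <- function(x) {
    out <- formatC(x, digits = 17, format = "g", flag = "-")
    trimws(out)
}

.writeTsv <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

.writeJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read an expression matrix and sample metadata from TSV files
#'
#' The expression file has a header row of sample ids and the gene id in
#' the first column; the metadata file has columns `sample_id` and
#' `timepoint`. Duplicate gene ids, malformed numeric cells (reported
#' with their row and column), samples without a metadata row, and
#' unknown timepoint labels are all rejected with explanatory errors;
#' metadata rows for samples absent from the matrix produce a warning.
#'
#' @param exprPath path to the expression TSV (genes x samples).
#' @param metaPath path to the two-column sample metadata TSV.
#' @param timepointLevels ordered vocabulary of allowed labels.
#' @return A [TimecourseExperiment-class].
#' @seealso [writeExpression()]
#' @export
readExpression <- function(exprPath, metaPath,
                           timepointLevels = c("pre", "mid", "post")) {
    for (p in c(exprPath, metaPath))
        if (!file.exists(p)) stop("file not found: ", p)
    raw <- utils::read.table(exprPath, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
    if (ncol(raw) < 2L)
        stop("expression file needs a gene-id column plus >= 1 sample")
    geneIds <- raw[[1L]]
    dup <- unique(geneIds[duplicated(geneIds)])
    if (length(dup))
        stop("duplicated gene id(s) in expression file: ",
             paste(utils::head(dup, 5L), collapse = ", "))
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    bad <- which(is.na(num) & !(toupper(vals) %in% "NA"), arr.ind = TRUE)
    if (nrow(bad))
        stop("malformed numeric cell '", vals[bad[1L, , drop = FALSE]],
             "' at gene row ", bad[1L, 1L], " (", geneIds[bad[1L, 1L]],
             "), sample column ", bad[1L, 2L], " (",
             colnames(vals)[bad[1L, 2L]], ")")
    if (anyNA(num))
        stop("missing values (NA) are not allowed in the expression matrix")
    dimnames(num) <- list(geneIds, colnames(vals))
    meta <- utils::read.table(metaPath, header = TRUE, sep = "\t",
                              check.names = FALSE,
                              colClasses = "character", quote = "",
                              comment.char = "")
    if (!all(c("sample_id", "timepoint") %in% colnames(meta)))
        stop("metadata file must have columns 'sample_id' and 'timepoint'")
    badLab <- setdiff(unique(meta$timepoint), timepointLevels)
    if (length(badLab))
        stop("unknown timepoint label(s): ",
             paste(badLab, collapse = ", "), "; allowed labels: ",
             paste(timepointLevels, collapse = ", "))
    tpOf <- stats::setNames(meta$timepoint, meta$sample_id)
    unlabeled <- setdiff(colnames(num), meta$sample_id)
    if (length(unlabeled))
        stop("missing timepoint label for sample(s): ",
             paste(utils::head(unlabeled, 5L), collapse = ", "))
    extra <- setdiff(meta$sample_id, colnames(num))
    if (length(extra))
        warning("metadata lists sample(s) not in the expression matrix: ",
                paste(utils::head(extra, 5L), collapse = ", "))
    TimecourseExperiment(num, tpOf[colnames(num)],
                         timepointLevels = timepointLevels)
}

#' Write an expression matrix and its sample metadata as TSV
#'
#' @param expr a [TimecourseExperiment-class].
#' @param exprPath output path for the genes x samples TSV (first column
#'   `gene_id`, header row of sample ids).
#' @param metaPath output path for the two-column metadata TSV
#'   (`sample_id`, `timepoint`).
#' @return Invisibly, the two paths.
#' @seealso [readExpression()]
#' @export
writeExpression <- function(expr, exprPath, metaPath) {
    stopifnot(is(expr, "TimecourseExperiment"))
    m <- exprMatrix(expr)
    df <- data.frame(gene_id = rownames(m), stringsAsFactors = FALSE)
    for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
    .writeTsv(df, exprPath)
    .writeTsv(data.frame(sample_id = colnames(m),
                         timepoint = as.character(timepoints(expr)),
                         stringsAsFactors = FALSE), metaPath)
    invisible(c(exprPath, metaPath))
}

#' Write a planted graph as a two-column edge list
#'
#' @param g a [PlantedGraph-class].
#' @param path output TSV path (columns `gene_a`, `gene_b`).
#' @return Invisibly, the path.
#' @export
writeGraphEdges <- function(g, path) {
    stopifnot(is(g, "PlantedGraph"))
    .writeTsv(as.data.frame(edgePairs(g), stringsAsFactors = FALSE), path)
}

#' Write the parameters of a synthetic truth as JSON
#'
#' Sidecar recording the generator configuration (including the seed) so
#' a simulated data set can be regenerated exactly.
#'
#' @param truth a [SyntheticTruth-class].
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
writeTruth <- function(truth, path) {
    stopifnot(is(truth, "SyntheticTruth"))
    .writeJson(list(
        timepoints = names(truth@graphs),
        n_genes = length(nodeIds(truth@graphs[[1L]])),
        n_edges = vapply(truth@graphs, edgeCount, integer(1L)),
        overlap_requested = truth@overlapRequested,
        shifted_genes = truth@shiftedGenes,
        shift_size = truth@shiftSize,
        seed = truth@seed), path)
}

#' Write a coexpression network as a tab-separated edge list
#'
#' Columns: `gene_a`, `gene_b`, `r`, `min_abs_partial`, `max_p`.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @seealso [readNetwork()], [writeNetworkGraphML()]
#' @export
writeNetwork <- function(net, path) {
    stopifnot(is(net, "CoexpressionNetwork"))
    .writeTsv(net@edgeTable, path)
}

#' Read a coexpression network back from an edge-list TSV
#'
#' Reconstructs a [CoexpressionNetwork-class] from a file written by
#' [writeNetwork()] plus the run parameters that the edge list itself
#' does not carry (node set, time point, sample count, alpha).
#'
#' @param path edge-list TSV path.
#' @param nodeIds full node set of the network (isolated nodes are not
#'   present in the edge list).
#' @param timepoint time point label.
#' @param nSamples sample count used to build the network.
#' @param alpha significance threshold used.
#' @param zeroOrderCount optional zero-order significant pair count.
#' @return A [CoexpressionNetwork-class].
#' @export
readNetwork <- function(path, nodeIds, timepoint, nSamples, alpha,
                        zeroOrderCount = NA_integer_) {
    et <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           "numeric", "numeric",
                                           "numeric"),
                            quote = "", comment.char = "")
    new("CoexpressionNetwork", timepoint = timepoint,
        nodeIds = nodeIds, edgeTable = et,
        nSamples = as.integer(nSamples), alpha = alpha,
        zeroOrderCount = as.integer(zeroOrderCount))
}

#' Write a coexpression network as GraphML
#'
#' Standard graph interchange format; edge attributes `r`,
#' `min_abs_partial` and `max_p` are carried along.
#'
#' @param net a [CoexpressionNetwork-class].
#' @param path output GraphML path.
#' @return Invisibly, the path.
#' @export
writeNetworkGraphML <- function(net, path) {
    stopifnot(is(net, "CoexpressionNetwork"))
    igraph::write_graph(asIgraph(net), path, format = "graphml")
    invisible(path)
}

.stage <- function(name, code) {
    tryCatch(code, error = function(e)
        stop("pipeline stage '", name, "' failed: ",
             conditionMessage(e), call. = FALSE))
}

#' Run the full temporal-coexpression pipeline
#'
#' Executes the complete analysis on a three-timepoint experiment:
#' differential-expression screen (skipped when an explicit node set is
#' supplied), per-timepoint first-order partial-correlation networks with
#' optional permutation-null validation, topology summaries and KS degree
#' comparisons, hub/bottleneck role classification, and the rewiring
#' summary. All stage outputs are written under `outDir` together with a
#' machine-readable run report capturing the configuration, the seed and
#' every summary statistic; identical configuration and seed reproduce
#' identical outputs byte for byte.
#'
#' @param expr a [TimecourseExperiment-class] with exactly three time
#'   point levels.
#' @param outDir output directory (created if needed).
#' @param nodes optional explicit node set (character vector of gene
#'   ids); when supplied, the differential-expression stage is skipped.
#' @param contrast,fdrThreshold passed to [fitGeneModels()].
#' @param alpha edge-test significance threshold (default 0.01).
#' @param nPermutations permutation-null replicates per time point
#'   (default 1000; 0 skips the permutation stage).
#' @param seed integer master seed for the permutation stage.
#' @param multiplier,quartileType outlier-fence parameters, see
#'   [outlierFence()].
#' @return Invisibly, a list with all in-memory stage results
#'   (`de_table`, `node_set`, `networks`, `permutation`, `topology`,
#'   `ks`, `roles`, `rewiring`, `report`).
#' @export
runPipeline <- function(expr, outDir, nodes = NULL,
                        contrast = c("pre", "post"), fdrThreshold = 0.05,
                        alpha = 0.01, nPermutations = 1000L, seed = 1L,
                        multiplier = 1.5, quartileType = 7L) {
    stopifnot(is(expr, "TimecourseExperiment"))
    tps <- timepointLevels(expr)
    if (length(tps) != 3L)
        stop("the pipeline expects exactly three timepoint levels, got: ",
             paste(tps, collapse = ", "))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(seed)

    deTable <- NULL
    if (is.null(nodes)) {
        deTable <- .stage("diffexpr",
                          fitGeneModels(expr, contrast, fdrThreshold))
        nodes <- .stage("diffexpr", selectNodeSet(deTable))
        .writeTsv(deTable, file.path(outDir, "de_table.tsv"))
    } else {
        nodes <- sort(unique(as.character(nodes)))
        message("node set supplied (", length(nodes),
                " genes); differential-expression stage skipped")
    }

    nets <- lapply(tps, function(tp) .stage(
        paste0("pcnet[", tp, "]"),
        buildNetwork(expr, tp, nodeIds = nodes, alpha = alpha)))
    names(nets) <- tps
    for (tp in tps) {
        writeNetwork(nets[[tp]],
                     file.path(outDir, paste0("network_", tp, ".tsv")))
        writeNetworkGraphML(nets[[tp]],
                            file.path(outDir,
                                      paste0("network_", tp, ".graphml")))
    }

    permRes <- NULL
    if (nPermutations > 0L) {
        permSeeds <- .withSeed(seed,
                               sample.int(.Machine$integer.max,
                                          length(tps)))
        permRes <- lapply(seq_along(tps), function(i) .stage(
            paste0("permutation[", tps[i], "]"),
            permutationNull(expr, tps[i], nodeIds = nodes, alpha = alpha,
                            nPermutations = nPermutations,
                            seed = permSeeds[i])))
        names(permRes) <- tps
        .writeJson(permRes, file.path(outDir, "permutation_null.json"))
    }

    topo <- .stage("graph_metrics", topologyTable(nets))
    .writeTsv(topo, file.path(outDir, "topology.tsv"))
    ks <- .stage("graph_metrics", list(
        ksCompareDegrees(nets[[1L]], nets[[2L]]),
        ksCompareDegrees(nets[[2L]], nets[[3L]])))
    names(ks) <- paste(tps[-3L], tps[-1L], sep = "_vs_")
    .writeJson(ks, file.path(outDir, "ks_degrees.json"))

    roles <- lapply(nets, function(nt) .stage(
        paste0("centrality_roles[", timepointLabel(nt), "]"),
        classifyNodes(nt, multiplier, quartileType)))
    for (tp in tps)
        .writeTsv(roles[[tp]]$records,
                  file.path(outDir, paste0("roles_", tp, ".tsv")))
    .writeJson(lapply(roles, `[[`, "fences"),
               file.path(outDir, "fences.json"))

    rew <- .stage("rewiring_dynamics",
                  rewiringSummary(nets, roles = roles))
    .writeTsv(rew$transitions$triples,
              file.path(outDir, "category_triples.tsv"))
    .writeTsv(rew$degree_patterns$per_gene,
              file.path(outDir, "degree_patterns.tsv"))
    .writeJson(list(
        conserved = rew$conserved,
        flows = lapply(rew$transitions$flows,
                       function(m) as.data.frame.matrix(m)),
        stability = rew$stability,
        degree_pattern_counts =
            as.data.frame.matrix(rew$degree_patterns$counts)),
        file.path(outDir, "rewiring.json"))

    report <- list(
        package = "netrewire",
        version = as.character(utils::packageVersion("netrewire")),
        config = list(
            contrast = contrast, fdr_threshold = fdrThreshold,
            alpha = alpha, n_permutations = nPermutations, seed = seed,
            fence_multiplier = multiplier,
            quartile_type = as.integer(quartileType),
            node_set_supplied = is.null(deTable),
            timepoints = tps),
        n_genes_total = nrow(expr),
        n_samples = as.vector(table(timepoints(expr))[tps]),
        node_set_size = length(nodes),
        de_selected = if (is.null(deTable)) NA_integer_
                      else sum(deTable$selected),
        edge_counts = vapply(nets, edgeCount, integer(1L)),
        zero_order_counts = vapply(nets, function(nt) nt@zeroOrderCount,
                                   integer(1L)),
        permutation = if (is.null(permRes)) NULL else lapply(
            permRes, function(z) z[c("observed_edge_count", "null_max",
                                     "exceeds_null")]),
        topology = topo,
        ks = ks,
        conserved = rew$conserved,
        category_counts = lapply(roles, function(z)
            as.list(table(z$records$category))))
    .writeJson(report, file.path(outDir, "run_report.json"))

    invisible(list(de_table = deTable, node_set = nodes, networks = nets,
                   permutation = permRes, topology = topo, ks = ks,
                   roles = roles, rewiring = rew, report = report))
}
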
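# per-gene two-group linear modeling with BH FDR control

#' Per-gene differential expression between two time points
#'
#' Fits, for every gene, the two-group linear model of expression on time
#' point (equivalent to an unpaired two-sample t-test with pooled
#' variance) for the requested contrast, and controls the false discovery
#' rate with the Benjamini-Hochberg step-up procedure. The selected genes
#' define the node set shared by all coexpression networks of a run.
#'
#' A gene with zero pooled variance and zero group difference carries no
#' signal; its p-value is set to 1 by convention and a message is logged.
#' A zero-variance gene with a non-zero difference yields an infinite t
#' statistic and p = 0.
#'
#' @param expr a [TimecourseExperiment-class].
#' @param contrast character vector of two time point labels
#'   `c(reference, treatment)`; the effect is the treatment-minus-reference
#'   mean difference. Default `c("pre", "post")`.
#' @param fdrThreshold FDR level for the selection flag (default 0.05).
#' @return A data.frame with one row per gene and columns `gene_id`,
#'   `effect`, `t_stat`, `p_value`, `q_value`, `direction` (`up` iff
#'   `effect > 0`) and `selected` (`q_value <= fdrThreshold`).
#' @examples
#' truth <- makeSyntheticTruth(30, 30, nHubs = 0, nShifted = 5, seed = 1)
#' tc <- sampleExpression(truth, c(pre = 30, mid = 30, post = 30),
#'                        partialStrength = 0.4, seed = 2)
#' de <- fitGeneModels(tc)
#' table(de$selected)
#' @export
fitGeneModels <- function(expr, contrast = c("pre", "post"),
                          fdrThreshold = 0.05) {
    stopifnot(is(expr, "TimecourseExperiment"))
    if (length(contrast) != 2L)
        stop("'contrast' must name exactly two timepoints")
    tp <- timepoints(expr)
    missing <- setdiff(contrast, levels(tp))
    if (length(missing))
        stop("contrast timepoint(s) absent from metadata: ",
             paste(missing, collapse = ", "))
    x1 <- exprMatrix(expr, contrast[1L])
    x2 <- exprMatrix(expr, contrast[2L])
    n1 <- ncol(x1); n2 <- ncol(x2)
    if (n1 < 2L || n2 < 2L)
        stop("both contrast timepoints need at least 2 samples")
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
    df <- n1 + n2 - 2L
    pooled <- (ss1 + ss2) / df
    effect <- m2 - m1
    se <- sqrt(pooled * (1 / n1 + 1 / n2))
    tstat <- effect / se
    p <- 2 * stats::pt(-abs(tstat), df = df)
    degenerate <- se == 0 & effect == 0
    if (any(degenerate)) {
        tstat[degenerate] <- 0
        p[degenerate] <- 1
        message(sum(degenerate), " gene(s) with zero pooled variance and ",
                "zero effect; p set to 1")
    }
    q <- stats::p.adjust(p, method = "BH")
    data.frame(
        gene_id = rownames(expr),
        effect = effect,
        t_stat = tstat,
        p_value = p,
        q_value = q,
        direction = ifelse(effect > 0, "up", "down"),
        selected = q <= fdrThreshold,
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the network node set from a differential-expression table
#'
#' Returns the selected genes in a stable, documented order
#' (lexicographic by gene id). This list is the node set shared by every
#' coexpression network of a run.
#'
#' @param table a data.frame as returned by [fitGeneModels()].
#' @return Character vector of selected gene ids, sorted.
#' @export
selectNodeSet <- function(table) {
    stopifnot(is.data.frame(table),
              all(c("gene_id", "selected") %in% colnames(table)))
    sel <- table$gene_id[table$selected]
    if (length(sel) == 0L)
        stop("no genes pass the FDR threshold; relax the threshold or ",
             "supply an explicit gene list as the node set")
    sort(sel)
}
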
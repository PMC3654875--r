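# temporal rewiring: conserved links, category transitions, degree
# change patterns

.CATEGORIES <- c("HB", "HNB", "NHB", "NHNB")

#' Conserved links between two networks
#'
#' Counts the edges shared by two networks over the identical node set
#' and reports the shared count as a fraction of the earlier network's
#' edges, of the later network's edges, and of their union. The headline
#' conservation statistic is `fraction_of_earlier` (links of the earlier
#' network still present at the next time point); all three denominators
#' are reported because the choice is a convention.
#'
#' @param netA,netB two [CoexpressionNetwork-class] (or
#'   [PlantedGraph-class]) objects with identical node sets; `netA` is
#'   the earlier time point.
#' @return List with `conserved_links`, `fraction_of_earlier`,
#'   `fraction_of_later`, `fraction_of_union`. Fractions are `NA` when
#'   their denominator is empty.
#' @export
conservedLinks <- function(netA, netB) {
    if (!identical(sort(nodeIds(netA)), sort(nodeIds(netB))))
        stop("the two networks must share an identical node set")
    ea <- .edgeKeys(netA)
    eb <- .edgeKeys(netB)
    shared <- length(intersect(ea, eb))
    frac <- function(d) if (d == 0L) NA_real_ else shared / d
    list(conserved_links = shared,
         fraction_of_earlier = frac(length(ea)),
         fraction_of_later = frac(length(eb)),
         fraction_of_union = frac(length(union(ea, eb))))
}

#' Category transitions of genes across three time points
#'
#' Tabulates each gene's ordered role-category triple and the 4 x 4
#' category flows for both consecutive transitions.
#'
#' @param records named list of three per-timepoint role data.frames
#'   (the `records` element of [classifyNodes()]), in time order; every
#'   gene must be present at all three time points.
#' @return List with `triples` (data.frame: `gene_id` plus one category
#'   column per time point) and `flows` (list of two 4 x 4 contingency
#'   matrices, rows = from-category, columns = to-category; each sums to
#'   the node count).
#' @export
categoryTransitions <- function(records) {
    stopifnot(is.list(records), length(records) == 3L)
    tps <- names(records)
    if (is.null(tps)) stop("'records' must be named by timepoint")
    genes <- sort(records[[1L]]$gene_id)
    for (tab in records)
        if (!identical(sort(tab$gene_id), genes))
            stop("every gene must be present at all three time points")
    cats <- lapply(records, function(tab) {
        v <- factor(as.character(tab$category), levels = .CATEGORIES)
        stats::setNames(v, tab$gene_id)[genes]
    })
    triples <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
    for (i in seq_along(tps))
        triples[[tps[i]]] <- as.character(cats[[i]])
    flows <- list(
        table(from = cats[[1L]], to = cats[[2L]]),
        table(from = cats[[2L]], to = cats[[3L]]))
    names(flows) <- paste(tps[-3L], tps[-1L], sep = "_to_")
    list(triples = triples, flows = flows)
}

#' Stable and transiently prominent genes
#'
#' Derives, from a transition table, the genes that hold network-
#' prominent positions stably or transiently: `stable_genes` keep one
#' identical non-NHNB category at all three time points;
#' `always_bottleneck` are in `{HB, NHB}` at all three;
#' `always_hub` are in `{HB, HNB}` at all three;
#' `prominent_in_exactly_one` lists, per time point, the genes that are
#' non-NHNB at that time point only. Pairwise Venn counts per category
#' between consecutive time points quantify category membership overlap.
#'
#' @param transitions result of [categoryTransitions()].
#' @return List with the four gene lists and `venn` (per consecutive
#'   pair and category: `only_first`, `both`, `only_second`).
#' @export
stabilityReport <- function(transitions) {
    tr <- transitions$triples
    tps <- colnames(tr)[-1L]
    stopifnot(length(tps) == 3L)
    m <- as.matrix(tr[, tps])
    rownames(m) <- tr$gene_id
    prominent <- m != "NHNB"
    nProm <- rowSums(prominent)
    stable <- rownames(m)[nProm == 3L & m[, 1L] == m[, 2L] &
                          m[, 2L] == m[, 3L]]
    alwaysBot <- rownames(m)[rowSums(m == "HB" | m == "NHB") == 3L]
    alwaysHub <- rownames(m)[rowSums(m == "HB" | m == "HNB") == 3L]
    exactlyOne <- lapply(seq_along(tps), function(i)
        rownames(m)[nProm == 1L & prominent[, i]])
    names(exactlyOne) <- tps
    venn <- list()
    for (i in 1:2) {
        pairName <- paste(tps[i], tps[i + 1L], sep = "_vs_")
        venn[[pairName]] <- lapply(.CATEGORIES, function(cc) {
            a <- m[, i] == cc
            b <- m[, i + 1L] == cc
            list(only_first = sum(a & !b), both = sum(a & b),
                 only_second = sum(!a & b))
        })
        names(venn[[pairName]]) <- .CATEGORIES
    }
    list(stable_genes = sort(stable),
         always_bottleneck = sort(alwaysBot),
         always_hub = sort(alwaysHub),
         prominent_in_exactly_one = lapply(exactlyOne, sort),
         venn = venn)
}

#' Degree-change patterns across three ordered networks
#'
#' Labels each gene's degree change over each of the two consecutive
#' transitions as `increase`, `decrease` or `no_change` (degrees are
#' integers, so "no change" means exact equality), and counts genes in
#' each of the 3 x 3 = 9 ordered patterns.
#'
#' @param nets list of three networks in time order with identical node
#'   sets.
#' @return List with `per_gene` (data.frame: `gene_id`, one label per
#'   transition, `pattern`) and `counts` (3 x 3 table, rows = first
#'   transition, columns = second; sums to the node count).
#' @export
degreeChangePatterns <- function(nets) {
    stopifnot(length(nets) == 3L)
    ids <- sort(nodeIds(nets[[1L]]))
    for (nt in nets)
        if (!identical(sort(nodeIds(nt)), ids))
            stop("all three networks must share an identical node set")
    degs <- vapply(nets, function(nt) degreeSequence(nt)[ids],
                   integer(length(ids)))
    lab <- function(d) factor(ifelse(d > 0L, "increase",
                              ifelse(d < 0L, "decrease", "no_change")),
                              levels = c("increase", "decrease",
                                         "no_change"))
    t1 <- lab(degs[, 2L] - degs[, 1L])
    t2 <- lab(degs[, 3L] - degs[, 2L])
    tpNames <- vapply(nets, timepointLabel, character(1L))
    perGene <- data.frame(
        gene_id = ids,
        first_transition = as.character(t1),
        second_transition = as.character(t2),
        pattern = paste(t1, t2, sep = "/"),
        row.names = NULL, stringsAsFactors = FALSE)
    counts <- table(first = t1, second = t2)
    names(dimnames(counts)) <- paste(tpNames[-3L], tpNames[-1L],
                                     sep = "_to_")
    list(per_gene = perGene, counts = counts)
}

#' Full rewiring summary for an ordered three-network series
#'
#' Orchestrates the rewiring analyses: conserved links for both
#' consecutive transitions, role-category transitions and stability,
#' and the nine degree-change patterns.
#'
#' @param nets list of three [CoexpressionNetwork-class] objects in time
#'   order with identical node sets.
#' @param roles optional list of three [classifyNodes()] results matching
#'   `nets`; computed if missing.
#' @param multiplier,quartileType passed to [classifyNodes()] when
#'   `roles` is computed here.
#' @return List with `conserved` (per transition), `transitions`,
#'   `stability` and `degree_patterns`.
#' @export
rewiringSummary <- function(nets, roles = NULL, multiplier = 1.5,
                            quartileType = 7L) {
    stopifnot(length(nets) == 3L)
    if (is.null(roles))
        roles <- lapply(nets, classifyNodes, multiplier = multiplier,
                        quartileType = quartileType)
    tps <- vapply(nets, timepointLabel, character(1L))
    conserved <- list(
        conservedLinks(nets[[1L]], nets[[2L]]),
        conservedLinks(nets[[2L]], nets[[3L]]))
    names(conserved) <- paste(tps[-3L], tps[-1L], sep = "_to_")
    recs <- lapply(roles, `[[`, "records")
    names(recs) <- tps
    transitions <- categoryTransitions(recs)
    list(conserved = conserved,
         transitions = transitions,
         stability = stabilityReport(transitions),
         degree_patterns = degreeChangePatterns(nets))
}
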
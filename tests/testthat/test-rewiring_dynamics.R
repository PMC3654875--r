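.cats <- c("HB", "HNB", "NHB", "NHNB")

.roleRecords <- function(genes, categories, timepoint) {
    data.frame(gene_id = genes, timepoint = timepoint,
               degree = 0L, betweenness = 0,
               category = factor(categories, levels = .cats),
               stringsAsFactors = FALSE)
}

test_that("conserved-link counting covers the degenerate cases", {
    ids <- sprintf("g%03d", 1:6)
    a <- mkNet(ids, rbind(c("g001", "g002"), c("g003", "g004"),
                          c("g005", "g006")))
    same <- conservedLinks(a, a)
    expect_equal(same$conserved_links, 3L)
    expect_equal(same$fraction_of_earlier, 1)
    expect_equal(same$fraction_of_later, 1)
    expect_equal(same$fraction_of_union, 1)
    b <- mkNet(ids, rbind(c("g001", "g003"), c("g002", "g005")))
    disjoint <- conservedLinks(a, b)
    expect_equal(disjoint$conserved_links, 0L)
    expect_equal(disjoint$fraction_of_earlier, 0)
    c1 <- mkNet(ids, rbind(c("g001", "g002"), c("g002", "g003")))
    mixed <- conservedLinks(a, c1)
    expect_equal(mixed$conserved_links, 1L)
    expect_equal(mixed$fraction_of_earlier, 1 / 3)
    expect_equal(mixed$fraction_of_later, 1 / 2)
    expect_equal(mixed$fraction_of_union, 1 / 4)
    expect_lte(mixed$fraction_of_union,
               min(mixed$fraction_of_earlier, mixed$fraction_of_later))
    other <- mkNet(sprintf("h%03d", 1:6), NULL)
    expect_error(conservedLinks(a, other), "identical node set")
})

test_that("category transitions tabulate flows that sum to the node set", {
    genes <- sprintf("g%03d", 1:8)
    recs <- list(
        pre = .roleRecords(genes, c("HB", rep("NHNB", 7)), "pre"),
        mid = .roleRecords(genes, c("NHNB", "NHB", rep("NHNB", 6)), "mid"),
        post = .roleRecords(genes, c("HB", rep("NHNB", 7)), "post"))
    tr <- categoryTransitions(recs)
    expect_equal(nrow(tr$triples), 8L)
    expect_identical(tr$triples$pre[tr$triples$gene_id == "g001"], "HB")
    expect_equal(tr$flows[[1L]]["HB", "NHNB"], 1L, ignore_attr = TRUE)
    expect_equal(tr$flows[[2L]]["NHNB", "HB"], 1L, ignore_attr = TRUE)
    expect_equal(sum(tr$flows[[1L]]), 8L)
    expect_equal(sum(tr$flows[[2L]]), 8L)
    # all-NHNB corner: one flow cell holds everything
    recs0 <- lapply(stats::setNames(c("pre", "mid", "post"),
                                    c("pre", "mid", "post")),
                    function(tp) .roleRecords(genes, rep("NHNB", 8), tp))
    tr0 <- categoryTransitions(recs0)
    expect_equal(tr0$flows[[1L]]["NHNB", "NHNB"], 8L,
                 ignore_attr = TRUE)
    # a gene missing at one timepoint is an error
    recsBad <- recs
    recsBad$mid <- recsBad$mid[-1L, ]
    expect_error(categoryTransitions(recsBad), "all three time points")
})

test_that("stability lists follow the category-union definitions", {
    genes <- sprintf("g%03d", 1:6)
    mk <- function(p, m, q) list(
        pre = .roleRecords(genes, p, "pre"),
        mid = .roleRecords(genes, m, "mid"),
        post = .roleRecords(genes, q, "post"))
    # g1 stable HB; g2 HB/NHB/HB (always bottleneck, not stable);
    # g3 HNB/HB/HNB (always hub); g4 prominent only at mid; rest NHNB
    recs <- mk(c("HB", "HB", "HNB", "NHNB", "NHNB", "NHNB"),
               c("HB", "NHB", "HB", "NHB", "NHNB", "NHNB"),
               c("HB", "HB", "HNB", "NHNB", "NHNB", "NHNB"))
    rep1 <- stabilityReport(categoryTransitions(recs))
    expect_identical(rep1$stable_genes, "g001")
    expect_identical(rep1$always_bottleneck, c("g001", "g002"))
    expect_identical(rep1$always_hub, c("g001", "g003"))
    expect_identical(rep1$prominent_in_exactly_one$mid, "g004")
    expect_length(rep1$prominent_in_exactly_one$pre, 0L)
    # stable genes never appear in any exactly-one list
    expect_false(any(rep1$stable_genes %in%
                     unlist(rep1$prominent_in_exactly_one)))
    # venn bookkeeping: only g1 is HB at both pre and mid
    expect_equal(rep1$venn$pre_vs_mid$HB$both, 1L)
    expect_equal(rep1$venn$pre_vs_mid$HB$only_first, 1L)   # g2
    expect_equal(rep1$venn$pre_vs_mid$HB$only_second, 1L)  # g3
    # all-NHNB corner: everything empty
    recs0 <- mk(rep("NHNB", 6), rep("NHNB", 6), rep("NHNB", 6))
    rep0 <- stabilityReport(categoryTransitions(recs0))
    expect_length(rep0$stable_genes, 0L)
    expect_length(rep0$always_bottleneck, 0L)
    expect_length(rep0$always_hub, 0L)
    expect_true(all(lengths(rep0$prominent_in_exactly_one) == 0L))
})

test_that("degree-change patterns partition genes into nine cells", {
    ids <- sprintf("g%03d", 1:6)
    a <- mkNet(ids, rbind(c("g001", "g002"), c("g003", "g004")), "pre")
    b <- mkNet(ids, rbind(c("g001", "g002"), c("g001", "g003"),
                          c("g001", "g004")), "mid")
    c1 <- mkNet(ids, rbind(c("g001", "g002")), "post")
    pat <- degreeChangePatterns(list(a, b, c1))
    expect_equal(dim(pat$counts), c(3L, 3L))
    expect_equal(sum(pat$counts), 6L)
    expect_equal(nrow(pat$per_gene), 6L)
    g1 <- pat$per_gene[pat$per_gene$gene_id == "g001", ]
    expect_identical(g1$pattern, "increase/decrease")
    # identical networks: everything in the no-change/no-change cell
    pat0 <- degreeChangePatterns(list(a, a, a))
    expect_equal(pat0$counts["no_change", "no_change"], 6L,
                 ignore_attr = TRUE)
    expect_equal(sum(pat0$counts), 6L)
})

test_that("planted overlap ordering survives end-to-end inference", {
    fractions <- sapply(c(0.2, 0.8), function(o) {
        sapply(1:2, function(rep) {
            truth <- makeSyntheticTruth(60, 60, nHubs = 0, overlap = o,
                                        nShifted = 0,
                                        seed = 700 + rep)
            tc <- sampleExpression(
                truth, c(pre = 200, mid = 200, post = 200),
                partialStrength = 0.5, seed = 800 + rep)
            nets <- lapply(c("pre", "mid", "post"),
                           function(tp) buildNetwork(tc, tp))
            mean(c(conservedLinks(nets[[1L]],
                                  nets[[2L]])$fraction_of_earlier,
                   conservedLinks(nets[[2L]],
                                  nets[[3L]])$fraction_of_earlier))
        })
    })
    # every replicate orders the planted overlaps correctly
    expect_true(all(fractions[, 2L] > fractions[, 1L]))
    # and the low-overlap side sits near its target
    expect_true(all(abs(fractions[, 1L] - 0.2) < 0.1))
})

test_that("the full rewiring summary is internally consistent", {
    s <- quickStudy(nGenes = 30, nEdges = 35, nHubs = 1, hubDegree = 7,
                    n = 80, seed = 81)
    nets <- lapply(c("pre", "mid", "post"),
                   function(tp) buildNetwork(s$tc, tp))
    rew <- rewiringSummary(nets)
    expect_named(rew$conserved, c("pre_to_mid", "mid_to_post"))
    expect_equal(sum(rew$degree_patterns$counts), 30L)
    expect_equal(sum(rew$transitions$flows[[1L]]), 30L)
    expect_false(any(rew$stability$stable_genes %in%
                     unlist(rew$stability$prominent_in_exactly_one)))
})
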
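toyTft <- function() {
    TFRegulationTable(data.frame(
        tf = c("T1", "T1", "T1", "T2", "T2", "T3"),
        target = c("g1", "g2", "g3", "g2", "g3", "g5")),
        universe = paste0("g", 1:6))
}

test_that("co-occurrence counts edges with both endpoints in the target set", {
    net <- SignedNetwork(data.frame(u = c("g1", "g2"), v = c("g2", "g4"),
                                    sign = 1))
    cnt <- tfCooccurrence(net, toyTft())
    expect_equal(unname(cnt["T1"]), 1L)   # only (g1, g2)
    expect_equal(unname(cnt["T3"]), 0L)
    # a TF targeting all nodes counts every edge
    allT <- TFRegulationTable(data.frame(tf = "T", target = paste0("g", 1:6)))
    expect_equal(unname(tfCooccurrence(net, allT)["T"]),
                 nrow(edgeTable(net)))
    # brute-force edge-by-edge membership oracle on random instances
    set.seed(1)
    for (i in 1:5) {
        genes <- paste0("g", 1:20)
        g <- igraph::sample_gnm(20, 40)
        el <- igraph::as_edgelist(g)
        rnet <- SignedNetwork(data.frame(u = genes[el[, 1]],
                                         v = genes[el[, 2]], sign = 1))
        tfdf <- do.call(rbind, lapply(1:4, function(j)
            data.frame(tf = paste0("T", j),
                       target = sample(genes, sample(5:15, 1)))))
        tft <- TFRegulationTable(tfdf, universe = genes)
        cnt <- tfCooccurrence(rnet, tft)
        e <- edgeTable(rnet)
        for (tf in names(tft@targets)) {
            brute <- sum(vapply(seq_len(nrow(e)), function(r)
                e$u[r] %in% tft@targets[[tf]] &&
                e$v[r] %in% tft@targets[[tf]], logical(1)))
            expect_equal(unname(cnt[tf]), brute)
        }
    }
})

test_that("the degree-matched null preserves TF-counts and is reproducible", {
    set.seed(2)
    genes <- sprintf("g%03d", 1:80)
    tfdf <- do.call(rbind, lapply(1:6, function(j)
        data.frame(tf = paste0("T", j), target = sample(genes, 30))))
    tft <- TFRegulationTable(tfdf, universe = genes)
    g <- igraph::sample_gnm(20, 35)
    el <- igraph::as_edgelist(g)
    net <- SignedNetwork(data.frame(u = genes[el[, 1]], v = genes[el[, 2]],
                                    sign = 1))
    null1 <- degreeMatchedNull(net, tft, nPerm = 150, seed = 3, minPool = 10)
    null2 <- degreeMatchedNull(net, tft, nPerm = 150, seed = 3, minPool = 10)
    expect_identical(null1, null2)
    expect_equal(dim(null1), c(6L, 150L))
    expect_true(all(null1 >= 0 & null1 <= nrow(edgeTable(net))))
})

test_that("activation p-values hit the boundaries and rank by evidence", {
    set.seed(4)
    obs <- setNames(c(0L, 10L), c("Tzero", "Thigh"))
    null <- rbind(Tzero = rpois(200, 3), Thigh = rpois(200, 2))
    null["Thigh", ] <- pmin(null["Thigh", ], 9L)
    res <- tfActivationPvalues(obs, null)
    expect_equal(unname(res$p_emp[res$tf == "Tzero"]), 1)  # all null >= 0
    expect_equal(unname(res$p_emp[res$tf == "Thigh"]), 0)  # above the null
    expect_equal(res$tf[1], "Thigh")
    expect_true(res$activated[res$tf == "Thigh"])
    expect_false(res$activated[res$tf == "Tzero"])
    expect_true(all(res$q >= res$p_emp))
})

test_that("the common TF index averages Jaccard and overlap", {
    # regulators: g2 -> {T1, T2}, g3 -> {T1, T2}, g1 -> {T1}, g5 -> {T3}
    tft <- toyTft()
    expect_equal(commonTfIndex("g2", "g3", tft), 1)
    expect_equal(commonTfIndex("g1", "g5", tft), 0)
    # A = {T1}, B = {T1, T2}: mean(1/2, 1/2)
    expect_equal(commonTfIndex("g1", "g2", tft), 0.5)
    # the worked two-set example: A = {t1, t2}, B = {t2, t3} -> 5/12
    tft2 <- TFRegulationTable(data.frame(
        tf = c("t1", "t2", "t2", "t3"), target = c("A", "A", "B", "B")))
    expect_equal(commonTfIndex("A", "B", tft2), 5 / 12)
    expect_message(idx <- commonTfIndex("g4", "g1", toyTft()), "zero regulating")
    expect_equal(idx, 0)
    expect_error(commonTfIndex("gZ", "g1", toyTft()), "not present")
})

test_that("target-correlation shift compares the two conditions' distributions", {
    gp <- generateExpressionPair(syntheticSpec(seed = 5))
    rA <- suppressMessages(spearmanMatrix(conditionMatrix(gp$expr, "a")))
    rB <- suppressMessages(spearmanMatrix(conditionMatrix(gp$expr, "b")))
    # a TF whose targets are one rewired module: condition-b correlations
    # drop (half the pairs flip to -1)
    tft <- TFRegulationTable(data.frame(tf = "Tmod",
                                        target = sprintf("g%03d", 1:12)),
                             universe = rownames(rA))
    shift <- targetCorrelationShift("Tmod", tft, rA, rB)
    expect_length(shift$values$a, choose(12, 2))
    expect_lt(shift$p.value, 0.01)
    expect_lt(shift$summary$mean[2], shift$summary$mean[1])
    # identical distributions: KS distance 0, p = 1
    same <- targetCorrelationShift("Tmod", tft, rA, rA)
    expect_equal(same$statistic, 0)
    expect_equal(same$p.value, 1)
    one <- TFRegulationTable(data.frame(tf = "T1", target = "g001"),
                             universe = rownames(rA))
    expect_error(targetCorrelationShift("T1", one, rA, rB), "fewer than 2")
})

test_that("planted TF deactivation is detected and nulls are calibrated", {
    gp <- generateExpressionPair(syntheticSpec(seed = 6))
    net <- assembleNetwork(gp$truth$plantedDcels, type = "DCEL")
    tft <- generateTFTable(nTfs = 15, truth = gp$truth, seed = 7)
    res <- tfActivation(net, tft$table, nPerm = 500, seed = 8)
    expect_equal(res$tf[1], tft$deactivatedTF)
    expect_true(res$activated[1])
    expect_lt(res$q[1], 0.05)
})
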
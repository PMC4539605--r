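triangleNet <- function(signs = c(1, 1, -1)) {
    SignedNetwork(data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"),
                             sign = signs))
}

test_that("degree statistics satisfy the handshake identity", {
    tri <- triangleNet()
    ds <- degreeStats(tri)
    expect_equal(ds$avgDegree, 2)
    expect_equal(ds$maxDegree, 2)
    expect_equal(sum(ds$pk$p), 1)

    star <- SignedNetwork(data.frame(u = "hub", v = paste0("l", 1:5), sign = 1))
    dsS <- degreeStats(star)
    expect_equal(dsS$avgDegree, 2 * 5 / 6)
    expect_equal(dsS$maxDegree, 5)

    set.seed(1)
    g <- igraph::sample_gnm(30, 60)
    el <- igraph::as_edgelist(g)
    net <- SignedNetwork(data.frame(u = paste0("n", el[, 1]),
                                    v = paste0("n", el[, 2]), sign = 1))
    expect_equal(degreeStats(net)$avgDegree * length(nodeIds(net)),
                 2 * nrow(edgeTable(net)))
})

test_that("the power-law exponent is recovered from a known discrete law", {
    set.seed(2)
    k <- 1:100000
    draws <- sample(k, 10000, replace = TRUE, prob = k^(-2.5))
    fit <- powerlawGamma(as.integer(draws))
    expect_lt(abs(fit$gamma - 2.5), 0.1)
    # invariant to relabeling (the fit sees only the degree multiset)
    expect_equal(powerlawGamma(as.integer(sample(draws)))$gamma, fit$gamma)
    expect_error(powerlawGamma(rep(3L, 50)), "degenerate")
})

test_that("clustering coefficients match hand enumeration", {
    expect_equal(clusteringStats(triangleNet())$C, 1)
    # square with one diagonal: the degree-2 corners see their two
    # neighbours linked (c = 1); the diagonal endpoints see 2 of the 3
    # possible edges among their neighbours (c = 2/3)
    sq <- SignedNetwork(data.frame(u = c("a", "b", "c", "d", "a"),
                                   v = c("b", "c", "d", "a", "c"), sign = 1))
    cs <- clusteringStats(sq)
    expect_equal(sort(unname(cs$ci)), sort(c(1, 1, 2/3, 2/3)))
    expect_equal(cs$C, 5/6)
    # trees have no triangles
    tree <- SignedNetwork(data.frame(u = c("a", "a", "b"),
                                     v = c("b", "c", "d"), sign = 1))
    expect_equal(clusteringStats(tree)$C, 0)
})

test_that("path statistics enumerate unordered pairs", {
    ps <- pathStats(triangleNet())
    expect_equal(ps$L, 1); expect_equal(ps$D, 1)
    p4 <- SignedNetwork(data.frame(u = c("a", "b", "c"),
                                   v = c("b", "c", "d"), sign = 1))
    ps4 <- pathStats(p4)
    expect_equal(ps4$L, 10 / 6)
    expect_equal(ps4$D, 3)
    disc <- SignedNetwork(data.frame(u = c("a", "c"), v = c("b", "d"), sign = 1))
    expect_error(pathStats(disc), "connected component")
})

test_that("the signed triad census agrees with brute-force enumeration", {
    tc <- triadCensus(triangleNet(c(1, 1, -1)))
    expect_equal(tc$nTriads, 1L)
    expect_equal(unname(tc$counts["2"]), 1L)
    # K4 all positive: C(4,3) triads, all in the 3-positive class
    k4 <- SignedNetwork(data.frame(
        u = c("a", "a", "a", "b", "b", "c"),
        v = c("b", "c", "d", "c", "d", "d"), sign = 1))
    tc4 <- triadCensus(k4)
    expect_equal(tc4$nTriads, 4L)
    expect_equal(unname(tc4$counts["3"]), 4L)

    set.seed(3)
    for (i in 1:5) {
        g <- igraph::sample_gnm(sample(10:50, 1), sample(20:80, 1))
        el <- igraph::as_edgelist(g)
        if (!nrow(el)) next
        net <- SignedNetwork(data.frame(
            u = paste0("n", el[, 1]), v = paste0("n", el[, 2]),
            sign = sample(c(-1L, 1L), nrow(el), replace = TRUE)))
        expect_identical(triadCensus(net)$counts, bruteTriads(net))
    }
})

test_that("degree-preserving rewiring keeps the degree sequence", {
    set.seed(4)
    g <- igraph::sample_gnm(25, 50)
    el <- igraph::as_edgelist(g)
    net <- SignedNetwork(data.frame(u = paste0("n", el[, 1]),
                                    v = paste0("n", el[, 2]), sign = 1))
    d0 <- sort(igraph::degree(asIgraph(net)))
    dp <- degreePreservingNullC(net, nSamples = 50, seed = 5)
    expect_length(dp$null, 50)
    expect_gte(dp$p, 0)
    # observed value is attainable within the null support
    expect_true(dp$p > 0 || dp$observed < min(dp$null))
    # chain invariance: two seeds give statistically similar nulls
    dp2 <- degreePreservingNullC(net, nSamples = 50, seed = 6)
    expect_lt(abs(mean(dp$null) - mean(dp2$null)), 3 * stats::sd(dp$null))
    star <- SignedNetwork(data.frame(u = "h", v = paste0("l", 1:4), sign = 1))
    expect_error(degreePreservingNullC(star), "swappable")
})

test_that("odd-positive triad fraction reflects sign transitivity", {
    k4 <- SignedNetwork(data.frame(
        u = c("a", "a", "a", "b", "b", "c"),
        v = c("b", "c", "d", "c", "d", "d"), sign = 1))
    expect_equal(coexpressionTransitivityCheck(k4), 1)  # 3-positive is odd
    expect_message(
        val <- coexpressionTransitivityCheck(
            SignedNetwork(data.frame(u = "a", v = "b", sign = 1))),
        "no triads")
    expect_true(is.na(val))
    # a thresholded network from a strongly coexpressed system is transitive
    gp <- generateExpressionPair(syntheticSpec(
        nGenes = 20, noiseSd = 0.05, latentAmplitude = 1, seed = 7,
        modules = list(syntheticModule(sprintf("g%03d", 1:12), flip = "a"))))
    rA <- spearmanMatrix(conditionMatrix(gp$expr, "a"))
    idx <- which(upper.tri(rA) & abs(rA) > 0.9, arr.ind = TRUE)
    net <- SignedNetwork(data.frame(u = rownames(rA)[idx[, 1]],
                                    v = rownames(rA)[idx[, 2]],
                                    sign = sign(rA[idx])))
    expect_gte(coexpressionTransitivityCheck(net), 0.95)
    # random signs give about one half
    set.seed(8)
    g <- igraph::sample_gnm(40, 250)
    el <- igraph::as_edgelist(g)
    rnd <- SignedNetwork(data.frame(u = paste0("n", el[, 1]),
                                    v = paste0("n", el[, 2]),
                                    sign = sample(c(-1L, 1L), 250, TRUE)))
    expect_lt(abs(coexpressionTransitivityCheck(rnd) - 0.5), 0.2)
})

test_that("the randomized-data triad null is deterministic and bounded", {
    rp <- generateRotationalPair(nGenes = 40, nMovers = 3, seed = 9)
    tn <- randomDcenTriadNull(rp$expr, observedEdgeCount = 60,
                              observedTriadProportion = 0, nReps = 20,
                              seed = 10)
    expect_length(tn$null, 20)
    expect_true(all(tn$null >= 0))
    tn2 <- randomDcenTriadNull(rp$expr, 60, 0, nReps = 20, seed = 10)
    expect_identical(tn$null, tn2$null)
    expect_error(randomDcenTriadNull(rp$expr, 10000, 0, nReps = 5, seed = 1),
                 "exceeds pair count")
})
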
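test_that("quantile normalization maps columns onto the reference distribution", {
    m <- cbind(c(1, 2, 3), c(4, 5, 6))
    out <- quantileNormalize(m)
    expect_equal(out[, 1], c(2.5, 3.5, 4.5))
    expect_equal(out[, 2], c(2.5, 3.5, 4.5))

    # fixed point on already-identical columns
    same <- cbind(c(1, 5, 9), c(1, 5, 9))
    expect_equal(quantileNormalize(same), same)

    # all columns share one multiset afterwards; idempotent; rank-preserving
    set.seed(1)
    r <- matrix(rnorm(60), 12, 5)
    qn <- quantileNormalize(r)
    for (j in 2:5) expect_equal(sort(qn[, j]), sort(qn[, 1]))
    expect_equal(quantileNormalize(qn), qn)
    for (j in 1:5) expect_equal(order(qn[, j]), order(r[, j]))

    expect_error(quantileNormalize(matrix(1:3, ncol = 1)),
                 "nothing to normalize against")
})

test_that("quantile normalization agrees with limma on complete matrices", {
    skip_if_not_installed("limma")
    set.seed(7)
    m <- matrix(rnorm(200), 25, 8)
    expect_equal(unname(quantileNormalize(m)),
                 unname(limma::normalizeQuantiles(m)))
})

test_that("quantile normalization keeps missing entries missing", {
    set.seed(2)
    m <- matrix(rnorm(40), 10, 4)
    m[c(2, 13, 27)] <- NA
    out <- quantileNormalize(m)
    expect_identical(is.na(out), is.na(m))
    # observed entries stay rank-ordered within column
    for (j in 1:4) {
        obs <- !is.na(m[, j])
        expect_equal(order(out[obs, j]), order(m[obs, j]))
    }
})

test_that("missing-probe filter applies the per-condition threshold", {
    mA <- matrix(rnorm(36), 3, 12); mB <- matrix(rnorm(36), 3, 12)
    mA[1, 1:3] <- NA            # 25% missing in a -> dropped
    mA[2, 1:2] <- NA; mB[2, 1:2] <- NA  # ~16.7% in each -> kept
    rownames(mA) <- rownames(mB) <- c("p1", "p2", "p3")
    tce <- tceOf(mA, mB)
    out <- filterMissingProbes(tce, 0.20)
    expect_setequal(rownames(out), c("p2", "p3"))
})

test_that("KNN imputation fills from nearest neighbours without touching data", {
    m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 7, 5, 1))
    m2 <- m; m2["a", 3] <- NA
    out <- knnImpute(m2, k = 1)
    expect_equal(unname(out["a", 3]), 3)  # exact duplicate row wins at k = 1
    expect_equal(out[-1, ], m2[-1, ])
    expect_warning(knnImpute(m2, k = 5), "fewer than k")

    # no missing entries -> identity
    expect_identical(knnImpute(m, k = 2), m)

    # imputed values bounded by the neighbours' values at that column
    set.seed(3)
    big <- matrix(rnorm(200), 20, 10)
    holes <- cbind(sample(20, 8), sample(10, 8, replace = TRUE))
    bigNA <- big; bigNA[holes] <- NA
    filled <- knnImpute(bigNA, k = 5)
    expect_false(anyNA(filled))
    hidx <- (holes[, 2] - 1) * nrow(big) + holes[, 1]
    expect_identical(filled[-hidx], bigNA[-hidx])
    for (i in seq_len(nrow(holes))) {
        col <- bigNA[, holes[i, 2]]
        expect_gte(filled[holes[i, 1], holes[i, 2]], min(col, na.rm = TRUE))
        expect_lte(filled[holes[i, 1], holes[i, 2]], max(col, na.rm = TRUE))
    }
})

test_that("probe collapse averages probes of a gene and drops unannotated ones", {
    m <- rbind(p1 = c(1, 2, 1, 2), p2 = c(3, 4, 3, 4), p3 = c(5, 5, 5, 5),
               p4 = c(9, 9, 9, 9))
    tce <- tceOf(m[, 1:2], m[, 3:4])
    ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                      gene_id = c("gA", "gA", "gB"))
    out <- collapseProbes(tce, ann)
    expect_setequal(rownames(out), c("gA", "gB"))
    expect_equal(unname(SummarizedExperiment::assay(out)["gA", ]),
                 c(2, 3, 2, 3))
    expect_equal(unname(SummarizedExperiment::assay(out)["gB", ]),
                 c(5, 5, 5, 5))
    expect_error(collapseProbes(tce, ann[0, ]), "empty probe annotation")
})

test_that("variance filter keeps genes in the top fraction of either condition", {
    set.seed(4)
    n <- 100
    sdsA <- rep(1, n); sdsB <- rep(1, n)
    sdsA[1:25] <- 10          # top-25% in condition a
    sdsB[26:50] <- 10         # disjoint top set in condition b
    mA <- t(vapply(sdsA, function(s) rnorm(12, sd = s), numeric(12)))
    mB <- t(vapply(sdsB, function(s) rnorm(12, sd = s), numeric(12)))
    rownames(mA) <- rownames(mB) <- sprintf("g%03d", 1:n)
    out <- varianceFilter(tceOf(mA, mB), topFrac = 0.25)
    expect_setequal(rownames(out), sprintf("g%03d", 1:50))
})

test_that("the preprocessing pipeline runs in fixed order and logs row counts", {
    set.seed(5)
    m <- matrix(rnorm(40 * 20), 40, 20)
    m[1, 1:4] <- NA              # 40% missing in condition a -> dropped
    m[2, 5] <- NA                # imputable
    rownames(m) <- sprintf("p%02d", 1:40)
    tce <- tceOf(m[, 1:10], m[, 11:20])
    ann <- data.frame(probe_id = sprintf("p%02d", 1:30),
                      gene_id = sprintf("G%02d", c(1, 1, 2:29)))
    pp <- preprocessExpression(tce, ann)
    expect_equal(pp$log$step,
                 c("input", "quantile_normalize", "missing_filter",
                   "knn_impute", "collapse_probes", "variance_filter"))
    expect_false(anyNA(SummarizedExperiment::assay(pp$data)))
    expect_true(all(diff(pp$log$n_rows) <= 0))

    # row order never affects the surviving gene set
    perm <- sample(nrow(m))
    tce2 <- tceOf(m[perm, 1:10], m[perm, 11:20])
    pp2 <- preprocessExpression(tce2, ann)
    expect_setequal(rownames(pp$data), rownames(pp2$data))
})
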
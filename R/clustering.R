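#' @include semantics.R
NULL

#' Cluster genes by their functional-similarity profiles
#'
#' Hierarchical agglomerative average-linkage clustering of the rows of a
#' functional similarity matrix, with distance = 1 - Pearson correlation
#' between profile rows. The tree is cut into `k` clusters or at height
#' `h`; the cluster count is a user decision (chosen by inspecting the
#' similarity heatmap/tree), never auto-selected. Genes with a constant
#' profile row (undefined correlation) become singleton clusters and are
#' reported in a message.
#'
#' @param sim symmetric functional similarity matrix (>= 3 genes).
#' @param k desired number of clusters (of the non-degenerate genes).
#' @param h alternatively, the tree cut height.
#' @return a [ClusterAssignment-class].
#' @export
clusterProfiles <- function(sim, k = NULL, h = NULL) {
    stopifnot(nrow(sim) >= 3, isTRUE(all.equal(rownames(sim), colnames(sim))))
    if (is.null(k) == is.null(h))
        stop("supply exactly one of k or h")
    genes <- rownames(sim)
    const <- apply(sim, 1, function(r) stats::sd(r) == 0)
    if (any(const))
        message(sum(const), " gene(s) with constant profile assigned to ",
                "singleton clusters")
    core <- genes[!const]
    labels <- integer(0); tree <- NULL
    if (length(core) >= 2) {
        d <- stats::as.dist(1 - stats::cor(t(sim[core, , drop = FALSE])))
        tree <- stats::hclust(d, method = "average")
        labels <- if (!is.null(k)) stats::cutree(tree, k = min(k, length(core)))
                  else stats::cutree(tree, h = h)
    } else if (length(core) == 1) {
        labels <- c(1L); names(labels) <- core
    }
    if (any(const)) {
        extra <- seq_along(genes[const]) + max(labels, 0L)
        names(extra) <- genes[const]
        labels <- c(labels, extra)
    }
    labels <- labels[intersect(genes, names(labels))]
    # relabel contiguously by first appearance
    relab <- as.integer(match(labels, unique(labels)))
    names(relab) <- names(labels)
    new("ClusterAssignment", labels = relab, k = max(relab), tree = tree)
}

# count DCELs per cluster pair; returns K x K symmetric integer matrix
.linkCounts <- function(lu, lv, K) {
    I <- matrix(0L, K, K)
    if (length(lu)) {
        lo <- pmin(lu, lv); hi <- pmax(lu, lv)
        tb <- table(factor((lo - 1L) * K + hi, levels = seq_len(K * K)))
        I <- matrix(as.integer(tb), K, K, byrow = TRUE)
        I <- I + t(I) - diag(diag(I))
    }
    I
}

#' Within/between-cluster link densities
#'
#' Connectivity density of differential links: for clusters i != j,
#' `D_ij = I_ij / (n_i * n_j)`; within a cluster,
#' `D_ii = I_ii / (n_i * (n_i - 1) / 2)`, where I is the number of links
#' within (i = j) or connecting (i != j) the clusters and n_i the cluster
#' size -- the pair-count normalization that makes D a density in \[0, 1\].
#' Only edges with both endpoints clustered are counted. A singleton
#' cluster's within-density is undefined and reported as 0 with a flag.
#'
#' @param net a [SignedNetwork-class].
#' @param clusters a [ClusterAssignment-class].
#' @return list with `D` (density matrix), `I` (counts, conserving the
#'   total clustered edge count), `sizes`, and `undefinedDiagonal`
#'   (logical flags for singleton clusters).
#' @export
linkDensity <- function(net, clusters) {
    lab <- clusterLabels(clusters)
    K <- clusters@k
    e <- edgeTable(net)
    keep <- e$u %in% names(lab) & e$v %in% names(lab)
    lu <- lab[e$u[keep]]; lv <- lab[e$v[keep]]
    I <- .linkCounts(lu, lv, K)
    sizes <- tabulate(lab, K)
    denom <- outer(sizes, sizes)
    diag(denom) <- sizes * (sizes - 1) / 2
    undef <- sizes < 2
    denom[cbind(which(undef), which(undef))] <- NA
    D <- I / denom
    D[is.na(D)] <- 0
    list(D = D, I = I, sizes = sizes, undefinedDiagonal = undef)
}

# shuffle labels nPerm times; returns K x K x nPerm array of densities
.densityNull <- function(lu0, lv0, labVec, K, sizes, nPerm) {
    denom <- outer(sizes, sizes)
    diag(denom) <- sizes * (sizes - 1) / 2
    denom[denom == 0] <- NA
    nGenes <- length(labVec)
    res <- array(0, c(K, K, nPerm))
    for (b in seq_len(nPerm)) {
        perm <- sample(labVec)
        lu <- perm[lu0]; lv <- perm[lv0]
        res[, , b] <- .linkCounts(lu, lv, K) / denom
    }
    res[is.na(res)] <- 0
    res
}

#' Randomization z-scores of link densities
#'
#' Shuffles the gene-cluster association (preserving cluster sizes) `nPerm`
#' times, recomputes all densities, and standardizes the observed density
#' of each cluster pair against the null mean and SD:
#' `z_ij = (D_ij - mu_ij) / sd_ij`. z > 1.5 flags cluster pairs (or
#' clusters, on the diagonal) linked significantly more densely than
#' expected by chance.
#'
#' @param net a [SignedNetwork-class].
#' @param clusters a [ClusterAssignment-class] with >= 2 clusters.
#' @param nPerm number of label shuffles (default 1000; production 1e5).
#' @param seed integer RNG seed.
#' @param zThreshold significance threshold on z (default 1.5).
#' @return list with `D`, `Z`, `mu`, `sd`, `significant` (z > threshold),
#'   and `undefined` (cells with zero null SD, z undefined).
#' @export
densityZscores <- function(net, clusters, nPerm = 1000, seed = 1L,
                           zThreshold = 1.5) {
    if (clusters@k < 2) stop("need at least 2 clusters")
    obs <- linkDensity(net, clusters)
    lab <- clusterLabels(clusters)
    e <- edgeTable(net)
    keep <- e$u %in% names(lab) & e$v %in% names(lab)
    lu0 <- match(e$u[keep], names(lab)); lv0 <- match(e$v[keep], names(lab))
    set.seed(seed)
    nullD <- .densityNull(lu0, lv0, unname(lab), clusters@k, obs$sizes, nPerm)
    mu <- apply(nullD, c(1, 2), mean)
    sdv <- apply(nullD, c(1, 2), stats::sd)
    undef <- sdv == 0
    Z <- (obs$D - mu) / sdv
    Z[undef] <- NA
    list(D = obs$D, I = obs$I, sizes = obs$sizes, mu = mu, sd = sdv, Z = Z,
         significant = !is.na(Z) & Z > zThreshold, undefined = undef)
}

#' Ratio test for between- vs within-cluster links
#'
#' Tests whether differential links fall between clusters more than
#' expected: the empirical p-value is the fraction of gene-cluster label
#' shuffles whose between/within link ratio is greater than or equal to
#' the observed ratio. With zero observed within-cluster links the ratio
#' is infinite and the test falls back to the between-link count (noted in
#' a message).
#'
#' @inheritParams densityZscores
#' @return list with `nBetween`, `nWithin`, `ratio` and `p`.
#' @export
betweenWithinRatioTest <- function(net, clusters, nPerm = 1000, seed = 1L) {
    lab <- clusterLabels(clusters)
    e <- edgeTable(net)
    keep <- e$u %in% names(lab) & e$v %in% names(lab)
    lu0 <- match(e$u[keep], names(lab)); lv0 <- match(e$v[keep], names(lab))
    labVec <- unname(lab)
    within <- sum(labVec[lu0] == labVec[lv0])
    between <- sum(labVec[lu0] != labVec[lv0])
    useCount <- within == 0
    if (useCount)
        message("no within-cluster links; testing the between-link count instead")
    obsStat <- if (useCount) between else between / within
    set.seed(seed)
    stat <- vapply(seq_len(nPerm), function(b) {
        perm <- sample(labVec)
        w <- sum(perm[lu0] == perm[lv0]); btw <- length(lu0) - w
        if (useCount) btw else btw / w
    }, numeric(1))
    list(nBetween = between, nWithin = within,
         ratio = if (useCount) Inf else obsStat,
         p = mean(stat >= obsStat))
}
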
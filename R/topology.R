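#' @include coexpression.R
NULL

#' Degree statistics of a network
#'
#' Edge signs are ignored: the network is treated as an unsigned simple
#' graph, as for all unsigned topology statistics here.
#'
#' @param net a [SignedNetwork-class].
#' @return list with `avgDegree` (exactly 2E/N), `maxDegree`, and `pk`, a
#'   data.frame of the degree distribution P(k) (summing to 1).
#' @export
degreeStats <- function(net) {
    stopifnot(length(nodeIds(net)) >= 1)
    d <- igraph::degree(asIgraph(net))
    tb <- table(d)
    list(avgDegree = 2 * nrow(edgeTable(net)) / length(nodeIds(net)),
         maxDegree = max(d),
         pk = data.frame(k = as.integer(names(tb)),
                         p = as.numeric(tb) / length(d)))
}

#' Power-law exponent of a degree sequence
#'
#' Discrete maximum-likelihood estimate of the exponent gamma of
#' P(k) ~ k^-gamma, with the lower cutoff xmin chosen by minimizing the
#' Kolmogorov-Smirnov distance (the `plfit` approach, via
#' [igraph::fit_power_law()]).
#'
#' @param degrees integer degree sequence, or a [SignedNetwork-class].
#' @return list with `gamma`, `xmin` and `ks` (the KS statistic at the
#'   chosen cutoff).
#' @export
powerlawGamma <- function(degrees) {
    if (is(degrees, "SignedNetwork"))
        degrees <- as.integer(igraph::degree(asIgraph(degrees)))
    degrees <- degrees[degrees >= 1]
    if (length(degrees) < 10) stop("need at least 10 nodes with degree >= 1")
    if (length(unique(degrees)) == 1) stop("degenerate degree sequence")
    fit <- igraph::fit_power_law(degrees, implementation = "plfit")
    list(gamma = fit$alpha, xmin = fit$xmin, ks = fit$KS.stat)
}

#' Clustering coefficients
#'
#' Local clustering c_i is the ratio of the edges among a node's neighbours
#' to the maximum possible; nodes of degree < 2 get c_i = 0. `C` is the
#' mean over all nodes and `ck` the mean over nodes of each degree.
#'
#' @param net a [SignedNetwork-class].
#' @return list with `C`, `ck` (data.frame k, C_k) and the per-node `ci`.
#' @export
clusteringStats <- function(net) {
    g <- asIgraph(net)
    ci <- igraph::transitivity(g, type = "local", isolates = "zero")
    ci[is.na(ci)] <- 0
    names(ci) <- igraph::V(g)$name
    d <- igraph::degree(g)
    ck <- vapply(split(ci, d), mean, numeric(1))
    list(C = mean(ci),
         ck = data.frame(k = as.integer(names(ck)), C_k = as.numeric(ck)),
         ci = ci)
}

#' Shortest-path statistics of a connected network
#'
#' Unweighted breadth-first distances over all unordered node pairs.
#'
#' @param net a *connected* [SignedNetwork-class]; pass the largest
#'   component (see [largestComponent()]).
#' @return list with `L` (mean distance), `D` (diameter) and `histogram`
#'   (counts of pairs at each distance).
#' @export
pathStats <- function(net) {
    g <- asIgraph(net)
    if (igraph::components(g)$no != 1) stop("pass a connected component")
    dt <- igraph::distance_table(g, directed = FALSE)
    h <- dt$res
    list(L = sum(h * seq_along(h)) / sum(h),
         D = length(h),
         histogram = data.frame(distance = seq_along(h), n_pairs = h))
}

#' One-stop topology summary
#'
#' Computes the standard characterization of a signed network: size, sign
#' balance, average/maximum degree, power-law exponent, average clustering
#' coefficient, and (on the largest component) diameter and average
#' shortest path length.
#'
#' @param net a [SignedNetwork-class].
#' @param fitGamma attempt the power-law fit (needs >= 10 nodes).
#' @return list of named statistics; `n_nodes_lcc`/`n_edges_lcc` refer to
#'   the largest component, on which `D` and `L` are measured.
#' @export
topologySummary <- function(net, fitGamma = TRUE) {
    e <- edgeTable(net)
    ds <- degreeStats(net)
    cs <- clusteringStats(net)
    lcc <- largestComponent(net)
    ps <- if (nrow(edgeTable(lcc))) pathStats(lcc) else list(L = NA, D = NA)
    gam <- if (fitGamma && length(nodeIds(net)) >= 10)
        tryCatch(powerlawGamma(net), error = function(e) list(gamma = NA, xmin = NA))
    else list(gamma = NA, xmin = NA)
    list(n_nodes = length(nodeIds(net)), n_edges = nrow(e),
         n_pos = sum(e$sign == 1L), n_neg = sum(e$sign == -1L),
         avg_degree = ds$avgDegree, max_degree = ds$maxDegree,
         gamma = gam$gamma, xmin = gam$xmin, C = cs$C,
         n_nodes_lcc = length(nodeIds(lcc)),
         n_edges_lcc = nrow(edgeTable(lcc)),
         avg_degree_lcc = degreeStats(lcc)$avgDegree,
         D = ps$D, L = ps$L)
}

#' Degree-preserving null distribution of the clustering coefficient
#'
#' Each null sample is produced by a double-edge-swap Markov chain started
#' from the observed graph (`swapsPerEdge * E` attempted swaps via
#' [igraph::rewire()]), preserving the degree sequence exactly. The
#' empirical p-value is the fraction of samples whose average clustering
#' coefficient is less than or equal to the observed one (testing whether
#' the observed network is *less* clustered than its degree sequence
#' implies, i.e. tree-like).
#'
#' @param net a [SignedNetwork-class] with at least 2 edges and at least
#'   one swappable (vertex-disjoint) edge pair.
#' @param nSamples number of null samples (default 1000; production-scale
#'   analyses use 1e5).
#' @param swapsPerEdge attempted swaps per edge per sample (default 10).
#' @param seed integer RNG seed.
#' @return list with `observed` C, `null` (vector of null C values) and
#'   `p`.
#' @export
degreePreservingNullC <- function(net, nSamples = 1000, swapsPerEdge = 10,
                                  seed = 1L) {
    e <- edgeTable(net)
    if (nrow(e) < 2) stop("need at least 2 edges")
    ok <- FALSE
    for (i in seq_len(nrow(e) - 1)) {
        disjoint <- e$u[-seq_len(i)] != e$u[i] & e$u[-seq_len(i)] != e$v[i] &
            e$v[-seq_len(i)] != e$u[i] & e$v[-seq_len(i)] != e$v[i]
        if (any(disjoint)) { ok <- TRUE; break }
    }
    if (!ok) stop("no swappable edge pair")
    g <- asIgraph(net)
    niter <- swapsPerEdge * nrow(e)
    cObs <- clusteringStats(net)$C
    meanC <- function(gr) {
        ci <- igraph::transitivity(gr, type = "local", isolates = "zero")
        ci[is.na(ci)] <- 0
        mean(ci)
    }
    set.seed(seed)
    nullC <- vapply(seq_len(nSamples), function(i) {
        meanC(igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                       niter = niter)))
    }, numeric(1))
    list(observed = cObs, null = nullC, p = mean(nullC <= cObs))
}

#' Signed triad census
#'
#' Enumerates all triads (three mutually linked nodes, the smallest unit of
#' a complete graph) and classifies each by its number of positive edges.
#' In a sign-transitive coexpression network only triads with an odd number
#' of positive links occur.
#'
#' @param net a [SignedNetwork-class].
#' @return list with `nTriads` and `counts`, a named vector over 0-3
#'   positive edges (summing to `nTriads`).
#' @export
triadCensus <- function(net) {
    g <- asIgraph(net)
    counts <- c("0" = 0L, "1" = 0L, "2" = 0L, "3" = 0L)
    tri <- igraph::triangles(g)
    n <- length(tri) / 3
    if (n > 0) {
        tm <- matrix(as.integer(tri), nrow = 3)
        sg <- igraph::E(g)$sign
        npos <- vapply(seq_len(ncol(tm)), function(j) {
            vs <- tm[, j]
            eid <- igraph::get_edge_ids(g, c(vs[1], vs[2], vs[1], vs[3],
                                             vs[2], vs[3]))
            sum(sg[eid] == 1L)
        }, integer(1))
        tb <- table(factor(npos, levels = 0:3))
        counts[] <- as.integer(tb)
    }
    list(nTriads = as.integer(n), counts = counts)
}

#' Fraction of triads with an odd number of positive edges
#'
#' Transitivity of (anti-)correlation implies that triads in a coexpression
#' network built from thresholded per-condition correlations carry an odd
#' number of positive edges (1 or 3); a random sign assignment gives 0.5.
#'
#' @param net a [SignedNetwork-class].
#' @return fraction in \[0, 1\], or `NA` (with a message) when the network
#'   has no triads.
#' @export
coexpressionTransitivityCheck <- function(net) {
    tc <- triadCensus(net)
    if (tc$nTriads == 0) {
        message("no triads present; odd-positive fraction undefined")
        return(NA_real_)
    }
    unname((tc$counts["1"] + tc$counts["3"]) / tc$nTriads)
}

#' Triad abundance null from randomized expression data
#'
#' Re-runs a rank-matched differential coexpression analysis on expression
#' data whose condition labels have been shuffled: per replicate, sample
#' columns are reassigned to conditions at random, pairwise differential
#' scores are recomputed, and the top `observedEdgeCount` pairs by absolute
#' score form a random differential network whose triad proportion (triads
#' per edge) is recorded. The empirical p-value is the fraction of
#' replicates whose proportion is less than or equal to the observed one.
#' (Rank-matching the edge count stands in for re-running the full
#' permutation test inside the null, keeping network size fixed while
#' remaining tractable.)
#'
#' @param x a [TimecourseExperiment-class] with two conditions.
#' @param observedEdgeCount number of edges of the observed network.
#' @param observedTriadProportion observed triads per edge.
#' @param nReps number of replicates (default 200).
#' @param seed integer RNG seed.
#' @param tieWeight passed to [differentialScore()].
#' @return list with `null` (vector of triad proportions) and `p`.
#' @export
randomDcenTriadNull <- function(x, observedEdgeCount,
                                observedTriadProportion, nReps = 200,
                                seed = 1L, tieWeight = 1) {
    conds <- conditionNames(x)
    stopifnot(length(conds) == 2)
    mA <- conditionMatrix(x, conds[1]); mB <- conditionMatrix(x, conds[2])
    nA <- ncol(mA); X <- cbind(mA, mB)
    nPairs <- choose(nrow(X), 2)
    if (observedEdgeCount > nPairs) stop("observedEdgeCount exceeds pair count")
    genes <- rownames(X)
    ut <- .upperPairs(nrow(X))
    set.seed(seed)
    null <- vapply(seq_len(nReps), function(b) {
        idx <- sample.int(ncol(X))
        sc <- .scorePairs(X[, idx[seq_len(nA)], drop = FALSE],
                          X[, idx[-seq_len(nA)], drop = FALSE],
                          tieWeight)$score[ut]
        sc[is.na(sc)] <- 0
        top <- order(abs(sc), decreasing = TRUE)[seq_len(observedEdgeCount)]
        sgn <- sign(sc[top]); sgn[sgn == 0] <- 1
        gnet <- SignedNetwork(data.frame(u = genes[ut[top, 1]],
                                         v = genes[ut[top, 2]],
                                         sign = sgn))
        triadCensus(gnet)$nTriads / observedEdgeCount
    }, numeric(1))
    list(null = null, p = mean(null <= observedTriadProportion))
}
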
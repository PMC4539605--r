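#' @include methods.R
NULL

#' Pairwise Spearman correlation matrix
#'
#' @param m numeric matrix, genes x samples (one condition, no missing
#'   values, at least 4 samples). Ties are handled by average ranks.
#' @return symmetric correlation matrix with unit diagonal; rows with zero
#'   variance yield `NA` correlations (a message reports how many) and such
#'   pairs are excluded downstream.
#' @export
spearmanMatrix <- function(m) {
    if (ncol(m) < 4) stop("need at least 4 samples per condition")
    if (anyNA(m)) stop("missing values present; impute first")
    r <- suppressWarnings(stats::cor(t(m), method = "spearman"))
    nbad <- sum(apply(m, 1, stats::sd) == 0)
    if (nbad) message(nbad, " zero-variance gene(s): correlations undefined")
    r
}

#' Differential coexpression score
#'
#' `score = delta * (1 + tieWeight * (|r_a| + |r_b|) / 2)` with
#' `delta = r_b - r_a`. The second factor separates pairs with identical
#' correlation differences: for equal delta, the magnitude grows with the
#' mean absolute correlation, so a change from 1.0 to 0.5 outranks a change
#' from 0.5 to 0.0. Positive scores mark pairs whose correlation is higher
#' in condition b; the score is antisymmetric under swapping conditions.
#'
#' @param rA,rB Spearman correlations in conditions a and b (vectorized).
#' @param tieWeight weight of the magnitude term (default 1).
#' @return numeric score(s), same sign as `rB - rA`.
#' @export
differentialScore <- function(rA, rB, tieWeight = 1) {
    (rB - rA) * (1 + tieWeight * (abs(rA) + abs(rB)) / 2)
}

# observed per-condition correlations + scores for all gene pairs;
# internal workhorse shared by permutationPvalues and the triad null
.scorePairs <- function(mA, mB, tieWeight = 1) {
    rA <- suppressWarnings(stats::cor(t(mA), method = "spearman"))
    rB <- suppressWarnings(stats::cor(t(mB), method = "spearman"))
    list(rA = rA, rB = rB, score = differentialScore(rA, rB, tieWeight))
}

#' Permutation test for differential coexpression
#'
#' Computes per-pair empirical p-values for the absolute differential score
#' by randomizing the assignment of sample columns to conditions. One shared
#' pool of `nPerm` permutations is applied to all pairs; the p-value of a
#' pair is the proportion of permutations whose absolute permuted score is
#' greater than or equal to the observed one (a two-sided test: links of
#' both signs are retained).
#'
#' Schemes: `"pooled"` reassigns columns to conditions at random, keeping
#' each condition's sample count; `"paired"` swaps the two condition labels
#' independently at each shared timepoint and requires equal time grids.
#'
#' @param x a [TimecourseExperiment-class] with exactly two conditions.
#' @param nPerm number of permutations (at least 100; the attainable
#'   minimum p is 1/nPerm with the default estimator).
#' @param scheme `"pooled"` or `"paired"`.
#' @param seed integer RNG seed.
#' @param tieWeight passed to [differentialScore()].
#' @param estimator `"proportion"` (count/nPerm, the default) or
#'   `"add-one"` ((count+1)/(nPerm+1), which never returns exactly 0).
#' @return [S4Vectors::DataFrame] with one row per gene pair: `u`, `v`,
#'   `r_a`, `r_b`, `delta`, `score`, `p_emp`. Pairs with an undefined
#'   correlation are dropped (count in a message). `metadata()` records
#'   `n_perm`, `scheme` and the dropped-pair count.
#' @export
permutationPvalues <- function(x, nPerm = 1000, scheme = c("pooled", "paired"),
                               seed = 1L, tieWeight = 1,
                               estimator = c("proportion", "add-one")) {
    scheme <- match.arg(scheme)
    estimator <- match.arg(estimator)
    stopifnot(nPerm >= 100)
    conds <- conditionNames(x)
    if (length(conds) != 2) stop("exactly two conditions required")
    mA <- conditionMatrix(x, conds[1]); mB <- conditionMatrix(x, conds[2])
    if (ncol(mA) < 4 || ncol(mB) < 4) stop("need at least 4 samples per condition")
    if (scheme == "paired" && ncol(mA) != ncol(mB))
        stop("paired scheme requires matching timepoints")
    nA <- ncol(mA); nB <- ncol(mB)
    X <- cbind(mA, mB)
    obs <- .scorePairs(mA, mB, tieWeight)
    absObs <- abs(obs$score)
    counts <- matrix(0, nrow(X), nrow(X))
    set.seed(seed)
    for (b in seq_len(nPerm)) {
        if (scheme == "pooled") {
            idx <- sample.int(nA + nB)
            ia <- idx[seq_len(nA)]; ib <- idx[-seq_len(nA)]
        } else {
            sw <- stats::runif(nA) < 0.5
            ia <- ifelse(sw, nA + seq_len(nA), seq_len(nA))
            ib <- ifelse(sw, seq_len(nA), nA + seq_len(nA))
        }
        p <- .scorePairs(X[, ia, drop = FALSE], X[, ib, drop = FALSE], tieWeight)
        sp <- abs(p$score); sp[is.na(sp)] <- 0
        counts <- counts + (sp >= absObs)
    }
    ut <- .upperPairs(nrow(X))
    rA <- obs$rA[ut]; rB <- obs$rB[ut]
    ok <- !is.na(rA) & !is.na(rB)
    nDropped <- sum(!ok)
    if (nDropped) message(nDropped, " pair(s) with undefined correlation dropped")
    pv <- if (estimator == "proportion") counts[ut] / nPerm
          else (counts[ut] + 1) / (nPerm + 1)
    genes <- rownames(X)
    out <- S4Vectors::DataFrame(
        u = genes[ut[, 1]], v = genes[ut[, 2]],
        r_a = rA, r_b = rB, delta = rB - rA,
        score = obs$score[ut], p_emp = pv)[ok, ]
    S4Vectors::metadata(out) <- list(n_perm = nPerm, scheme = scheme,
                                     estimator = estimator,
                                     n_dropped = nDropped,
                                     conditions = conds)
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone in rank, clipped at 1), via
#' [stats::p.adjust()].
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, elementwise at least the raw ones.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Call differentially coexpressed links (DCELs)
#'
#' Keeps gene pairs whose (BH-adjusted by default) permutation p-value is
#' strictly below `alpha` and assigns the sign class from the score sign.
#'
#' @param links output of [permutationPvalues()].
#' @param alpha significance threshold (default 1e-4).
#' @param adjust threshold the BH-adjusted p (`TRUE`, default) or the raw
#'   empirical p.
#' @return [S4Vectors::DataFrame] of DCELs with added `q` and `sign_class`
#'   (`"positive"` iff score > 0) columns. Warns when `alpha` is below the
#'   1/nPerm resolution of the permutation p-values.
#' @export
callDcels <- function(links, alpha = 1e-4, adjust = TRUE) {
    nPerm <- S4Vectors::metadata(links)$n_perm
    if (!is.null(nPerm) && alpha < 1 / nPerm)
        warning("alpha below 1/nPerm resolution; calls depend on zero-count p-values")
    links$q <- bhAdjust(links$p_emp)
    keep <- if (adjust) links$q < alpha else links$p_emp < alpha
    out <- links[keep & !is.na(keep), ]
    out$sign_class <- ifelse(out$score > 0, "positive", "negative")
    out
}

#' Call constitutively coexpressed links (CCELs)
#'
#' A pair is constitutively coexpressed when its Spearman correlation is
#' strictly above `rMin` in *both* conditions.
#'
#' @param links a table with `r_a` and `r_b` columns (e.g. from
#'   [permutationPvalues()]) or a [TimecourseExperiment-class], in which
#'   case correlations are computed directly.
#' @param rMin correlation threshold (default 0.95, strict).
#' @return table of CCEL pairs.
#' @export
callCcels <- function(links, rMin = 0.95) {
    if (is(links, "TimecourseExperiment")) {
        conds <- conditionNames(links)
        stopifnot(length(conds) == 2)
        obs <- .scorePairs(conditionMatrix(links, conds[1]),
                           conditionMatrix(links, conds[2]))
        ut <- .upperPairs(nrow(links))
        genes <- rownames(links)
        links <- S4Vectors::DataFrame(u = genes[ut[, 1]], v = genes[ut[, 2]],
                                      r_a = obs$rA[ut], r_b = obs$rB[ut])
    }
    keep <- !is.na(links$r_a) & !is.na(links$r_b) &
        links$r_a > rMin & links$r_b > rMin
    links[keep, ]
}

#' Assemble a signed network from called links
#'
#' @param edges DCEL or CCEL table with `u`, `v` and a `score` (sign taken
#'   from it) or `sign` column; CCELs (no score) get positive sign.
#' @param type edge type to record (`"DCEL"`, `"CCEL"` or `"generic"`).
#' @param nodes optional isolates to declare.
#' @return a [SignedNetwork-class].
#' @export
assembleNetwork <- function(edges, type = c("DCEL", "CCEL", "generic"),
                            nodes = NULL) {
    type <- match.arg(type)
    edges <- as.data.frame(edges)
    if (is.null(edges[["sign"]]) && is.null(edges[["score"]]) &&
        is.null(edges[["weight"]]))
        edges$sign <- rep(1L, nrow(edges))
    SignedNetwork(edges, nodes = nodes, type = type)
}

#' Connected components, largest first
#'
#' @param net a [SignedNetwork-class].
#' @return list of character vectors of node ids, ordered by decreasing
#'   size; ties broken by the lexicographically smallest member.
#' @export
connectedComponentsOf <- function(net) {
    g <- asIgraph(net)
    cmp <- igraph::components(g)
    groups <- split(igraph::V(g)$name, cmp$membership)
    groups <- lapply(groups, sort)
    ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
    unname(groups[ord])
}

#' Induced subnetwork on a node subset
#'
#' @param net a [SignedNetwork-class].
#' @param nodes node ids to keep.
#' @return a [SignedNetwork-class] with the edges among `nodes`.
#' @export
inducedSubnetwork <- function(net, nodes) {
    e <- edgeTable(net)
    keep <- e$u %in% nodes & e$v %in% nodes
    SignedNetwork(e[keep, ], nodes = intersect(net@nodes, nodes))
}

#' Largest connected component as a subnetwork
#'
#' Topology statistics that require connectivity (diameter, average
#' shortest path) are conventionally reported on the largest component.
#'
#' @param net a [SignedNetwork-class].
#' @return a [SignedNetwork-class].
#' @export
largestComponent <- function(net) {
    inducedSubnetwork(net, connectedComponentsOf(net)[[1]])
}
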
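#' @include clustering.R
NULL

# logical membership matrix: universe genes x TFs
.tfMembership <- function(tft, genes) {
    tfs <- names(tft@targets)
    M <- matrix(FALSE, length(genes), length(tfs),
                dimnames = list(genes, tfs))
    for (tf in tfs) {
        hit <- genes %in% tft@targets[[tf]]
        M[hit, tf] <- TRUE
    }
    M
}

#' TF co-occurrence counts on a differential network
#'
#' For each transcription factor, counts the links whose *both* endpoints
#' are targets of that TF.
#'
#' @param net a [SignedNetwork-class] with at least one edge.
#' @param tft a [TFRegulationTable-class].
#' @return named integer vector, one count per TF (each at most the number
#'   of edges).
#' @export
tfCooccurrence <- function(net, tft) {
    e <- edgeTable(net)
    if (!nrow(e)) stop("network has no edges")
    genes <- nodeIds(net)
    M <- .tfMembership(tft, genes)
    iu <- match(e$u, genes); iv <- match(e$v, genes)
    cnt <- colSums(M[iu, , drop = FALSE] & M[iv, , drop = FALSE])
    stats::setNames(as.integer(cnt), colnames(M))
}

# replacement pools per distinct TF-count, widened symmetrically (+-1,
# +-2, ...) until they hold >= minPool genes
.matchingPools <- function(tft, nodeCounts, minPool) {
    uniCounts <- tfCountOf(tft, tft@universe)
    pools <- list()
    for (cc in unique(nodeCounts)) {
        w <- 0L
        repeat {
            pool <- tft@universe[abs(uniCounts - cc) <= w]
            if (length(pool) >= minPool || length(pool) == length(tft@universe))
                break
            w <- w + 1L
        }
        pools[[as.character(cc)]] <- pool
    }
    pools
}

#' Degree-matched null distribution of TF co-occurrence
#'
#' Estimates the background co-occurrence of each TF by randomizing the
#' network's gene identities while keeping the edge topology fixed: in
#' each permutation every node is replaced by a gene regulated by the same
#' (or, when that bin is sparse, a similar) number of TFs, drawn from the
#' gene universe without repetition within the permutation. A node may
#' draw itself, so the observed configuration lies in the null's support.
#' The matching pool for a TF-count is widened symmetrically (+-1, +-2,
#' ...) until it holds at least `minPool` genes.
#'
#' @param net a [SignedNetwork-class].
#' @param tft a [TFRegulationTable-class].
#' @param nPerm number of permutations (default 1000; production 1e5).
#' @param seed integer RNG seed.
#' @param minPool minimum matching-pool size (default 50).
#' @return matrix of null co-occurrence counts, TFs x permutations.
#' @export
degreeMatchedNull <- function(net, tft, nPerm = 1000, seed = 1L,
                              minPool = 50) {
    e <- edgeTable(net)
    if (!nrow(e)) stop("network has no edges")
    genes <- nodeIds(net)
    nodeCounts <- tfCountOf(tft, genes)
    pools <- .matchingPools(tft, nodeCounts, minPool)
    poolIdx <- lapply(pools, function(p) match(p, tft@universe))
    M <- .tfMembership(tft, tft@universe)
    iu <- match(e$u, genes); iv <- match(e$v, genes)
    nG <- length(genes); nU <- length(tft@universe)
    key <- as.character(nodeCounts)
    classes <- split(seq_len(nG), key)      # nodes sharing one matching pool
    set.seed(seed)
    out <- matrix(0L, ncol(M), nPerm,
                  dimnames = list(colnames(M), NULL))
    for (b in seq_len(nPerm)) {
        used <- logical(nU)
        repl <- integer(nG)
        for (cl in sample(names(classes))) {    # random class order
            idx <- classes[[cl]]
            cand <- poolIdx[[cl]]
            cand <- cand[!used[cand]]
            if (length(cand) < length(idx))     # pool exhausted: widen
                cand <- unique(c(cand, which(!used)))
            pick <- cand[sample.int(length(cand), length(idx))]
            repl[idx] <- pick
            used[pick] <- TRUE
        }
        out[, b] <- colSums(M[repl[iu], , drop = FALSE] &
                            M[repl[iv], , drop = FALSE])
    }
    out
}

#' Empirical p-values and activation calls for TFs
#'
#' `p_emp` is the fraction of permutations whose null co-occurrence is
#' greater than or equal to the observed count; `q` is the BH adjustment
#' across all TFs. A TF is called differentially activated when its
#' empirical p (or, with `useAdjusted = TRUE`, its q) is below `alpha`
#' (default 0.05).
#'
#' @param observed named counts from [tfCooccurrence()].
#' @param nullCounts TFs x permutations matrix from [degreeMatchedNull()]
#'   (at least 100 permutations).
#' @param alpha call threshold (default 0.05).
#' @param useAdjusted threshold q instead of p.
#' @return [S4Vectors::DataFrame] sorted by p then decreasing count: `tf`,
#'   `co_occurrence`, `null_mean`, `null_sd`, `p_emp`, `q`, `activated`.
#' @export
tfActivationPvalues <- function(observed, nullCounts, alpha = 0.05,
                                useAdjusted = FALSE) {
    stopifnot(ncol(nullCounts) >= 100,
              identical(names(observed), rownames(nullCounts)))
    p <- rowMeans(nullCounts >= observed)
    q <- bhAdjust(p)
    out <- S4Vectors::DataFrame(
        tf = names(observed),
        co_occurrence = as.integer(observed),
        null_mean = rowMeans(nullCounts),
        null_sd = apply(nullCounts, 1, stats::sd),
        p_emp = p, q = q,
        activated = (if (useAdjusted) q else p) < alpha)
    out[order(out$p_emp, -out$co_occurrence), ]
}

#' Identify differentially activated TFs on a network
#'
#' Convenience wrapper: observed co-occurrence, degree-matched null,
#' p-values and calls in one step.
#'
#' @inheritParams degreeMatchedNull
#' @inheritParams tfActivationPvalues
#' @return see [tfActivationPvalues()]; an `in_network` column marks TFs
#'   that are themselves components of the network.
#' @export
tfActivation <- function(net, tft, nPerm = 1000, seed = 1L, minPool = 50,
                         alpha = 0.05, useAdjusted = FALSE) {
    obs <- tfCooccurrence(net, tft)
    null <- degreeMatchedNull(net, tft, nPerm = nPerm, seed = seed,
                              minPool = minPool)
    res <- tfActivationPvalues(obs, null, alpha = alpha,
                               useAdjusted = useAdjusted)
    res$in_network <- res$tf %in% nodeIds(net)
    res
}

#' Common-TF index of a gene pair
#'
#' Arithmetic mean of the Jaccard coefficient |A∩B| / |A∪B| and the
#' overlap coefficient |A∩B| / max(|A|, |B|) of the two genes' regulator
#' sets A and B.
#'
#' @param geneU,geneV gene identifiers (must be in the table's universe).
#' @param tft a [TFRegulationTable-class].
#' @return index in \[0, 1\]; 0 (with a message) when either gene has no
#'   regulating TF.
#' @export
commonTfIndex <- function(geneU, geneV, tft) {
    if (!geneU %in% tft@universe || !geneV %in% tft@universe)
        stop("gene not present in the regulation table universe")
    A <- regulatorsOf(tft, geneU); B <- regulatorsOf(tft, geneV)
    if (!length(A) || !length(B)) {
        message("gene with zero regulating TFs; index reported as 0")
        return(0)
    }
    inter <- length(intersect(A, B))
    mean(c(inter / length(union(A, B)), inter / max(length(A), length(B))))
}

#' Shift in correlation among a TF's targets between conditions
#'
#' Collects the pairwise Spearman correlations among the TF's targets in
#' each condition and compares the two distributions with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param tf TF identifier.
#' @param tft a [TFRegulationTable-class].
#' @param corrA,corrB per-condition Spearman correlation matrices (from
#'   [spearmanMatrix()]), sharing row/column gene names.
#' @return list with per-condition `values` (each of length
#'   choose(nTargets, 2)), `summary` (n, mean, median per condition),
#'   `statistic` (KS distance) and `p.value`.
#' @export
targetCorrelationShift <- function(tf, tft, corrA, corrB) {
    tg <- intersect(targetsOf(tft, tf), rownames(corrA))
    tg <- intersect(tg, rownames(corrB))
    if (length(tg) < 2) stop("TF has fewer than 2 targets in the expression data")
    ut <- which(upper.tri(matrix(0, length(tg), length(tg))))
    va <- corrA[tg, tg][ut]; vb <- corrB[tg, tg][ut]
    kt <- suppressWarnings(stats::ks.test(va, vb))
    summ <- data.frame(condition = c("a", "b"),
                       n = c(length(va), length(vb)),
                       mean = c(mean(va), mean(vb)),
                       median = c(stats::median(va), stats::median(vb)))
    list(values = list(a = va, b = vb), summary = summ,
         statistic = unname(kt$statistic), p.value = kt$p.value)
}
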
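#' @include methods.R
NULL

# Quantile-normalize one matrix (one quantile pool). Missing entries keep
# missing; each column's non-missing entries are mapped onto the reference
# distribution (row-wise mean of per-column sorted values, interpolated for
# columns with fewer observations), ties getting the average reference value.
.quantileNormalizeMatrix <- function(m) {
    if (ncol(m) < 2L) stop("nothing to normalize against")
    n <- nrow(m)
    if (n == 0L) return(m)
    grid <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
    ref <- rowMeans(vapply(seq_len(ncol(m)), function(j) {
        x <- m[, j]; x <- x[!is.na(x)]
        if (!length(x)) stop("column ", j, " is entirely missing")
        stats::quantile(x, probs = grid, type = 7, names = FALSE)
    }, numeric(n)))
    out <- m
    for (j in seq_len(ncol(m))) {
        obs <- !is.na(m[, j])
        nobs <- sum(obs)
        r <- rank(m[obs, j], ties.method = "average")
        pos <- if (nobs == 1L) (n + 1) / 2 else 1 + (r - 1) / (nobs - 1) * (n - 1)
        lo <- floor(pos); hi <- ceiling(pos); w <- pos - lo
        out[obs, j] <- ref[lo] * (1 - w) + ref[hi] * w
    }
    out
}

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
    .quantileNormalizeMatrix(x)
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "TimecourseExperiment",
          function(x, perCondition = TRUE, ...) {
    m <- assay(x)
    if (perCondition) {
        for (cc in conditionNames(x)) {
            j <- sampleCondition(x) == cc
            m[, j] <- .quantileNormalizeMatrix(m[, j, drop = FALSE])
        }
    } else {
        m <- .quantileNormalizeMatrix(m)
    }
    SummarizedExperiment::assay(x, withDimnames = FALSE) <- m
    x
})

#' Discard probes with too many missing timepoints
#'
#' A probe survives only if its fraction of missing values is at most
#' `maxMissingFrac` within *each* condition separately.
#'
#' @param x a [TimecourseExperiment-class].
#' @param maxMissingFrac maximum tolerated missing fraction per condition
#'   (default 0.20).
#' @return The filtered [TimecourseExperiment-class] (possibly with zero
#'   rows).
#' @export
filterMissingProbes <- function(x, maxMissingFrac = 0.20) {
    stopifnot(maxMissingFrac >= 0, maxMissingFrac < 1)
    m <- assay(x)
    keep <- rep(TRUE, nrow(m))
    for (cc in conditionNames(x)) {
        j <- sampleCondition(x) == cc
        frac <- rowMeans(is.na(m[, j, drop = FALSE]))
        keep <- keep & (frac <= maxMissingFrac)
    }
    x[keep, ]
}

# impute one matrix in place
.knnImputeMatrix <- function(m, k) {
    stopifnot(k >= 1)
    miss <- which(is.na(m), arr.ind = TRUE)
    if (!nrow(miss)) return(m)
    out <- m
    for (i in unique(miss[, 1])) {
        cols <- miss[miss[, 1] == i, 2]
        for (j in cols) {
            cand <- which(!is.na(m[, j]))
            cand <- setdiff(cand, i)
            if (!length(cand))
                stop("no candidate neighbour observed at column ", j)
            d <- vapply(cand, function(r) {
                shared <- !is.na(m[i, ]) & !is.na(m[r, ])
                if (!any(shared)) return(Inf)
                sqrt(sum((m[i, shared] - m[r, shared])^2))
            }, numeric(1))
            if (length(cand) < k)
                warning("fewer than k=", k, " candidate neighbours; using all ",
                        length(cand), call. = FALSE)
            nb <- cand[order(d)][seq_len(min(k, length(cand)))]
            out[i, j] <- mean(m[nb, j])
        }
    }
    out
}

#' @rdname knnImpute
#' @export
setMethod("knnImpute", "matrix", function(x, k = 10, ...) {
    .knnImputeMatrix(x, k)
})

#' @rdname knnImpute
#' @export
setMethod("knnImpute", "TimecourseExperiment", function(x, k = 10, ...) {
    m <- assay(x)
    for (cc in conditionNames(x)) {
        j <- sampleCondition(x) == cc
        m[, j] <- .knnImputeMatrix(m[, j, drop = FALSE], k)
    }
    SummarizedExperiment::assay(x, withDimnames = FALSE) <- m
    x
})

#' Collapse probes to genes
#'
#' Probes without a gene annotation are removed; probes mapping to the same
#' gene are averaged (arithmetic mean per sample).
#'
#' @param x a [TimecourseExperiment-class] keyed by probe id.
#' @param annotation data.frame whose first two columns are probe id and
#'   gene id.
#' @return A [TimecourseExperiment-class] keyed by gene id.
#' @export
collapseProbes <- function(x, annotation) {
    annotation <- as.data.frame(annotation)
    if (!nrow(annotation)) stop("empty probe annotation map")
    colnames(annotation)[1:2] <- c("probe_id", "gene_id")
    annotation$probe_id <- as.character(annotation$probe_id)
    annotation$gene_id <- as.character(annotation$gene_id)
    if (any(!nzchar(annotation$gene_id)))
        stop("empty gene_id in annotation map")
    gene <- annotation$gene_id[match(rownames(x), annotation$probe_id)]
    keep <- !is.na(gene)
    m <- assay(x)[keep, , drop = FALSE]
    gene <- gene[keep]
    collapsed <- rowsum(m, group = gene, reorder = FALSE) /
        as.vector(table(factor(gene, levels = unique(gene))))
    TimecourseExperiment(collapsed, sampleCondition(x), sampleTime(x))
}

#' Remove genes with low expression variance
#'
#' The per-gene standard deviation is computed within each condition; a gene
#' is kept iff its SD is in the top `topFrac` of all genes in at least one
#' condition (dropped only when low-variance in *both*). Ties at the
#' empirical quantile cut are kept.
#'
#' @param x a [TimecourseExperiment-class] (genes x samples, both
#'   conditions).
#' @param topFrac fraction of top-variance genes retained per condition
#'   (default 0.25).
#' @return The filtered [TimecourseExperiment-class].
#' @export
varianceFilter <- function(x, topFrac = 0.25) {
    stopifnot(topFrac > 0, topFrac <= 1)
    keep <- rep(FALSE, nrow(x))
    for (cc in conditionNames(x)) {
        sds <- apply(conditionMatrix(x, cc), 1, stats::sd)
        cut <- stats::quantile(sds, probs = 1 - topFrac, names = FALSE)
        keep <- keep | (sds >= cut)
    }
    x[keep, ]
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: quantile normalization, missing-probe filter, KNN
#' imputation, probe collapse (if an annotation is given), variance filter.
#' Postconditions are asserted between steps.
#'
#' @param x a [TimecourseExperiment-class] of raw probe intensities.
#' @param annotation optional probe -> gene data.frame for
#'   [collapseProbes()]; when `NULL` rows are assumed to be genes already.
#' @param maxMissingFrac,k,topFrac step parameters (defaults 0.20, 10, 0.25).
#' @param perCondition normalize each condition as its own quantile pool.
#' @return list with `data` (the cleaned [TimecourseExperiment-class]) and
#'   `log`, a data.frame of per-step row counts.
#' @export
preprocessExpression <- function(x, annotation = NULL, maxMissingFrac = 0.20,
                                 k = 10, topFrac = 0.25, perCondition = TRUE) {
    steps <- character(); counts <- integer()
    note <- function(s, obj) {
        steps <<- c(steps, s); counts <<- c(counts, nrow(obj))
    }
    note("input", x)
    x <- quantileNormalize(x, perCondition = perCondition)
    note("quantile_normalize", x)
    x <- filterMissingProbes(x, maxMissingFrac)
    note("missing_filter", x)
    x <- knnImpute(x, k)
    stopifnot(!anyNA(assay(x)))
    note("knn_impute", x)
    if (!is.null(annotation)) {
        x <- collapseProbes(x, annotation)
        note("collapse_probes", x)
    }
    x <- varianceFilter(x, topFrac)
    note("variance_filter", x)
    list(data = x, log = data.frame(step = steps, n_rows = counts))
}
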
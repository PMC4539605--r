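#' @include ontology.R
NULL

#' Schlicker relevance similarity between two terms
#'
#' Combines Lin's ratio with a Resnik-style specificity weight: over the
#' common ancestors c of the two terms (is_a closure, including the terms
#' themselves),
#' `s = max_c (2 log p(c) / (log p(t1) + log p(t2))) * (1 - p(c))`.
#' The `(1 - p(c))` factor downweights shallow ancestors, so two terms
#' whose only shared ancestor is the root (p = 1) get similarity 0; a term
#' compared with itself gets `1 - p(t)`.
#'
#' @param t1,t2 term identifiers with defined annotation frequency.
#' @param ic named p(term) vector from [informationContent()].
#' @param dag an [OntologyDAG-class].
#' @return similarity in \[0, 1\]; symmetric in its term arguments.
#' @export
simRel <- function(t1, t2, ic, dag) {
    if (!t1 %in% names(ic) || !t2 %in% names(ic))
        stop("term with undefined annotation frequency")
    p1 <- ic[[t1]]; p2 <- ic[[t2]]
    common <- intersect(ancestorsOf(dag, t1), ancestorsOf(dag, t2))
    common <- common[common %in% names(ic)]
    if (!length(common)) return(0)
    denom <- log(p1) + log(p2)
    pc <- ic[common]
    lin <- if (denom == 0) rep(0, length(pc)) else 2 * log(pc) / denom
    s <- max(lin * (1 - pc))
    min(max(s, 0), 1)
}

# memoised all-pairs term similarity for a set of terms
.termSimMatrix <- function(terms1, terms2, ic, dag) {
    outer(seq_along(terms1), seq_along(terms2),
          Vectorize(function(i, j) simRel(terms1[i], terms2[j], ic, dag)))
}

#' Gene-level functional similarity (funSim, best-match average)
#'
#' Builds the N x M matrix S of pairwise term similarities between the two
#' genes' (direct) annotation term sets and returns the best-match average
#' `0.5 * (mean over rows of row maxima + mean over columns of column
#' maxima)`.
#'
#' @param geneA,geneB gene identifiers.
#' @param ann annotation data.frame (gene, term, evidence), evidence-
#'   filtered; terms must have defined annotation frequency.
#' @param ic named p(term) vector from [informationContent()].
#' @param dag an [OntologyDAG-class].
#' @return funSim in \[0, 1\], symmetric.
#' @export
funSim <- function(geneA, geneB, ann, ic, dag) {
    ta <- unique(ann$term[ann$gene == geneA])
    tb <- unique(ann$term[ann$gene == geneB])
    ta <- ta[ta %in% names(ic)]; tb <- tb[tb %in% names(ic)]
    if (!length(ta) || !length(tb)) stop("no usable annotations")
    S <- .termSimMatrix(ta, tb, ic, dag)
    0.5 * (mean(apply(S, 1, max)) + mean(apply(S, 2, max)))
}

#' Functional similarity profile of a gene set
#'
#' Symmetric matrix of pairwise funSim values. Genes without usable
#' annotations are excluded (a message reports how many); duplicate gene
#' ids are an error.
#'
#' @param genes character vector of gene ids.
#' @inheritParams funSim
#' @return symmetric numeric matrix with the retained genes as dimnames;
#'   the diagonal holds each gene's self-similarity.
#' @export
similarityMatrix <- function(genes, ann, ic, dag) {
    if (anyDuplicated(genes)) stop("duplicate gene ids")
    termsOf <- lapply(genes, function(g) {
        tt <- unique(ann$term[ann$gene == g])
        tt[tt %in% names(ic)]
    })
    names(termsOf) <- genes
    usable <- lengths(termsOf) > 0
    if (any(!usable))
        message(sum(!usable), " gene(s) without usable annotations excluded")
    genes <- genes[usable]; termsOf <- termsOf[usable]
    n <- length(genes)
    # memoise term-pair similarities: many genes share terms
    allTerms <- sort(unique(unlist(termsOf)))
    TS <- matrix(NA_real_, length(allTerms), length(allTerms),
                 dimnames = list(allTerms, allTerms))
    for (i in seq_along(allTerms)) for (j in i:length(allTerms)) {
        s <- simRel(allTerms[i], allTerms[j], ic, dag)
        TS[i, j] <- s; TS[j, i] <- s
    }
    out <- matrix(0, n, n, dimnames = list(genes, genes))
    for (i in seq_len(n)) for (j in i:n) {
        S <- TS[termsOf[[i]], termsOf[[j]], drop = FALSE]
        v <- 0.5 * (mean(apply(S, 1, max)) + mean(apply(S, 2, max)))
        out[i, j] <- v; out[j, i] <- v
    }
    out
}
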
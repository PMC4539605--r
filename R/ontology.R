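#' @include methods.R
NULL

# assemble an OntologyDAG from a term table and parents list; detects
# cycles by Kahn topological sort and precomputes ancestor closures
.buildDAG <- function(terms, parents) {
    ids <- terms$id
    parents <- parents[ids]
    indeg <- lengths(parents)
    names(indeg) <- ids
    children <- vector("list", length(ids)); names(children) <- ids
    for (id in ids) for (p in parents[[id]])
        children[[p]] <- c(children[[p]], id)
    queue <- ids[indeg == 0]
    order <- character()
    deg <- indeg
    while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        order <- c(order, v)
        for (ch in children[[v]]) {
            deg[ch] <- deg[ch] - 1L
            if (deg[ch] == 0L) queue <- c(queue, ch)
        }
    }
    if (length(order) != length(ids)) stop("ontology contains a cycle")
    anc <- vector("list", length(ids)); names(anc) <- ids
    for (v in order)
        anc[[v]] <- unique(c(v, unlist(anc[parents[[v]]], use.names = FALSE)))
    root <- ids[indeg == 0]
    if (!length(root)) stop("ontology contains a cycle")
    new("OntologyDAG", terms = terms, parents = parents, ancestors = anc,
        root = root)
}

#' Load an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas (id, name, namespace, is_a, is_obsolete),
#' retains one namespace (biological_process by default), drops obsolete
#' terms, and errors with a line number on malformed stanzas or on cycles.
#' is_a links pointing outside the retained namespace are dropped.
#'
#' @param path OBO file path.
#' @param namespace namespace to retain (default `"biological_process"`).
#' @return an [OntologyDAG-class].
#' @export
loadObo <- function(path, namespace = "biological_process") {
    lines <- readLines(path)
    inTerm <- FALSE
    cur <- NULL; start <- 0L
    recs <- list()
    flush <- function(cur, start) {
        if (is.null(cur)) return(NULL)
        if (is.null(cur$id))
            stop("malformed [Term] stanza without id at line ", start)
        cur
    }
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (ln == "[Term]") {
            r <- flush(cur, start)
            if (!is.null(r)) recs[[length(recs) + 1L]] <- r
            cur <- list(is_a = character(), obsolete = FALSE, name = NA_character_,
                        namespace = NA_character_)
            start <- i
            inTerm <- TRUE
        } else if (grepl("^\\[", ln)) {
            r <- flush(cur, start)
            if (!is.null(r)) recs[[length(recs) + 1L]] <- r
            cur <- NULL; inTerm <- FALSE
        } else if (inTerm && nzchar(ln)) {
            kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
            if (length(kv) != 3)
                stop("malformed line ", i, ": ", ln)
            key <- kv[2]; val <- sub("\\s*!.*$", "", kv[3])
            if (key == "id") cur$id <- val
            else if (key == "name") cur$name <- val
            else if (key == "namespace") cur$namespace <- val
            else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
            else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
        }
    }
    r <- flush(cur, start)
    if (!is.null(r)) recs[[length(recs) + 1L]] <- r
    keep <- vapply(recs, function(r)
        !r$obsolete && identical(r$namespace, namespace), logical(1))
    recs <- recs[keep]
    if (!length(recs)) stop("no terms in namespace ", namespace)
    terms <- data.frame(id = vapply(recs, `[[`, character(1), "id"),
                        name = vapply(recs, `[[`, character(1), "name"),
                        namespace = namespace, stringsAsFactors = FALSE)
    parents <- lapply(recs, function(r) intersect(r$is_a, terms$id))
    names(parents) <- terms$id
    .buildDAG(terms, parents)
}

#' Write an ontology as OBO 1.2
#'
#' @param dag an [OntologyDAG-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeObo <- function(dag, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("format-version: 1.2", ""), con)
    for (i in seq_len(nrow(dag@terms))) {
        id <- dag@terms$id[i]
        writeLines(c("[Term]",
                     paste0("id: ", id),
                     paste0("name: ", dag@terms$name[i]),
                     paste0("namespace: ", dag@terms$namespace[i]),
                     paste0("is_a: ", dag@parents[[id]]),
                     ""), con)
    }
    invisible(path)
}

#' Read a three-column annotation table
#'
#' Reduced GAF-like dialect: columns gene, term, evidence.
#'
#' @param path TSV path with a header row.
#' @return data.frame with columns `gene`, `term`, `evidence`.
#' @export
readAnnotations <- function(path) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    colnames(ann)[1:3] <- c("gene", "term", "evidence")
    ann
}

#' Filter annotations by evidence code
#'
#' Removes annotations carrying an excluded evidence code (by default IEP,
#' inferred from expression pattern, and IGI, inferred from genetic
#' interaction, which would bias expression-based analyses). Genes left
#' without any annotation are reported in a message.
#'
#' @param ann data.frame (gene, term, evidence).
#' @param excludedCodes character vector of codes to drop.
#' @return filtered data.frame.
#' @export
filterAnnotations <- function(ann, excludedCodes = c("IEP", "IGI")) {
    out <- ann[!(ann$evidence %in% excludedCodes), , drop = FALSE]
    lost <- setdiff(unique(ann$gene), unique(out$gene))
    if (length(lost))
        message(length(lost), " gene(s) left without annotations and dropped ",
                "from similarity analyses")
    out
}

#' Term annotation frequencies (information-content map)
#'
#' Propagates each gene's annotations to all ancestors and computes, per
#' term, p(t) = (genes annotated to t or any descendant) / (genes annotated
#' anywhere in the namespace). p is 1 at the root and non-increasing from
#' root to leaves; -log p is the Resnik information content.
#'
#' @param dag an [OntologyDAG-class].
#' @param ann annotation data.frame (gene, term, evidence), already
#'   evidence-filtered; terms outside the DAG are ignored.
#' @return named numeric vector p(term) for every term with at least one
#'   propagated annotation (terms with none have undefined p and are
#'   absent).
#' @export
informationContent <- function(dag, ann) {
    ann <- ann[ann$term %in% termIds(dag), , drop = FALSE]
    if (!nrow(ann)) stop("no annotations overlap the DAG")
    perGene <- split(ann$term, ann$gene)
    N <- length(perGene)
    hits <- lapply(perGene, function(tt)
        unique(unlist(dag@ancestors[unique(tt)], use.names = FALSE)))
    tb <- table(unlist(hits, use.names = FALSE))
    p <- as.numeric(tb) / N
    names(p) <- names(tb)
    p
}

#' Hypergeometric enrichment of GO terms
#'
#' Upper-tail hypergeometric test per term: with a test set of n genes of
#' which k are annotated (after ancestor propagation) to term g, and a
#' reference set of N genes of which M are annotated to g,
#' p = P(X >= k), X ~ Hypergeometric(N, M, n). Terms with M >= 1 and
#' k >= 1 are tested; BH adjustment across the tested terms of the run.
#'
#' @param testSet character vector of genes (must be a subset of
#'   `referenceSet`, non-empty).
#' @param referenceSet character vector of background genes.
#' @param dag an [OntologyDAG-class].
#' @param ann annotation data.frame (gene, term, evidence).
#' @return data.frame (term, k, n, M, N, p, q) sorted by q then p.
#' @export
hypergeomEnrich <- function(testSet, referenceSet, dag, ann) {
    if (!length(testSet)) stop("empty test set")
    if (!all(testSet %in% referenceSet))
        stop("test set must be a subset of the reference set")
    ann <- ann[ann$term %in% termIds(dag) & ann$gene %in% referenceSet, ,
               drop = FALSE]
    perGene <- lapply(split(ann$term, ann$gene), function(tt)
        unique(unlist(dag@ancestors[unique(tt)], use.names = FALSE)))
    N <- length(referenceSet); n <- length(testSet)
    refHits <- table(unlist(perGene, use.names = FALSE))
    testHits <- table(unlist(perGene[intersect(names(perGene), testSet)],
                             use.names = FALSE))
    terms <- names(testHits)          # tested terms: M >= 1 and k >= 1
    k <- as.integer(testHits[terms])
    M <- as.integer(refHits[terms])
    p <- stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
    out <- data.frame(term = terms, k = k, n = n, M = M, N = N, p = p,
                      q = bhAdjust(p), stringsAsFactors = FALSE)
    out[order(out$q, out$p, out$term), , drop = FALSE]
}
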
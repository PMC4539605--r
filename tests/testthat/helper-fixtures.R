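# shared fixtures and independent brute-force oracles

pairKey <- function(u, v) paste(pmin(u, v), pmax(u, v))

# small TimecourseExperiment from two matrices
tceOf <- function(mA, mB) {
    TimecourseExperiment(cbind(mA, mB),
                         condition = rep(c("a", "b"), c(ncol(mA), ncol(mB))),
                         time = c(seq_len(ncol(mA)), seq_len(ncol(mB))) * 10)
}

# write a chain ontology root -> A -> B as OBO and load it;
# annotations give propagated gene counts 4 / 2 / 1
chainOntology <- function() {
    obo <- tempfile(fileext = ".obo")
    writeLines(c(
        "format-version: 1.2", "",
        "[Term]", "id: T:0001", "name: root",
        "namespace: biological_process", "",
        "[Term]", "id: T:0002", "name: middle",
        "namespace: biological_process", "is_a: T:0001 ! root", "",
        "[Term]", "id: T:0003", "name: leaf",
        "namespace: biological_process", "is_a: T:0002 ! middle", ""), obo)
    dag <- loadObo(obo)
    ann <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                      term = c("T:0001", "T:0001", "T:0002", "T:0003"),
                      evidence = "EXP")
    list(dag = dag, ann = ann, ic = informationContent(dag, ann))
}

# brute-force triad census by triple enumeration
bruteTriads <- function(net) {
    e <- edgeTable(net)
    key <- pairKey(e$u, e$v)
    sgn <- setNames(e$sign, key)
    nodes <- nodeIds(net)
    counts <- c("0" = 0L, "1" = 0L, "2" = 0L, "3" = 0L)
    if (length(nodes) < 3) return(counts)
    trip <- utils::combn(nodes, 3)
    for (j in seq_len(ncol(trip))) {
        v <- trip[, j]
        k <- c(pairKey(v[1], v[2]), pairKey(v[1], v[3]), pairKey(v[2], v[3]))
        if (all(k %in% key)) {
            np <- as.character(sum(sgn[k] == 1L))
            counts[np] <- counts[np] + 1L
        }
    }
    counts
}

# brute-force agglomerative average-linkage over a distance matrix:
# cluster distance = mean pairwise member distance; merge until k remain
bruteAverageLinkage <- function(d, k) {
    d <- as.matrix(d)
    clusters <- as.list(seq_len(nrow(d)))
    while (length(clusters) > k) {
        best <- c(NA, NA); bestd <- Inf
        for (i in seq_len(length(clusters) - 1))
            for (j in (i + 1):length(clusters)) {
                dd <- mean(d[clusters[[i]], clusters[[j]]])
                if (dd < bestd) { bestd <- dd; best <- c(i, j) }
            }
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    lab <- integer(nrow(d))
    for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
    lab
}

# canonical form of a partition for label-free comparison
partitionOf <- function(labels) {
    unname(sort(vapply(split(names(labels), labels),
                       function(g) paste(sort(g), collapse = ","),
                       character(1))))
}

# exhaustive hypergeometric upper tail: draw n of N (M marked), P(X >= k)
bruteHyperTail <- function(N, M, n, k) {
    sets <- utils::combn(N, n)
    mean(vapply(seq_len(ncol(sets)),
                function(j) sum(sets[, j] <= M) >= k, logical(1)))
}
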
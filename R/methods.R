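#' @include AllGenerics.R
NULL

#' @rdname sampleCondition
#' @export
setMethod("sampleCondition", "TimecourseExperiment",
          function(x) as.character(colData(x)$condition))

#' @rdname sampleTime
#' @export
setMethod("sampleTime", "TimecourseExperiment",
          function(x) as.numeric(colData(x)$time))

#' @rdname conditionNames
#' @export
setMethod("conditionNames", "TimecourseExperiment",
          function(x) unique(sampleCondition(x)))

#' @rdname conditionMatrix
#' @export
setMethod("conditionMatrix", "TimecourseExperiment", function(x, condition) {
    keep <- sampleCondition(x) == condition
    if (!any(keep)) stop("unknown condition: ", condition)
    assay(x)[, keep, drop = FALSE]
})

setMethod("show", "TimecourseExperiment", function(object) {
    cc <- table(sampleCondition(object))
    cat("TimecourseExperiment:", nrow(object), "features,",
        ncol(object), "samples\n")
    cat("  conditions:",
        paste(sprintf("%s (%d timepoints)", names(cc), cc), collapse = ", "),
        "\n")
})

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "SignedNetwork", function(x) x@nodes)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "SignedNetwork", function(x) x@edges)

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "SignedNetwork", function(x) {
    e <- x@edges
    if (nrow(e)) {
        g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                           vertices = data.frame(name = x@nodes))
    } else {
        g <- igraph::make_empty_graph(n = length(x@nodes), directed = FALSE)
        g <- igraph::set_vertex_attr(g, "name", value = x@nodes)
    }
    g
})

setMethod("show", "SignedNetwork", function(object) {
    e <- object@edges
    cat("SignedNetwork:", length(object@nodes), "nodes,", nrow(e), "edges",
        sprintf("(%d positive, %d negative)\n",
                sum(e$sign == 1L), sum(e$sign == -1L)))
    if (nrow(e)) {
        ty <- table(e$type)
        cat("  edge types:",
            paste(sprintf("%s: %d", names(ty), ty), collapse = ", "), "\n")
    }
})

#' @rdname ancestorsOf
#' @export
setMethod("ancestorsOf", "OntologyDAG", function(dag, term) {
    a <- dag@ancestors[[term]]
    if (is.null(a)) stop("unknown term: ", term)
    a
})

#' @rdname termIds
#' @export
setMethod("termIds", "OntologyDAG", function(dag) dag@terms$id)

setMethod("show", "OntologyDAG", function(object) {
    cat("OntologyDAG:", nrow(object@terms), "terms, namespace",
        paste(unique(object@terms$namespace), collapse = "/"),
        "- root:", paste(object@root, collapse = ", "), "\n")
})

#' @rdname targetsOf
#' @export
setMethod("targetsOf", "TFRegulationTable", function(x, tf) {
    t <- x@targets[[tf]]
    if (is.null(t)) stop("unknown TF: ", tf)
    t
})

#' @rdname regulatorsOf
#' @export
setMethod("regulatorsOf", "TFRegulationTable", function(x, gene) {
    names(x@targets)[vapply(x@targets, function(t) gene %in% t, logical(1))]
})

#' @rdname tfCountOf
#' @export
setMethod("tfCountOf", "TFRegulationTable", function(x, genes) {
    cnt <- rep(0L, length(genes)); names(cnt) <- genes
    hit <- genes %in% x@universe
    cnt[hit] <- x@geneTFCount[genes[hit]]
    cnt
})

setMethod("show", "TFRegulationTable", function(object) {
    cat("TFRegulationTable:", length(object@targets), "TFs,",
        length(object@universe), "genes,",
        sum(lengths(object@targets)), "regulations\n")
})

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

setMethod("show", "ClusterAssignment", function(object) {
    cat("ClusterAssignment:", length(object@labels), "genes in",
        object@k, "clusters; sizes:",
        paste(tabulate(object@labels, object@k), collapse = ", "), "\n")
})
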
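#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Two-condition time-course expression container
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass for
#' log-intensity expression values measured over time under two (or more)
#' conditions. Each column carries a `condition` label and a `time` (minutes)
#' in `colData`; correlations are only ever computed within a condition, so
#' the two series may have unequal numbers of timepoints.
#'
#' @slot .. see `SummarizedExperiment`; the first assay holds the values.
#' @export
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
    cd <- colData(object)
    if (!all(c("condition", "time") %in% colnames(cd)))
        return("colData must contain 'condition' and 'time' columns")
    if (is.null(rownames(object)))
        return("rows must be named by probe or gene identifiers")
    if (anyDuplicated(rownames(object)))
        return("row identifiers must be unique")
    if (!is.numeric(cd$time))
        return("'time' must be numeric (minutes)")
    for (cc in unique(cd$condition)) {
        tt <- cd$time[cd$condition == cc]
        if (any(diff(tt) <= 0))
            return(sprintf("times within condition '%s' must be strictly increasing", cc))
    }
    TRUE
})

#' Construct a TimecourseExperiment
#'
#' @param values numeric matrix, rows = probes/genes, columns = samples.
#' @param condition condition label per column.
#' @param time numeric time in minutes per column; must be strictly
#'   increasing within each condition.
#' @return A [TimecourseExperiment-class].
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' tce <- TimecourseExperiment(m, rep(c("a", "b"), each = 5),
#'                             rep(seq(0, 40, 10), 2))
#' @export
TimecourseExperiment <- function(values, condition, time) {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- paste0(condition, "_t", time)
    se <- SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(condition = as.character(condition),
                                       time = as.numeric(time),
                                       row.names = colnames(values)))
    new("TimecourseExperiment", se)
}

#' Undirected signed network
#'
#' Container for DCEN/CCEN-style networks: an undirected simple graph whose
#' edges carry a sign (+1 / -1) and a type (`"DCEL"`, `"CCEL"` or
#' `"generic"`). Unsigned topology statistics ignore the sign; the triad
#' census and edge counts use it.
#'
#' @slot nodes character vector of node (gene) identifiers; the union of the
#'   edge endpoints plus any declared isolates.
#' @slot edges data.frame with columns `u`, `v`, `sign`, `type`, `weight`;
#'   pairs stored with `u < v`.
#' @export
setClass("SignedNetwork",
         representation(nodes = "character", edges = "data.frame"))

setValidity("SignedNetwork", function(object) {
    e <- object@edges
    need <- c("u", "v", "sign", "type", "weight")
    if (!all(need %in% colnames(e)))
        return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
    if (nrow(e)) {
        if (any(e$u == e$v)) return("self-loops are not allowed")
        key <- paste(pmin(e$u, e$v), pmax(e$u, e$v))
        if (anyDuplicated(key)) return("duplicate edges are not allowed")
        if (!all(e$sign %in% c(-1L, 1L))) return("edge signs must be -1 or 1")
        if (!all(c(e$u, e$v) %in% object@nodes))
            return("all edge endpoints must appear in the node set")
    }
    if (anyDuplicated(object@nodes)) return("duplicate node identifiers")
    TRUE
})

#' Construct a SignedNetwork
#'
#' @param edges data.frame with columns `u`, `v` and either `sign` (+1/-1) or
#'   a numeric `score`/`weight` whose sign is used; optional `weight`.
#' @param nodes optional character vector of nodes (to declare isolates);
#'   defaults to the edge endpoints.
#' @param type edge type recorded for edges lacking a `type` column.
#' @return A [SignedNetwork-class]. An edge listed twice with conflicting
#'   signs is an error.
#' @export
SignedNetwork <- function(edges = NULL, nodes = NULL, type = "generic") {
    if (is.null(edges) || nrow(edges) == 0L) {
        e <- data.frame(u = character(), v = character(), sign = integer(),
                        type = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
    } else {
        edges <- as.data.frame(edges)
        u <- as.character(edges$u); v <- as.character(edges$v)
        swap <- u > v
        tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
        if (!is.null(edges[["sign"]])) {
            sg <- as.integer(sign(edges[["sign"]]))
        } else if (!is.null(edges[["score"]])) {
            sg <- as.integer(sign(edges[["score"]]))
        } else if (!is.null(edges[["weight"]])) {
            sg <- as.integer(sign(edges[["weight"]]))
        } else {
            sg <- rep(1L, nrow(edges))
        }
        if (any(sg == 0L))
            stop("edge sign cannot be zero; drop zero-score pairs first")
        wt <- if (!is.null(edges[["weight"]])) as.numeric(edges[["weight"]])
              else if (!is.null(edges[["score"]])) as.numeric(edges[["score"]])
              else rep(1, nrow(edges))
        ty <- if (!is.null(edges[["type"]])) as.character(edges[["type"]])
              else rep(type, nrow(edges))
        key <- paste(u, v)
        if (anyDuplicated(key)) {
            first <- match(key, key)
            if (any(sg != sg[first]))
                stop("duplicate edge with conflicting signs")
            keep <- !duplicated(key)
            u <- u[keep]; v <- v[keep]; sg <- sg[keep]; wt <- wt[keep]; ty <- ty[keep]
        }
        e <- data.frame(u = u, v = v, sign = sg, type = ty, weight = wt,
                        stringsAsFactors = FALSE)
    }
    nn <- sort(unique(c(nodes, e$u, e$v)))
    new("SignedNetwork", nodes = nn, edges = e)
}

#' Gene Ontology DAG (is_a closure)
#'
#' A rooted directed acyclic graph of ontology terms restricted to one
#' namespace, with the ancestor closure (including the term itself)
#' precomputed for semantic-similarity queries.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot parents named list, term id -> character vector of is_a parents.
#' @slot ancestors named list, term id -> ancestor closure including self.
#' @slot root character vector of terms without parents (usually length 1).
#' @export
setClass("OntologyDAG",
         representation(terms = "data.frame", parents = "list",
                        ancestors = "list", root = "character"))

setValidity("OntologyDAG", function(object) {
    ids <- object@terms$id
    if (anyDuplicated(ids)) return("duplicate term ids")
    if (!all(names(object@parents) == ids)) return("parents list out of sync")
    if (!all(unlist(object@parents) %in% ids))
        return("parent term missing from DAG")
    if (length(object@root) < 1L) return("DAG has no root")
    TRUE
})

#' Transcription-factor regulation table
#'
#' TF -> target-gene sets plus the gene universe replacements are drawn from
#' in the degree-matched co-occurrence null. The "TF-count" of a gene is the
#' number of TFs regulating it.
#'
#' @slot targets named list, TF -> character vector of target genes.
#' @slot universe character vector of all genes considered.
#' @slot geneTFCount named integer, TF-count per universe gene.
#' @export
setClass("TFRegulationTable",
         representation(targets = "list", universe = "character",
                        geneTFCount = "integer"))

setValidity("TFRegulationTable", function(object) {
    if (any(lengths(object@targets) == 0L)) return("empty target set")
    if (!all(unlist(object@targets) %in% object@universe))
        return("target gene outside universe")
    if (!identical(names(object@geneTFCount), object@universe))
        return("geneTFCount out of sync with universe")
    TRUE
})

#' Construct a TFRegulationTable
#'
#' @param regulations two-column data.frame (`tf`, `target`), the flat
#'   export dialect of TF-target databases such as YEASTRACT.
#' @param universe optional gene universe; defaults to all target genes.
#'   Genes in the universe regulated by no TF get TF-count 0.
#' @return A [TFRegulationTable-class].
#' @export
TFRegulationTable <- function(regulations, universe = NULL) {
    regulations <- as.data.frame(regulations)
    colnames(regulations)[1:2] <- c("tf", "target")
    regulations$tf <- as.character(regulations$tf)
    regulations$target <- as.character(regulations$target)
    regulations <- unique(regulations[, c("tf", "target")])
    targets <- split(regulations$target, regulations$tf)
    universe <- sort(unique(c(universe, regulations$target)))
    cnt <- integer(length(universe)); names(cnt) <- universe
    tb <- table(regulations$target)
    cnt[names(tb)] <- as.integer(tb)
    new("TFRegulationTable", targets = targets, universe = universe,
        geneTFCount = cnt)
}

#' Cluster assignment from functional-profile clustering
#'
#' @slot labels named integer vector, gene -> cluster label (contiguous 1..k).
#' @slot k number of clusters.
#' @slot tree the `hclust` merge tree (or NULL for degenerate inputs).
#' @export
setClass("ClusterAssignment",
         representation(labels = "integer", k = "integer", tree = "ANY"))

setValidity("ClusterAssignment", function(object) {
    if (is.null(names(object@labels))) return("labels must be named by gene")
    if (anyDuplicated(names(object@labels))) return("duplicate gene in labels")
    lv <- sort(unique(object@labels))
    if (length(lv) && !identical(lv, seq_len(object@k)))
        return("cluster labels must be contiguous 1..k")
    TRUE
})
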
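#' @include AllClasses.R
NULL

#' Condition label per sample column
#' @param x a [TimecourseExperiment-class]
#' @return character vector, one label per column.
#' @export
setGeneric("sampleCondition", function(x) standardGeneric("sampleCondition"))

#' Time (minutes) per sample column
#' @param x a [TimecourseExperiment-class]
#' @return numeric vector of times.
#' @export
setGeneric("sampleTime", function(x) standardGeneric("sampleTime"))

#' Distinct condition labels, in column order
#' @param x a [TimecourseExperiment-class]
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' Expression matrix of one condition
#' @param x a [TimecourseExperiment-class]
#' @param condition condition label.
#' @return numeric matrix restricted to that condition's columns.
#' @export
setGeneric("conditionMatrix",
           function(x, condition) standardGeneric("conditionMatrix"))

#' Quantile normalization
#'
#' Forces every column to share one reference distribution (the row-wise
#' mean of the per-column sorted values), preserving within-column rank
#' order. Ties receive the average reference value and missing entries stay
#' missing (ranks are computed per column over the non-missing entries).
#'
#' @param x numeric matrix or [TimecourseExperiment-class].
#' @param ... further arguments; for the `TimecourseExperiment` method,
#'   `perCondition = TRUE` normalizes each condition's columns as a separate
#'   quantile pool (the two conditions are separate series), `FALSE` pools
#'   all columns.
#' @return Object of the same class with normalized values.
#' @export
setGeneric("quantileNormalize", function(x, ...) standardGeneric("quantileNormalize"))

#' K-nearest-neighbour imputation of missing values
#'
#' Missing entries are replaced by the unweighted mean of the values of the
#' `k` nearest rows (Euclidean distance over mutually non-missing columns,
#' neighbour pool restricted to the same matrix / condition) that are
#' observed at that column. Non-missing entries are never changed.
#'
#' @param x numeric matrix or [TimecourseExperiment-class] (imputed per
#'   condition).
#' @param k number of neighbours (default 10).
#' @param ... unused.
#' @return Object of the same class with no missing values.
#' @export
setGeneric("knnImpute", function(x, k = 10, ...) standardGeneric("knnImpute"))

#' Node identifiers of a network
#' @param x a [SignedNetwork-class]
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Edge table of a network
#' @param x a [SignedNetwork-class]
#' @return data.frame with columns `u`, `v`, `sign`, `type`, `weight`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Convert to an igraph object
#' @param x a [SignedNetwork-class]
#' @return an undirected `igraph` graph with `sign`, `type`, `weight`
#'   edge attributes.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Ancestor closure of a term (including the term itself)
#' @param dag an [OntologyDAG-class]
#' @param term term identifier.
#' @export
setGeneric("ancestorsOf", function(dag, term) standardGeneric("ancestorsOf"))

#' Term identifiers of a DAG
#' @param dag an [OntologyDAG-class]
#' @export
setGeneric("termIds", function(dag) standardGeneric("termIds"))

#' Target genes of a transcription factor
#' @param x a [TFRegulationTable-class]
#' @param tf TF identifier.
#' @export
setGeneric("targetsOf", function(x, tf) standardGeneric("targetsOf"))

#' Regulating TFs of a gene
#' @param x a [TFRegulationTable-class]
#' @param gene gene identifier.
#' @export
setGeneric("regulatorsOf", function(x, gene) standardGeneric("regulatorsOf"))

#' Number of TFs regulating each gene
#' @param x a [TFRegulationTable-class]
#' @param genes gene identifiers; genes outside the universe get count 0.
#' @export
setGeneric("tfCountOf", function(x, genes) standardGeneric("tfCountOf"))

#' Cluster labels
#' @param x a [ClusterAssignment-class]
#' @return named integer vector, gene -> cluster.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
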
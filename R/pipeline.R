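#' @include tf.R
NULL

#' Read an expression TSV plus sample-map sidecar
#'
#' Expression format: first column = probe/gene id, header row of sample
#' ids, missing values as empty fields or `NA`. The sample map is a TSV
#' with columns `sample`, `condition`, `time` (minutes).
#'
#' @param path expression TSV.
#' @param sampleMapPath sample map TSV.
#' @return a [TimecourseExperiment-class].
#' @export
readExpressionTsv <- function(path, sampleMapPath) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE, na.strings = c("NA", ""))
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
    map <- utils::read.delim(sampleMapPath, stringsAsFactors = FALSE)
    i <- match(colnames(m), map$sample)
    if (anyNA(i)) stop("sample(s) missing from the sample map: ",
                       paste(colnames(m)[is.na(i)], collapse = ", "))
    TimecourseExperiment(m, map$condition[i], map$time[i])
}

#' Read a two-column TF-target TSV
#'
#' @param path TSV with a header row; first column TF, second target gene
#'   (the flat dialect of YEASTRACT exports).
#' @param universe optional gene universe.
#' @return a [TFRegulationTable-class].
#' @export
readTfTable <- function(path, universe = NULL) {
    TFRegulationTable(utils::read.delim(path, stringsAsFactors = FALSE),
                      universe = universe)
}

#' Export a signed network
#'
#' Formats: `"tsv"` (edge table `u v sign type weight` with isolates
#' declared in a `# nodes:` header; lossless), `"graphml"` (via igraph;
#' lossless), `"sif"` (relation `pos`/`neg`; edge types and isolates are
#' not representable).
#'
#' @param net a [SignedNetwork-class].
#' @param path output file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("tsv", "sif", "graphml")) {
    format <- match.arg(format)
    e <- edgeTable(net)
    if (format == "tsv") {
        con <- file(path, "w"); on.exit(close(con))
        writeLines(paste0("# nodes: ", paste(nodeIds(net), collapse = ",")), con)
        utils::write.table(e, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else if (format == "sif") {
        rel <- ifelse(e$sign == 1L, "pos", "neg")
        utils::write.table(data.frame(e$u, rel, e$v), path, sep = "\t",
                           quote = FALSE, row.names = FALSE, col.names = FALSE)
    } else {
        igraph::write_graph(asIgraph(net), path, format = "graphml")
    }
    invisible(path)
}

#' Import a signed network written by [exportNetwork()]
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param type edge type assigned when reading SIF (which does not store
#'   types).
#' @return a [SignedNetwork-class].
#' @export
importNetwork <- function(path, format = c("tsv", "sif", "graphml"),
                          type = "generic") {
    format <- match.arg(format)
    if (format == "tsv") {
        first <- readLines(path, n = 1)
        nodes <- strsplit(sub("^# nodes: ?", "", first), ",")[[1]]
        nodes <- nodes[nzchar(nodes)]
        e <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
        SignedNetwork(e, nodes = nodes)
    } else if (format == "sif") {
        e <- utils::read.delim(path, header = FALSE,
                               stringsAsFactors = FALSE,
                               col.names = c("u", "rel", "v"))
        SignedNetwork(data.frame(u = e$u, v = e$v,
                                 sign = ifelse(e$rel == "pos", 1L, -1L),
                                 type = type))
    } else {
        g <- igraph::read_graph(path, format = "graphml")
        el <- igraph::as_data_frame(g, what = "edges")
        SignedNetwork(data.frame(u = el$from, v = el$to,
                                 sign = as.integer(el$sign),
                                 type = el$type, weight = el$weight),
                      nodes = igraph::V(g)$name)
    }
}

#' Overlap between a network and a reference edge list
#'
#' Counts unordered gene pairs present in both (e.g. checking DCELs
#' against a protein-protein or genetic interaction export).
#'
#' @param net a [SignedNetwork-class].
#' @param referenceEdges data.frame whose first two columns are the
#'   reference pairs.
#' @return list with `n` and `pairs` (data.frame of shared pairs).
#' @export
edgeOverlap <- function(net, referenceEdges) {
    e <- edgeTable(net)
    referenceEdges <- as.data.frame(referenceEdges)
    refKey <- unique(.pairKey(as.character(referenceEdges[[1]]),
                              as.character(referenceEdges[[2]])))
    hit <- .pairKey(e$u, e$v) %in% refKey
    list(n = sum(hit), pairs = e[hit, c("u", "v")])
}

#' Default pipeline parameters
#'
#' All thresholds of the analysis in one block: missing-probe fraction
#' 0.20, KNN k = 10, top-variance fraction 0.25, permutation count, DCEL
#' alpha 1e-4 (on BH-adjusted p), CCEL minimum correlation 0.95, score tie
#' weight 1, density z threshold 1.5, TF alpha 0.05, and the cluster count
#' (a user decision; 7 was used for the glucose-response analysis, 9 for
#' the cell-cycle one).
#'
#' @return named list of parameters.
#' @export
defaultPipelineParams <- function() {
    list(max_missing_frac = 0.20, knn_k = 10, top_var_frac = 0.25,
         n_perm = 1000, scheme = "pooled", alpha = 1e-4, adjust = TRUE,
         ccel_min_r = 0.95, tie_weight = 1, z_threshold = 1.5,
         tf_alpha = 0.05, tf_min_pool = 50, n_clusters = 7)
}

#' Run the full differential coexpression pipeline
#'
#' Configuration-driven orchestration: preprocessing, DCEN/CCEN
#' construction, topology, GO-based functional clustering, and TF
#' activation. Stages whose inputs are absent are skipped with a notice;
#' a failing stage aborts with its name (outputs of completed stages are
#' retained). One master seed derives all stage seeds via [stageSeed()],
#' so repeated runs are identical and adding a stage does not shift the
#' others' randomness.
#'
#' @param config a YAML file path or list with entries `expression`,
#'   `sample_map`, optional `probe_annotation`, `obo`, `go_annotations`,
#'   `tf_table`, `reference_edges`, plus `outdir`, `seed` and `params`
#'   (overriding [defaultPipelineParams()]).
#' @return the run manifest (per-stage parameters, row counts, timings and
#'   output-file hashes), invisibly; also written as `manifest.json`.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(!is.null(config$expression), !is.null(config$sample_map),
              !is.null(config$outdir))
    params <- utils::modifyList(defaultPipelineParams(),
                                config$params %||% list())
    seed <- as.integer(config$seed %||% 1L)
    outdir <- config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(seed = seed, params = params, stages = list())
    t0all <- Sys.time()
    record <- function(name, nIn, nOut, files, extra = list()) {
        manifest$stages[[name]] <<- c(list(
            n_in = nIn, n_out = nOut, seed = stageSeed(seed, name),
            seconds = as.numeric(Sys.time() - t0, units = "secs"),
            files = as.list(tools::md5sum(files))), extra)
    }
    stage <- function(name, expr) {
        t0 <<- Sys.time()
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    t0 <- Sys.time()

    ## 1. preprocess ------------------------------------------------------
    tce <- stage("preprocess", {
        raw <- readExpressionTsv(config$expression, config$sample_map)
        ann <- if (!is.null(config$probe_annotation))
            utils::read.delim(config$probe_annotation, stringsAsFactors = FALSE)
        pp <- preprocessExpression(raw, annotation = ann,
                                   maxMissingFrac = params$max_missing_frac,
                                   k = params$knn_k,
                                   topFrac = params$top_var_frac)
        log <- file.path(outdir, "preprocess_log.tsv")
        utils::write.table(pp$log, log, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        for (cc in conditionNames(pp$data)) {
            m <- conditionMatrix(pp$data, cc)
            utils::write.table(data.frame(gene = rownames(m), m,
                                          check.names = FALSE),
                               file.path(outdir, paste0("clean_", cc, ".tsv")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        }
        record("preprocess", nrow(raw), nrow(pp$data),
               c(log, file.path(outdir, paste0("clean_",
                                               conditionNames(pp$data), ".tsv"))))
        pp$data
    })

    ## 2. DCEN / CCEN -----------------------------------------------------
    nets <- stage("dcen", {
        links <- permutationPvalues(tce, nPerm = params$n_perm,
                                    scheme = params$scheme,
                                    seed = stageSeed(seed, "dcen"),
                                    tieWeight = params$tie_weight)
        dcels <- callDcels(links, alpha = params$alpha,
                           adjust = params$adjust)
        ccels <- callCcels(links, rMin = params$ccel_min_r)
        dcen <- assembleNetwork(dcels, type = "DCEL")
        ccelDf <- as.data.frame(ccels)[, c("u", "v")]
        ccen <- assembleNetwork(ccelDf, type = "CCEL")
        lp <- file.path(outdir, "dcels.tsv")
        utils::write.table(as.data.frame(dcels), lp, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        cp <- file.path(outdir, "ccels.tsv")
        utils::write.table(as.data.frame(ccels), cp, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        np <- file.path(outdir, "dcen.tsv")
        exportNetwork(dcen, np)
        record("dcen", nrow(tce), nrow(edgeTable(dcen)), c(lp, cp, np),
               list(n_ccels = nrow(edgeTable(ccen))))
        list(dcen = dcen, ccen = ccen)
    })

    ## 3. topology --------------------------------------------------------
    stage("topology", {
        if (nrow(edgeTable(nets$dcen)) >= 1) {
            ts <- topologySummary(nets$dcen)
            tp <- file.path(outdir, "topology.json")
            jsonlite::write_json(ts, tp, auto_unbox = TRUE, digits = NA,
                                 na = "null")
            record("topology", nrow(edgeTable(nets$dcen)), length(ts), tp)
        } else message("skipping topology: empty DCEN")
    })

    ## 4. GO clustering ---------------------------------------------------
    stage("go_cluster", {
        if (is.null(config$obo) || is.null(config$go_annotations)) {
            message("skipping GO clustering: no ontology/annotations supplied")
        } else if (length(nodeIds(nets$dcen)) < 3) {
            message("skipping GO clustering: DCEN too small")
        } else {
            dag <- loadObo(config$obo)
            ann <- filterAnnotations(readAnnotations(config$go_annotations))
            ic <- informationContent(dag, ann)
            genes <- intersect(nodeIds(nets$dcen), unique(ann$gene))
            sim <- similarityMatrix(genes, ann, ic, dag)
            cl <- clusterProfiles(sim, k = min(params$n_clusters, nrow(sim) - 1))
            dz <- densityZscores(nets$dcen, cl,
                                 nPerm = params$n_perm,
                                 seed = stageSeed(seed, "go_cluster"),
                                 zThreshold = params$z_threshold)
            rt <- betweenWithinRatioTest(nets$dcen, cl,
                                         nPerm = params$n_perm,
                                         seed = stageSeed(seed, "go_cluster"))
            ca <- file.path(outdir, "clusters.tsv")
            utils::write.table(data.frame(gene = names(clusterLabels(cl)),
                                          cluster = clusterLabels(cl)),
                               ca, sep = "\t", quote = FALSE, row.names = FALSE)
            zp <- file.path(outdir, "cluster_z.tsv")
            utils::write.table(dz$Z, zp, sep = "\t", quote = FALSE)
            record("go_cluster", length(genes), cl@k, c(ca, zp),
                   list(ratio_p = rt$p, n_between = rt$nBetween,
                        n_within = rt$nWithin))
        }
    })

    ## 5. TF activation ---------------------------------------------------
    stage("tf", {
        if (is.null(config$tf_table)) {
            message("skipping TF activation: no TF table supplied")
        } else if (nrow(edgeTable(nets$dcen)) == 0) {
            message("skipping TF activation: empty DCEN")
        } else {
            tft <- readTfTable(config$tf_table)
            res <- tfActivation(nets$dcen, tft, nPerm = params$n_perm,
                                seed = stageSeed(seed, "tf"),
                                minPool = params$tf_min_pool,
                                alpha = params$tf_alpha)
            tp <- file.path(outdir, "tf_activation.tsv")
            utils::write.table(as.data.frame(res), tp, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            record("tf", length(tft@targets), sum(res$activated), tp)
        }
    })

    ## optional reference-overlap check -----------------------------------
    if (!is.null(config$reference_edges)) {
        ref <- utils::read.delim(config$reference_edges,
                                 stringsAsFactors = FALSE)
        ov <- edgeOverlap(nets$dcen, ref)
        manifest$reference_overlap <- ov$n
    }

    manifest$total_seconds <- as.numeric(Sys.time() - t0all, units = "secs")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
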
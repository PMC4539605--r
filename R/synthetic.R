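#' @include methods.R
NULL

#' Describe one planted coexpression module
#'
#' Three constructions are supported. A module coexpressed in both
#' conditions with `flip = "none"` plants constitutive links (CCELs). A
#' module coexpressed in both conditions with `flip = "a"` or `"b"`
#' follows the sign-flipped latent for half its genes in exactly that
#' condition: pairs across the two halves are strongly differential
#' (correlation jumps between +r and -r; positive links for `"a"`,
#' negative for `"b"`), while pairs within a half stay constitutive --
#' the sign-rewiring construction. A module coexpressed in one condition
#' only plants links that *lose* coexpression (r -> ~0); these have
#' intrinsically limited detectability at a handful of timepoints (see
#' the vignette's power discussion).
#'
#' @param genes character vector of member gene ids.
#' @param coexA,coexB is the module coexpressed (sharing a latent time
#'   course) in condition a / b?
#' @param flip `"none"`, `"a"` or `"b"`: condition in which half the
#'   genes follow the sign-flipped latent (requires coexpression in that
#'   condition).
#' @return list describing the module.
#' @export
syntheticModule <- function(genes, coexA = TRUE, coexB = TRUE,
                            flip = c("none", "a", "b")) {
    flip <- match.arg(flip)
    list(genes = as.character(genes), coexA = isTRUE(coexA),
         coexB = isTRUE(coexB), flip = flip)
}

#' Specification for a synthetic two-condition time course
#'
#' Defaults are the package's standard benchmark conditions: 200 genes, 14
#' timepoints per condition, latent amplitude 5 against unit noise, four
#' 12-gene sign-rewired modules planting 144 differential links (72
#' positive, 72 negative), one 10-gene constitutive module, and 142
#' background noise genes. Each module gets its own sinusoid frequency so
#' genes of different modules are uncorrelated in both conditions.
#'
#' @param nGenes total genes (module genes plus background noise genes).
#' @param nTimesA,nTimesB timepoints per condition (at least 8 each, so
#'   rank correlations have resolution).
#' @param modules list of [syntheticModule()] descriptions with disjoint
#'   gene sets; `NULL` for the default four-module layout.
#' @param latentAmplitude amplitude of the shared sinusoidal latent signal.
#' @param noiseSd standard deviation of the iid Gaussian per-gene noise
#'   (must be positive).
#' @param seed integer RNG seed.
#' @return validated spec list, input to [generateExpressionPair()].
#' @export
syntheticSpec <- function(nGenes = 200, nTimesA = 14, nTimesB = 14,
                          modules = NULL, latentAmplitude = 5, noiseSd = 1,
                          seed = 1L) {
    if (is.null(modules)) {
        g <- function(i) sprintf("g%03d", i)
        modules <- list(
            syntheticModule(g(1:12), flip = "b"),
            syntheticModule(g(13:24), flip = "b"),
            syntheticModule(g(25:36), flip = "a"),
            syntheticModule(g(37:48), flip = "a"),
            syntheticModule(g(49:58), flip = "none"))
    }
    for (m in modules) {
        if (m$flip == "a" && !m$coexA)
            stop("flip = 'a' requires coexpression in condition a")
        if (m$flip == "b" && !m$coexB)
            stop("flip = 'b' requires coexpression in condition b")
    }
    allg <- unlist(lapply(modules, `[[`, "genes"))
    if (anyDuplicated(allg)) stop("module gene sets must be disjoint")
    if (length(allg) > nGenes) stop("modules exceed nGenes")
    if (nTimesA < 8 || nTimesB < 8) stop("need at least 8 timepoints per condition")
    if (noiseSd <= 0) stop("noiseSd must be positive")
    list(nGenes = nGenes, nTimesA = nTimesA, nTimesB = nTimesB,
         modules = modules, latentAmplitude = latentAmplitude,
         noiseSd = noiseSd, seed = as.integer(seed))
}

# per-gene latent sign factors for one module in one condition
.moduleFactors <- function(mod, condition) {
    f <- rep(1, length(mod$genes))
    if (mod$flip == condition) {
        half <- seq_len(floor(length(mod$genes) / 2))
        f[-half] <- -1
    }
    f
}

#' Generate a planted two-condition expression pair
#'
#' Genes belonging to a module coexpressed in a condition follow that
#' module's sinusoidal latent time course (one frequency per module, so
#' distinct modules are uncorrelated; phases randomly jittered, mimicking
#' cell-cycle-like periodicity) plus iid Gaussian noise; everywhere else
#' genes are independent noise. The returned truth enumerates the planted
#' differential (DCEL) and constitutive (CCEL) pairs implied by the
#' construction.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `expr` (a [TimecourseExperiment-class] with conditions
#'   `"a"` and `"b"`) and `truth` (planted DCELs with sign, planted CCELs,
#'   module layout, background genes).
#' @export
generateExpressionPair <- function(spec) {
    set.seed(spec$seed)
    genes <- sprintf("g%03d", seq_len(spec$nGenes))
    mgenes <- unlist(lapply(spec$modules, `[[`, "genes"))
    stopifnot(all(mgenes %in% genes))
    nM <- length(spec$modules)
    phase <- if (nM) stats::runif(nM, 0, 2 * pi) else numeric()
    freq <- seq_len(nM)                 # one frequency per module
    tA <- seq_len(spec$nTimesA); tB <- seq_len(spec$nTimesB)
    latent <- function(tt, f, ph) sin(2 * pi * f * tt / length(tt) + ph)

    mk <- function(tt, condition) {
        m <- matrix(stats::rnorm(spec$nGenes * length(tt), sd = spec$noiseSd),
                    nrow = spec$nGenes, dimnames = list(genes, NULL))
        for (i in seq_len(nM)) {
            mod <- spec$modules[[i]]
            coex <- if (condition == "a") mod$coexA else mod$coexB
            if (!coex) next
            f <- .moduleFactors(mod, condition)
            sig <- spec$latentAmplitude * latent(tt, freq[i], phase[i])
            m[mod$genes, ] <- m[mod$genes, ] + outer(f, sig)
        }
        m
    }
    mA <- mk(tA, "a"); mB <- mk(tB, "b")
    colnames(mA) <- paste0("a_t", tA); colnames(mB) <- paste0("b_t", tB)
    expr <- TimecourseExperiment(cbind(mA, mB),
                                 condition = rep(c("a", "b"),
                                                 c(length(tA), length(tB))),
                                 time = c(tA, tB) * 10)

    dcel <- list(); ccel <- list()
    for (i in seq_len(nM)) {
        mod <- spec$modules[[i]]
        fA <- .moduleFactors(mod, "a"); fB <- .moduleFactors(mod, "b")
        ng <- length(mod$genes)
        for (p in seq_len(ng - 1)) for (q in (p + 1):ng) {
            rA <- if (mod$coexA) fA[p] * fA[q] else 0
            rB <- if (mod$coexB) fB[p] * fB[q] else 0
            key <- c(u = mod$genes[p], v = mod$genes[q])
            if (rA == 1 && rB == 1) {
                ccel[[length(ccel) + 1L]] <- key
            } else if (rA != rB) {
                dcel[[length(dcel) + 1L]] <-
                    c(key, sign = if (rB > rA) 1L else -1L)
            }
        }
    }
    asDf <- function(l, cols) {
        if (!length(l)) {
            out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
        } else {
            out <- as.data.frame(do.call(rbind, l), stringsAsFactors = FALSE)
        }
        if ("sign" %in% colnames(out)) out$sign <- as.integer(out$sign)
        out
    }
    truth <- list(
        plantedDcels = asDf(dcel, c("u", "v", "sign")),
        plantedCcels = asDf(ccel, c("u", "v")),
        modules = spec$modules,
        backgroundGenes = setdiff(genes, mgenes),
        spec = spec)
    list(expr = expr, truth = truth)
}

#' Generate a phase-continuum expression pair with rewired "mover" genes
#'
#' Topology benchmark variant of the generator: every gene follows one
#' sinusoidal latent with its own phase drawn uniformly on the circle, so
#' the population forms a coexpression continuum (correlation between two
#' genes ~ cosine of their phase difference) rather than discrete blocks
#' -- the geometric, sign-transitive structure real coexpression networks
#' have. A chosen set of "mover" genes is rewired in condition b: their
#' phase jumps by pi, flipping the sign of their correlation with every
#' other gene. The resulting true differential links form bipartite stars
#' around the movers (a tree-like, triangle-free differential network),
#' while chance differential networks from condition-shuffled data are
#' angular-band graphs rich in triads.
#'
#' @param nGenes total genes (default 100).
#' @param nTimesA,nTimesB timepoints per condition.
#' @param nMovers number of rewired genes (default 8).
#' @param latentAmplitude,noiseSd signal amplitude and noise SD (defaults
#'   5 and 1, the standard benchmark ratio).
#' @param seed integer RNG seed.
#' @return list with `expr` (a [TimecourseExperiment-class]) and `truth`
#'   (`movers`, per-gene `phase`, and `strongDcels`: mover/non-mover pairs
#'   with |cos(phase difference)| >= 0.6, whose correlation flips by at
#'   least 1.2).
#' @export
generateRotationalPair <- function(nGenes = 100, nTimesA = 14, nTimesB = 14,
                                   nMovers = 8, latentAmplitude = 5,
                                   noiseSd = 1, seed = 1L) {
    stopifnot(nMovers < nGenes, nTimesA >= 8, nTimesB >= 8, noiseSd > 0)
    set.seed(seed)
    genes <- sprintf("g%03d", seq_len(nGenes))
    phase <- stats::runif(nGenes, 0, 2 * pi)
    names(phase) <- genes
    movers <- sample(genes, nMovers)
    shift <- ifelse(genes %in% movers, pi, 0)
    mk <- function(tt, shifted) {
        ph <- phase + if (shifted) shift else 0
        sig <- latentAmplitude *
            sin(outer(ph, 2 * pi * tt / length(tt), `+`))
        sig + matrix(stats::rnorm(nGenes * length(tt), sd = noiseSd),
                     nrow = nGenes)
    }
    tA <- seq_len(nTimesA); tB <- seq_len(nTimesB)
    mA <- mk(tA, FALSE); mB <- mk(tB, TRUE)
    rownames(mA) <- rownames(mB) <- genes
    colnames(mA) <- paste0("a_t", tA); colnames(mB) <- paste0("b_t", tB)
    expr <- TimecourseExperiment(cbind(mA, mB),
                                 condition = rep(c("a", "b"),
                                                 c(nTimesA, nTimesB)),
                                 time = c(tA, tB) * 10)
    nonmov <- setdiff(genes, movers)
    sd_list <- list()
    for (m in movers) for (g in nonmov) {
        cw <- cos(phase[[m]] - phase[[g]])
        if (abs(cw) >= 0.6)
            sd_list[[length(sd_list) + 1L]] <-
                data.frame(u = min(m, g), v = max(m, g),
                           sign = if (cw > 0) -1L else 1L)
    }
    strong <- if (length(sd_list)) do.call(rbind, sd_list)
              else data.frame(u = character(), v = character(),
                              sign = integer())
    list(expr = expr,
         truth = list(movers = movers, phase = phase, strongDcels = strong))
}

#' Generate a toy rooted ontology with gene annotations
#'
#' Builds a small DAG in a biological_process-like namespace: term 1 is the
#' root, every later term draws one or two is_a parents among the earlier
#' terms. Each gene is annotated to one to three of the deepest terms;
#' annotations propagate to ancestors for information-content computation. A
#' fraction of the annotation rows is tagged with the excluded evidence
#' codes (IEP/IGI) to exercise evidence filtering.
#'
#' @param nTerms number of terms (at least 3).
#' @param nGenes number of genes to annotate.
#' @param seed integer RNG seed.
#' @param excludedFrac fraction of annotation rows tagged IEP or IGI.
#' @return list with `dag` (an [OntologyDAG-class]) and `annotations`
#'   (data.frame gene, term, evidence).
#' @export
generateToyOntology <- function(nTerms = 15, nGenes = 60, seed = 1L,
                                excludedFrac = 0.15) {
    stopifnot(nTerms >= 3)
    set.seed(seed)
    ids <- sprintf("TOY:%04d", seq_len(nTerms))
    parents <- vector("list", nTerms); names(parents) <- ids
    parents[[1]] <- character()
    for (i in 2:nTerms) {
        np <- if (i > 3 && stats::runif(1) < 0.3) 2L else 1L
        parents[[i]] <- sample(ids[seq_len(i - 1)], min(np, i - 1))
    }
    terms <- data.frame(id = ids,
                        name = paste("toy process", seq_len(nTerms)),
                        namespace = "biological_process",
                        stringsAsFactors = FALSE)
    dag <- .buildDAG(terms, parents)
    # annotate genes to the more specific half of the terms
    isParent <- ids %in% unlist(parents)
    leafish <- ids[!isParent]
    if (length(leafish) < 2) leafish <- ids[-1]
    genes <- sprintf("g%03d", seq_len(nGenes))
    ann <- do.call(rbind, lapply(genes, function(g) {
        tt <- sample(leafish, sample(1:min(3, length(leafish)), 1))
        data.frame(gene = g, term = tt, evidence = "EXP",
                   stringsAsFactors = FALSE)
    }))
    nEx <- round(excludedFrac * nrow(ann))
    if (nEx) {
        i <- sample(nrow(ann), nEx)
        ann$evidence[i] <- sample(c("IEP", "IGI"), nEx, replace = TRUE)
    }
    list(dag = dag, annotations = ann)
}

#' Generate a TF-regulation table with one planted deactivated TF
#'
#' The designated TF's target set covers at least `coverage` of the genes
#' incident to planted differential links (so its targets lose coexpression
#' in condition b); all other TFs regulate uniformly random gene sets of
#' comparable size.
#'
#' @param nTfs number of TFs (the first, `TF001`, is the designated one).
#' @param truth the `truth` component of [generateExpressionPair()].
#' @param seed integer RNG seed.
#' @param coverage fraction of planted-DCEL endpoint genes the designated
#'   TF must target (default 0.9).
#' @return list with `table` (a [TFRegulationTable-class]), `deactivatedTF`
#'   (its id) and `universe`.
#' @export
generateTFTable <- function(nTfs = 20, truth, seed = 1L, coverage = 0.9) {
    set.seed(seed)
    universe <- sprintf("g%03d", seq_len(truth$spec$nGenes))
    endpoints <- unique(c(truth$plantedDcels$u, truth$plantedDcels$v))
    tfs <- sprintf("TF%03d", seq_len(nTfs))
    nCov <- ceiling(coverage * length(endpoints))
    t1 <- unique(c(sample(endpoints, nCov),
                   sample(universe, max(5, round(0.05 * length(universe))))))
    sizes <- pmax(5L, stats::rpois(nTfs - 1, lambda = max(10, length(t1))))
    rows <- rbind(
        data.frame(tf = tfs[1], target = t1, stringsAsFactors = FALSE),
        do.call(rbind, lapply(seq_len(nTfs - 1), function(i) {
            data.frame(tf = tfs[i + 1],
                       target = sample(universe, min(sizes[i], length(universe))),
                       stringsAsFactors = FALSE)
        })))
    list(table = TFRegulationTable(rows, universe = universe),
         deactivatedTF = tfs[1], universe = universe)
}

#' Write a complete synthetic analysis bundle to disk
#'
#' Emits the same plain-text formats the real pipeline reads: an expression
#' TSV with a sample-map sidecar, an OBO 1.2 ontology, a three-column
#' annotation TSV, a two-column TF-target TSV, a JSON truth file, and a YAML
#' pipeline configuration pointing at them all.
#'
#' @param dir output directory (created if absent).
#' @param spec a [syntheticSpec()]; the default benchmark layout if `NULL`.
#' @param seed master seed (stage seeds derived via [stageSeed()]).
#' @param nTfs,nTerms sizes of the TF table and toy ontology.
#' @return path of the written YAML config, invisibly.
#' @export
writeSyntheticBundle <- function(dir, spec = NULL, seed = 1L, nTfs = 10,
                                 nTerms = 15) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(spec))
        spec <- syntheticSpec(nGenes = 60, seed = stageSeed(seed, "expression"),
                              modules = list(
                                  syntheticModule(sprintf("g%03d", 1:8), flip = "b"),
                                  syntheticModule(sprintf("g%03d", 9:16), flip = "a"),
                                  syntheticModule(sprintf("g%03d", 17:24), flip = "none")))
    gp <- generateExpressionPair(spec)
    m <- assay(gp$expr)
    exprPath <- file.path(dir, "expression.tsv")
    utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                       exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
    mapPath <- file.path(dir, "sample_map.tsv")
    utils::write.table(data.frame(sample = colnames(m),
                                  condition = sampleCondition(gp$expr),
                                  time = sampleTime(gp$expr)),
                       mapPath, sep = "\t", quote = FALSE, row.names = FALSE)
    toy <- generateToyOntology(nTerms = nTerms, nGenes = spec$nGenes,
                               seed = stageSeed(seed, "ontology"))
    oboPath <- file.path(dir, "toy.obo")
    writeObo(toy$dag, oboPath)
    annPath <- file.path(dir, "annotations.tsv")
    utils::write.table(toy$annotations, annPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tft <- generateTFTable(nTfs = nTfs, truth = gp$truth,
                           seed = stageSeed(seed, "tf"))
    tfPath <- file.path(dir, "tf_table.tsv")
    tfdf <- do.call(rbind, lapply(names(tft$table@targets), function(tf)
        data.frame(tf = tf, target = tft$table@targets[[tf]])))
    utils::write.table(tfdf, tfPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truthPath <- file.path(dir, "truth.json")
    jsonlite::write_json(list(plantedDcels = gp$truth$plantedDcels,
                              plantedCcels = gp$truth$plantedCcels,
                              backgroundGenes = gp$truth$backgroundGenes,
                              deactivatedTF = tft$deactivatedTF),
                         truthPath, auto_unbox = TRUE, digits = NA)
    cfg <- list(expression = exprPath, sample_map = mapPath, obo = oboPath,
                go_annotations = annPath, tf_table = tfPath,
                outdir = file.path(dir, "out"), seed = as.integer(seed),
                params = list(n_perm = 500, n_clusters = 3))
    cfgPath <- file.path(dir, "config.yaml")
    yaml::write_yaml(cfg, cfgPath)
    invisible(cfgPath)
}
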
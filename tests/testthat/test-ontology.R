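test_that("the OBO parser keeps one namespace and rejects malformed input", {
    path <- tempfile(fileext = ".obo")
    writeLines(c(
        "format-version: 1.2", "",
        "[Term]", "id: T:1", "name: root", "namespace: biological_process", "",
        "[Term]", "id: T:2", "name: kid", "namespace: biological_process",
        "is_a: T:1 ! root", "",
        "[Term]", "id: T:3", "name: other", "namespace: molecular_function", "",
        "[Term]", "id: T:4", "name: dead", "namespace: biological_process",
        "is_obsolete: true", ""), path)
    dag <- loadObo(path)
    expect_setequal(termIds(dag), c("T:1", "T:2"))    # MF + obsolete dropped
    expect_equal(dag@root, "T:1")
    expect_equal(ancestorsOf(dag, "T:2"), c("T:2", "T:1"))

    bad <- tempfile(fileext = ".obo")
    writeLines(c("[Term]", "name: no id here",
                 "namespace: biological_process"), bad)
    expect_error(loadObo(bad), "line 1")

    cyc <- tempfile(fileext = ".obo")
    writeLines(c("[Term]", "id: T:1", "name: a",
                 "namespace: biological_process", "is_a: T:2", "",
                 "[Term]", "id: T:2", "name: b",
                 "namespace: biological_process", "is_a: T:1", ""), cyc)
    expect_error(loadObo(cyc), "cycle")
})

test_that("a generated ontology round-trips through OBO", {
    toy <- generateToyOntology(nTerms = 10, nGenes = 15, seed = 1)
    path <- tempfile(fileext = ".obo")
    writeObo(toy$dag, path)
    back <- loadObo(path)
    expect_identical(termIds(back), termIds(toy$dag))
    expect_identical(lapply(back@parents, sort), lapply(toy$dag@parents, sort))
})

test_that("evidence filtering drops IEP/IGI and never adds annotations", {
    ann <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                      term = c("T:1", "T:2", "T:1", "T:2"),
                      evidence = c("IEP", "EXP", "IGI", "IDA"))
    expect_message(out <- filterAnnotations(ann), "without annotations")
    expect_setequal(out$gene, c("g1", "g3"))
    expect_false(any(out$evidence %in% c("IEP", "IGI")))
    # empty exclusion set is the identity
    expect_identical(filterAnnotations(ann, character()), ann)
    # monotone: per-gene annotation counts never increase
    tb0 <- table(ann$gene); tb1 <- table(out$gene)
    expect_true(all(tb1 <= tb0[names(tb1)]))
})

test_that("annotation frequencies propagate along the chain", {
    ch <- chainOntology()
    expect_equal(unname(ch$ic["T:0001"]), 1)     # root
    expect_equal(unname(ch$ic["T:0002"]), 0.5)
    expect_equal(unname(ch$ic["T:0003"]), 0.25)
    # adding an annotation never decreases an ancestor's frequency
    more <- rbind(ch$ann, data.frame(gene = "g5", term = "T:0003",
                                     evidence = "EXP"))
    ic2 <- informationContent(ch$dag, more)
    # the new gene raises the denominator but every ancestor gains it too
    expect_equal(unname(ic2["T:0001"]), 1)
    expect_gte(ic2[["T:0003"]], 1 / 5)
})

test_that("Schlicker similarity reproduces the hand-computed chain values", {
    ch <- chainOntology()
    # self-similarity of the leaf: Lin factor 1, specificity 1 - 0.25
    expect_equal(simRel("T:0003", "T:0003", ch$ic, ch$dag), 0.75)
    # leaf vs middle through their MICA (the middle term)
    expect_equal(simRel("T:0002", "T:0003", ch$ic, ch$dag),
                 (2 * log(0.5)) / (log(0.5) + log(0.25)) * (1 - 0.5))
    expect_equal(simRel("T:0002", "T:0003", ch$ic, ch$dag), 1 / 3)
    # sharing only the root gives zero
    expect_equal(simRel("T:0001", "T:0001", ch$ic, ch$dag), 0)
    expect_equal(simRel("T:0002", "T:0003", ch$ic, ch$dag),
                 simRel("T:0003", "T:0002", ch$ic, ch$dag))
})

test_that("funSim is the best-match average and lives in [0, 1]", {
    ch <- chainOntology()
    ann <- rbind(ch$ann,
                 data.frame(gene = c("gX", "gY"), term = "T:0003",
                            evidence = "EXP"))
    ic <- informationContent(ch$dag, ch$ann)  # frequencies from the corpus
    expect_equal(funSim("gX", "gY", ann, ic, ch$dag), 0.75)
    expect_equal(funSim("gX", "gY", ann, ic, ch$dag),
                 funSim("gY", "gX", ann, ic, ch$dag))
    expect_error(funSim("gX", "nope", ann, ic, ch$dag), "no usable annotations")

    # property: random toy DAGs keep both similarities in [0, 1]
    for (s in 1:3) {
        toy <- generateToyOntology(nTerms = 10, nGenes = 20, seed = s)
        ann2 <- filterAnnotations(toy$annotations)
        ic2 <- informationContent(toy$dag, ann2)
        genes <- unique(ann2$gene)[1:6]
        sim <- similarityMatrix(genes, ann2, ic2, toy$dag)
        expect_true(all(sim >= 0 & sim <= 1))
        expect_equal(sim, t(sim))
        # entries reproduce pairwise funSim calls
        expect_equal(sim[1, 2],
                     funSim(genes[1], genes[2], ann2, ic2, toy$dag))
    }
    expect_error(similarityMatrix(c("g1", "g1"), ch$ann, ch$ic, ch$dag),
                 "duplicate")
})

test_that("hypergeometric enrichment matches exhaustive tail enumeration", {
    ch <- chainOntology()
    # N=10, M=5, n=2, k=2 -> C(5,2)/C(10,2)
    expect_equal(stats::phyper(1, 5, 5, 2, lower.tail = FALSE), 10 / 45)
    set.seed(1)
    for (i in 1:10) {
        N <- sample(5:12, 1); M <- sample(1:N, 1)
        n <- sample(1:N, 1); k <- sample(0:min(n, M), 1)
        expect_equal(stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE),
                     bruteHyperTail(N, M, n, k))
    }
    ref <- paste0("g", 1:4)
    res <- hypergeomEnrich(c("g3", "g4"), ref, ch$dag, ch$ann)
    # both test genes reach the root; only g4 reaches the leaf
    expect_equal(res$p[res$term == "T:0001"], 1)
    expect_equal(res$p[res$term == "T:0003"], 1 / 2)   # P(g4 in a draw of 2)
    expect_true(all(res$q >= res$p))
    expect_error(hypergeomEnrich(character(), ref, ch$dag, ch$ann), "empty")
    expect_error(hypergeomEnrich("zz", ref, ch$dag, ch$ann), "subset")
})
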
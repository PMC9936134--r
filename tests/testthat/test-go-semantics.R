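test_that("OBO parsing handles the toy ontology, obsoletes and part_of", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeToyObo(f)
  dag <- loadObo(f)
  expect_s4_class(dag, "GoDag")
  expect_identical(nTerms(dag), 5L)                     # obsolete excluded
  expect_identical(sum(lengths(dag@parents)), 4L)       # is_a edges only
  expect_identical(dagRoots(dag), "GO:0000001")
  # part_of honored only on request
  dagP <- loadObo(f, includePartOf = TRUE)
  expect_identical(sort(dagP@parents[["GO:0000004"]]),
                   c("GO:0000002", "GO:0000003"))
  # ancestor closure includes self and reaches the root
  expect_setequal(dag@ancestors[["GO:0000004"]],
                  c("GO:0000004", "GO:0000002", "GO:0000001"))
})

test_that("OBO parsing rejects cycles and unknown parents", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "namespace: biological_process",
               "is_a: GO:2", "",
               "[Term]", "id: GO:2", "namespace: biological_process",
               "is_a: GO:1", ""), f)
  expect_error(loadObo(f), "cycle")
  writeLines(c("[Term]", "id: GO:1", "namespace: biological_process",
               "is_a: GO:9", ""), f)
  expect_error(loadObo(f), "GO:9")
})

test_that("OBO round-trips through writeObo", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeToyObo(f)
  dag <- loadObo(f)
  f2 <- withr::local_tempfile(fileext = ".obo")
  writeObo(dag, f2)
  dag2 <- loadObo(f2)
  expect_identical(dag2@terms, dag@terms)
  expect_identical(dag2@parents, dag@parents)
})

test_that("annotation merging de-duplicates and propagates to ancestors", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeToyObo(f)
  dag <- loadObo(f)
  ann1 <- data.frame(gene = c("gA", "gB"), term = c("GO:0000004", "GO:0000005"))
  ann2 <- data.frame(gene = c("gA", "gC", "gD"),
                     term = c("GO:0000004", "GO:0000002", "GO:0000003"))
  corpus <- annotationCorpus(list(ann1, ann2), dag)
  expect_identical(corpus@totalGenes, 4L)
  # gA annotated once despite appearing in both files
  expect_identical(corpus@termCounts[["GO:0000004"]], 1L)
  # leaf annotation counts at every ancestor
  expect_identical(corpus@termCounts[["GO:0000002"]], 2L)  # gA via 4, gC direct
  expect_identical(corpus@termCounts[["GO:0000001"]], 4L)  # root sees everyone
  expect_equal(termProb("GO:0000001", corpus), 1)
  # monotone along edges
  for (t in dag@terms) {
    if (!t %in% names(corpus@termCounts)) next
    for (p in dag@parents[[t]])
      expect_gte(corpus@termCounts[[p]], corpus@termCounts[[t]])
  }
  # brute-force count check over explicit closures
  g2t <- list(gA = "GO:0000004", gB = "GO:0000005",
              gC = "GO:0000002", gD = "GO:0000003")
  for (t in names(corpus@termCounts)) {
    cnt <- sum(vapply(g2t, function(ts) {
      any(vapply(ts, function(x) t %in% bruteAncestors(x, dag@parents),
                 logical(1)))
    }, logical(1)))
    expect_identical(corpus@termCounts[[t]], cnt)
  }
  expect_warning(annotationCorpus(data.frame(gene = c("gA", "gE"),
                                             term = c("GO:0000004", "GO:9999999")),
                                  dag),
                 "dropped")
})

test_that("Lin similarity matches hand values on the canonical toy DAG", {
  # root(p=1) -> A(p=0.5) -> {B(p=0.25), C(p=0.25)}
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: R", "namespace: biological_process", "",
               "[Term]", "id: A", "namespace: biological_process", "is_a: R", "",
               "[Term]", "id: B", "namespace: biological_process", "is_a: A", "",
               "[Term]", "id: C", "namespace: biological_process", "is_a: A", "",
               "[Term]", "id: D", "namespace: biological_process", "is_a: R", ""), f)
  dag <- loadObo(f)
  ann <- data.frame(gene = paste0("g", 1:4),
                    term = c("B", "C", "A", "D"))
  corpus <- annotationCorpus(ann, dag)
  expect_equal(termProb("A", corpus), 0.75)
  # rescale to the worked probabilities: use 4 genes st p(A)=0.5
  ann2 <- data.frame(gene = paste0("g", 1:4), term = c("B", "C", "D", "D"))
  corpus2 <- annotationCorpus(ann2, dag)
  expect_equal(termProb("A", corpus2), 0.5)
  expect_equal(termProb("B", corpus2), 0.25)
  expect_equal(linSimilarity("B", "C", dag, corpus2),
               2 * log(0.5) / (log(0.25) + log(0.25)))  # = 0.5
  expect_equal(linSimilarity("B", "B", dag, corpus2), 1)
  # only shared ancestor is the root (p = 1): similarity 0
  expect_equal(linSimilarity("B", "D", dag, corpus2), 0)
  # the literal printed form always picks the root and is identically 0
  expect_equal(linSimilarity("B", "C", dag, corpus2, literal = TRUE), 0)
  expect_error(linSimilarity("B", "Z", dag, corpus2))
})

test_that("Lin similarity matches exhaustive search on random DAGs", {
  set.seed(77)
  for (rep in 1:20) {
    nT <- sample(8:30, 1)
    toy <- randomToyDag(nT)
    # random annotations: 10 genes, 1-3 random terms each
    g2t <- lapply(1:10, function(g) {
      toy$ids[sample.int(nT, sample(1:3, 1))]
    })
    names(g2t) <- paste0("g", 1:10)
    ann <- data.frame(gene = rep(names(g2t), lengths(g2t)),
                      term = unlist(g2t, use.names = FALSE))
    f <- withr::local_tempfile(fileext = ".obo")
    stanzas <- unlist(lapply(toy$ids, function(t) {
      c("[Term]", paste0("id: ", t), "namespace: biological_process",
        paste0("is_a: ", toy$parents[[t]], recycle0 = TRUE), "")
    }))
    writeLines(stanzas, f)
    dag <- loadObo(f)
    corpus <- annotationCorpus(ann, dag)
    annotated <- names(corpus@termCounts)
    pairIds <- sample(annotated, min(6, length(annotated)))
    for (t1 in pairIds) for (t2 in pairIds) {
      got <- linSimilarity(t1, t2, dag, corpus)
      expect_gte(got, 0); expect_lte(got, 1)
      expect_equal(got, linSimilarity(t2, t1, dag, corpus))
      expect_equal(got, bruteLin(t1, t2, toy$parents, g2t), tolerance = 1e-12)
    }
  }
})

test_that("the MICA choice dominates every other common ancestor", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeToyObo(f)
  dag <- loadObo(f)
  set.seed(3)
  ann <- data.frame(gene = paste0("g", 1:6),
                    term = c("GO:0000004", "GO:0000005", "GO:0000002",
                             "GO:0000003", "GO:0000004", "GO:0000005"))
  corpus <- annotationCorpus(ann, dag)
  for (t1 in dag@terms) for (t2 in dag@terms) {
    common <- intersect(dag@ancestors[[t1]], dag@ancestors[[t2]])
    got <- linSimilarity(t1, t2, dag, corpus)
    den <- log(termProb(t1, corpus)) + log(termProb(t2, corpus))
    if (den == 0 || t1 == t2) next
    for (anc in common) {
      alt <- 2 * log(termProb(anc, corpus)) / den
      expect_gte(got + 1e-12, min(1, max(0, alt)))
    }
  }
})

test_that("GAF tables are read with aspect filtering", {
  f <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2",
               paste("DB", "GENE1", "GENE1sym", "", "GO:0000004", "REF",
                     "IEA", "", "P", sep = "\t"),
               paste("DB", "GENE2", "GENE2sym", "", "GO:0000005", "REF",
                     "IEA", "", "F", sep = "\t")), f)
  got <- readGaf(f, aspect = "P")
  expect_identical(got$gene, "GENE1")
  expect_identical(got$term, "GO:0000004")
  expect_identical(nrow(readGaf(f, aspect = NULL)), 2L)
})
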
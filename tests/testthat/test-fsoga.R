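test_that("the box-plot membership threshold follows type-7 quartiles", {
  expect_equal(membershipThreshold(c(1, 2, 3, 4, 5)), 4 + 1.5 * 2)  # Q1=2, Q3=4
  expect_equal(membershipThreshold(rep(0.3, 6)), 0.3)               # zero IQR
  expect_equal(membershipThreshold(0.7), 0.7)                       # single point
})

test_that("potential-module lists follow the threshold rule on a hand example", {
  # 3 modules; gene 7 sits close to medoids 1 and 2
  x <- rbind(
    g1 = c(1, 2, 3, 4, 5, 6), g2 = c(1.1, 2, 3, 4, 5, 6.2),
    g3 = c(1, 2.1, 3.1, 4, 5, 6),
    g4 = c(6, 5, 4, 3, 2, 1), g5 = c(6.1, 5, 4, 3, 2.2, 1),
    g6 = c(6, 5.2, 4, 3.1, 2, 1),
    g7 = c(1, 2, 3.5, 3.9, 5.2, 6),
    g8 = c(3, 1, 4, 1, 5, 9), g9 = c(3.2, 1, 4.1, 1, 5, 8.8))
  D <- distanceMatrix(x)
  medoids <- c(1L, 4L, 8L)
  labels <- assignToMedoids(D, medoids)
  pot <- buildPotentialModules(D, medoids, labels)
  th <- attr(pot, "thresholds")
  # oracle: recompute the rule by hand for every gene/module
  for (i in seq_len(nrow(x))) {
    want <- union(which(D[i, medoids] < th), labels[i])
    want <- want[order(D[i, medoids][want])]
    expect_identical(pot[[i]], want)
    expect_true(labels[i] %in% pot[[i]])
  }
  # a medoid gene always lists its own module (self-distance 0)
  for (j in 1:3) expect_true(j %in% pot[[medoids[j]]])
})

test_that("membership initialization obeys the overlap rule", {
  pot <- list(g1 = 1:3, g2 = 2L, g3 = c(1L, 3L))
  seedM <- matrix(c(1L, 0L, 0L,
                    0L, 1L, 0L,
                    0L, 0L, 1L), 3, 3, byrow = TRUE,
                  dimnames = list(names(pot), NULL))
  D <- matrix(0.5, 3, 3); diag(D) <- 0
  medoids <- 1:3

  set.seed(1)
  pop0 <- fsogaInit(pot, over = 0, P = 50, seedM, D, medoids)
  expect_length(pop0, 50)
  expect_true(any(vapply(pop0, identical, logical(1), seedM)))
  # over = 0: hard partitions (ignoring forced repairs of empty modules)
  rs <- vapply(pop0, function(A) max(rowSums(A)), numeric(1))
  expect_true(all(rs >= 1))

  # over = 1, M = 3: row sums uniform over {1,2,3}
  set.seed(2)
  draws <- replicate(10000, {
    A <- matrix(0L, 3, 3, dimnames = dimnames(seedM))
    A[1, moduleGA:::.drawRow(1:3, over = 1)] <- 1L
    sum(A[1, ])
  })
  freq <- table(factor(draws, levels = 1:3)) / 10000
  expect_true(all(abs(freq - 1 / 3) < 0.02))

  # M = 1 gene always gets its single module
  expect_true(all(vapply(pop0, function(A) A[2, 2] == 1L, logical(1))))
})

test_that("membership crossover is a row cut of the two parents", {
  pot <- list(g1 = 1:2, g2 = 1:2, g3 = 1:2, g4 = 1:2)
  # both parents keep every module non-empty, so no repair can kick in
  A1 <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L), 4, 2, byrow = TRUE,
               dimnames = list(names(pot), NULL))
  A2 <- matrix(c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L), 4, 2, byrow = TRUE,
               dimnames = list(names(pot), NULL))
  D <- matrix(0.5, 4, 4); diag(D) <- 0
  medoids <- c(1L, 2L)
  expect_identical(fsogaCrossover(A1, A1, pot, D, medoids), A1)
  set.seed(3)
  for (r in 1:50) {
    child <- fsogaCrossover(A1, A2, pot, D, medoids)
    rowsOk <- vapply(1:4, function(i) {
      identical(child[i, ], A1[i, ]) || identical(child[i, ], A2[i, ])
    }, logical(1))
    expect_true(all(colSums(child) >= 1))
    expect_true(all(rowSums(child) >= 1))
    expect_true(all(rowsOk))
    # a prefix comes from A1 and the suffix from A2
    fromA1 <- vapply(1:4, function(i) identical(child[i, ], A1[i, ]), logical(1))
    expect_false(is.unsorted(rev(fromA1)))
  }
})

test_that("membership mutation redraws rows within the potential lists", {
  pot <- list(g1 = 1:3, g2 = c(1L, 2L), g3 = 2:3, g4 = 3L)
  A <- matrix(0L, 4, 3, dimnames = list(names(pot), NULL))
  A[cbind(1:4, c(1L, 2L, 3L, 3L))] <- 1L
  D <- matrix(0.5, 4, 4); diag(D) <- 0
  medoids <- c(1L, 2L, 4L)
  expect_identical(fsogaMutate(A, mu = 0, pot, over = 1, D, medoids), A)
  set.seed(4)
  ok <- TRUE
  for (r in 1:1000) {
    M <- fsogaMutate(A, mu = 1, pot, over = 1, D, medoids)
    for (i in 1:4) {
      picked <- which(M[i, ] == 1L)
      ok <- ok && length(picked) >= 1 && length(picked) <= length(pot[[i]]) &&
        all(picked %in% pot[[i]])
    }
    ok <- ok && all(colSums(M) >= 1)
  }
  expect_true(ok)
})

test_that("fitness aggregation reproduces the worked micro-examples exactly", {
  # one module, two terms with pairwise similarity 0.6
  one <- aggregateTarget(list(data.frame(term = c("A", "B"),
                                         pAdj = c(1e-5, 1e-3))),
                         k = 1, alpha = 0, pairSim = function(t1, t2) 0.6)
  expect_identical(one$sim, 0.6)
  # Sig normalized by module count k as published: (5 + 3) / 2 = 4
  two <- aggregateTarget(list(data.frame(term = c("A", "B"),
                                         pAdj = c(1e-5, 1e-3))),
                         k = 2, alpha = 0, pairSim = function(t1, t2) 0.6)
  expect_identical(two$sig, 4)
  # per-term alternative normalization
  alt <- aggregateTarget(list(data.frame(term = c("A", "B"),
                                         pAdj = c(1e-5, 1e-3))),
                         k = 2, alpha = 0, pairSim = function(t1, t2) 0.6,
                         sigNorm = "per_bp")
  expect_identical(alt$sig, 4)  # (5+3)/2 terms
  # Target = Sim * alpha + Sig with Sim 0.5, alpha 1000, Sig 30 -> 530
  t530 <- aggregateTarget(list(data.frame(term = c("A", "B"),
                                          pAdj = c(1e-15, 1e-15))),
                          k = 1, alpha = 1000, pairSim = function(t1, t2) 0.5)
  expect_identical(t530$sim, 0.5)
  expect_identical(t530$sig, 30)
  expect_identical(t530$target, 530)
  # single-term module contributes significance but no similarity
  single <- aggregateTarget(list(data.frame(term = "A", pAdj = 1e-4)),
                            k = 1, alpha = 1000, pairSim = function(t1, t2) 1)
  expect_identical(single$sim, 0)
  expect_identical(single$sig, 4)
  # no enriched terms anywhere: all components zero
  zero <- aggregateTarget(list(data.frame(term = character(),
                                          pAdj = numeric())),
                          k = 2, alpha = 1000, pairSim = function(t1, t2) 1)
  expect_identical(unlist(zero), c(target = 0, sim = 0, sig = 0))
})

test_that("fitness is label-invariant and bounded", {
  fx <- tinyStage2Fixture()
  A <- partitionToMatrix(fx$partition)
  f1 <- fsogaFitness(A, fx$toy$dag, fx$toy$corpus, alpha = 1000)
  expect_gte(f1$sim, 0); expect_lte(f1$sim, 1)
  expect_gte(f1$sig, 0)
  perm <- c(2L, 3L, 1L)
  f2 <- fsogaFitness(A[, perm], fx$toy$dag, fx$toy$corpus, alpha = 1000)
  expect_equal(f1$sim, f2$sim)
  expect_equal(f1$sig, f2$sig)
})

test_that("stage-2 GA improves on its seed and is reproducible", {
  fx <- stage2Fixture()
  res <- runFsoGa(fx$stage1$partition, fx$stage1$D, fx$toy$dag, fx$toy$corpus,
                  over = 1, alpha = 1000,
                  config = gaConfig(populationSize = 60, generations = 15,
                                    seed = 11))
  expect_gte(res$membership@target, res$seed$target)
  expect_false(is.unsorted(res$fit@trace))
  expect_true(validObject(res$membership))
  expect_gte(res$membership@sim, 0); expect_lte(res$membership@sim, 1)
  res2 <- runFsoGa(fx$stage1$partition, fx$stage1$D, fx$toy$dag, fx$toy$corpus,
                   over = 1, alpha = 1000,
                   config = gaConfig(populationSize = 60, generations = 15,
                                     seed = 11))
  expect_identical(res$membership@A, res2$membership@A)
  # over/alpha have no defaults
  expect_error(runFsoGa(fx$stage1$partition, fx$stage1$D, fx$toy$dag,
                        fx$toy$corpus),
               "no universal defaults")
})

test_that("every individual evaluated by the stage-2 GA is a valid membership", {
  fx <- tinyStage2Fixture()
  pot <- buildPotentialModules(fx$D, fx$partition@medoids, fx$partition@labels)
  seen <- 0L
  allValid <- TRUE
  fitWrap <- function(A) {
    seen <<- seen + 1L
    allValid <<- allValid &&
      all(A %in% c(0L, 1L)) && all(rowSums(A) >= 1) && all(colSums(A) >= 1) &&
      all(vapply(seq_len(nrow(A)),
                 function(i) all(which(A[i, ] == 1L) %in% pot[[i]]),
                 logical(1)))
    fsogaFitness(A, fx$toy$dag, fx$toy$corpus, alpha = 1000)$target
  }
  set.seed(6)
  pop <- fsogaInit(pot, over = 1, P = 15, partitionToMatrix(fx$partition),
                   fx$D, fx$partition@medoids)
  gaEvolve(pop, fitWrap,
           crossover = function(a, e) fsogaCrossover(a, e, pot, fx$D,
                                                     fx$partition@medoids),
           mutate = function(a) fsogaMutate(a, 0.3, pot, 1, fx$D,
                                            fx$partition@medoids),
           config = gaConfig(populationSize = 15, generations = 4,
                             patience = 10))
  expect_gt(seen, 15L)
  expect_true(allValid)
})
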
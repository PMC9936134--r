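#' Box-plot outlier threshold for module membership
#'
#' Upper whisker `Q3 + 1.5 * (Q3 - Q1)` of the distances from a module's
#' member genes to its medoid; quartiles by linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param clusterDistances numeric vector of member-to-medoid distances
#'   (length >= 1).
#' @return the threshold.
#' @export
membershipThreshold <- function(clusterDistances) {
  stopifnot(length(clusterDistances) >= 1L)
  q <- stats::quantile(clusterDistances, c(0.25, 0.75), type = 7, names = FALSE)
  q[2L] + 1.5 * (q[2L] - q[1L])
}

#' Potential-module lists from a stage-1 partition
#'
#' A gene may join module j when its distance to medoid j is strictly below
#' that module's box-plot threshold. The gene's own stage-1 module is
#' always included (the strict inequality could otherwise exclude outlier
#' genes entirely). Lists are ordered by ascending distance to the medoid.
#'
#' @param D distance matrix.
#' @param medoids stage-1 medoid indices.
#' @param labels stage-1 cluster labels.
#' @return named list (by gene id when `D` has dimnames) of integer module
#'   index vectors; attribute `"thresholds"` carries the per-module cutoffs.
#' @export
buildPotentialModules <- function(D, medoids, labels) {
  k <- length(medoids)
  thresholds <- vapply(seq_len(k), function(j) {
    membershipThreshold(D[labels == j, medoids[j]])
  }, numeric(1))
  n <- nrow(D)
  potential <- lapply(seq_len(n), function(i) {
    d <- D[i, medoids]
    js <- union(which(d < thresholds), labels[i])
    js[order(d[js])]
  })
  names(potential) <- rownames(D)
  attr(potential, "thresholds") <- thresholds
  potential
}

# Draw one gene's membership row per the initialization rule.
.drawRow <- function(choices, over) {
  M <- length(choices)
  if (M == 1L) return(choices)
  if (over >= 1) {
    nMod <- sample.int(M, 1L)
  } else if (stats::runif(1) < over) {
    nMod <- if (M == 2L) 2L else sample(2:M, 1L)
  } else {
    nMod <- 1L
  }
  sort(choices[sample.int(M, nMod)])
}

# Repair empty module columns: re-add, among genes listing that module, the
# one closest to its medoid.
.repairColumns <- function(A, potential, D, medoids) {
  emptyCols <- which(colSums(A) == 0L)
  for (j in emptyCols) {
    cand <- which(vapply(potential, function(p) j %in% p, logical(1)))
    best <- cand[which.min(D[cand, medoids[j]])]
    A[best, j] <- 1L
  }
  A
}

#' Initial population of membership matrices
#'
#' For each individual and gene: with `over = 1` the gene joins a uniform
#' random number 1..M of modules drawn from its potential list; otherwise a
#' uniform draw below `over` (and M > 1) assigns it to 2..M modules, else
#' to exactly one. The stage-1 partition matrix is included, so the GA can
#' only improve on it.
#'
#' @param potential list from [buildPotentialModules()].
#' @param over overlap probability in \[0, 1\].
#' @param P population size.
#' @param seedMatrix the stage-1 partition as a binary matrix.
#' @param D,medoids used to repair empty modules.
#' @return list of P binary matrices.
#' @export
fsogaInit <- function(potential, over, P, seedMatrix, D, medoids) {
  k <- ncol(seedMatrix)
  n <- nrow(seedMatrix)
  draw <- function() {
    A <- matrix(0L, n, k, dimnames = dimnames(seedMatrix))
    for (i in seq_len(n)) A[i, .drawRow(potential[[i]], over)] <- 1L
    .repairColumns(A, potential, D, medoids)
  }
  pop <- replicate(P - 1L, draw(), simplify = FALSE)
  c(pop, list(seedMatrix))
}

#' Single-point row crossover of membership matrices
#'
#' A cut point is drawn uniformly in `[1, n]`; the child takes rows
#' `1..cut` from the first parent and the rest from the second, then empty
#' modules are repaired.
#'
#' @param A1,A2 binary membership matrices of equal shape.
#' @param potential,D,medoids repair context.
#' @return child matrix.
#' @export
fsogaCrossover <- function(A1, A2, potential, D, medoids) {
  n <- nrow(A1)
  cut <- sample.int(n, 1L)
  child <- A1
  if (cut < n) child[(cut + 1L):n, ] <- A2[(cut + 1L):n, ]
  .repairColumns(child, potential, D, medoids)
}

#' Row-reassignment mutation of a membership matrix
#'
#' Each gene independently, with probability `mu`, has its row zeroed and
#' redrawn by the initialization rule.
#'
#' @param A binary membership matrix.
#' @param mu per-gene mutation probability.
#' @param potential,over initialization context.
#' @param D,medoids repair context.
#' @return mutated matrix.
#' @export
fsogaMutate <- function(A, mu, potential, over, D, medoids) {
  if (mu <= 0) return(A)
  hit <- stats::runif(nrow(A)) < mu
  for (i in which(hit)) {
    A[i, ] <- 0L
    A[i, .drawRow(potential[[i]], over)] <- 1L
  }
  if (any(hit)) A <- .repairColumns(A, potential, D, medoids)
  A
}

# Pairwise Lin similarities among a set of terms, with memoization.
.linCache <- function(dag, corpus) {
  cache <- new.env(parent = emptyenv())
  function(t1, t2) {
    key <- if (t1 < t2) paste(t1, t2) else paste(t2, t1)
    val <- cache[[key]]
    if (is.null(val)) {
      val <- linSimilarity(t1, t2, dag, corpus)
      cache[[key]] <- val
    }
    val
  }
}

#' Aggregate module term profiles into Sim, Sig and Target
#'
#' Given the retained enriched terms of each module, computes the three
#' fitness components. For a module with `num >= 2` retained terms, each
#' term contributes its mean pairwise similarity to the module's other
#' terms; `Sim` is the mean of these contributions over all such terms
#' (modules with fewer than two terms add none). `Sig` sums
#' `-log10(adjusted p)` over every retained term and divides by the module
#' count `k` (`sigNorm = "per_module"`) or by the retained-term count
#' (`sigNorm = "per_bp"`). `Target = Sim * alpha + Sig`.
#'
#' @param profiles list (one entry per module) of data.frames with columns
#'   `term` and `pAdj`; empty data.frames for modules with no significant
#'   terms.
#' @param k module count used in the `Sig` normalization.
#' @param alpha similarity weight.
#' @param pairSim function(t1, t2) returning the term-pair similarity.
#' @param sigNorm see above.
#' @return list with `target`, `sim`, `sig`.
#' @export
aggregateTarget <- function(profiles, k, alpha, pairSim,
                            sigNorm = c("per_module", "per_bp")) {
  sigNorm <- match.arg(sigNorm)
  simTerms <- numeric(0)
  logps <- numeric(0)
  for (prof in profiles) {
    num <- nrow(prof)
    if (num == 0L) next
    logps <- c(logps, -log10(prof$pAdj))
    if (num >= 2L) {
      for (i in seq_len(num)) {
        others <- prof$term[-i]
        simTerms <- c(simTerms,
                      mean(vapply(others, pairSim, numeric(1),
                                  t2 = prof$term[i])))
      }
    }
  }
  sim <- if (length(simTerms)) mean(simTerms) else 0
  sig <- if (length(logps)) {
    if (sigNorm == "per_module") sum(logps) / k else mean(logps)
  } else 0
  list(target = sim * alpha + sig, sim = sim, sig = sig)
}

#' Functional-similarity fitness of a membership matrix
#'
#' Each module's gene set is enriched for biological-process terms
#' ([enrichModule()]; up to `top` significant terms kept). For a module
#' with `num >= 2` retained terms, each term's similarity is its mean Lin
#' similarity to the module's other retained terms; `Sim` is the mean of
#' these per-term values across all modules (modules with fewer than two
#' retained terms contribute none). `Sig` is the sum over all retained
#' terms of `-log10(adjusted p)`, normalized by the module count `k`
#' (`sigNorm = "per_module"`, the published form) or by the retained term
#' count (`sigNorm = "per_bp"`). The fitness is
#' `Target = Sim * alpha + Sig`.
#'
#' @param A binary membership matrix with gene rownames.
#' @param dag a [GoDag-class].
#' @param corpus an [AnnotationCorpus-class].
#' @param alpha weighting factor balancing similarity against significance.
#' @param alphaSig enrichment significance cutoff.
#' @param top retained-term cap per module.
#' @param sigNorm normalization of `Sig` (see above).
#' @param linFn optional memoized pair-similarity function (internal reuse).
#' @return list with `target`, `sim`, `sig`.
#' @export
fsogaFitness <- function(A, dag, corpus, alpha, alphaSig = 0.05, top = 20L,
                         sigNorm = c("per_module", "per_bp"), linFn = NULL) {
  sigNorm <- match.arg(sigNorm)
  if (is.null(linFn)) linFn <- .linCache(dag, corpus)
  k <- ncol(A)
  profiles <- lapply(seq_len(k), function(j) {
    enrichModule(rownames(A)[A[, j] == 1L], dag, corpus,
                 alphaSig = alphaSig, top = top)
  })
  aggregateTarget(profiles, k, alpha, linFn, sigNorm)
}

#' Encode a stage-1 partition as a membership matrix
#'
#' @param partition a [ModulePartition-class].
#' @return binary genes x modules matrix with gene rownames.
#' @export
partitionToMatrix <- function(partition) {
  n <- length(partition@geneIds)
  A <- matrix(0L, n, partition@k,
              dimnames = list(partition@geneIds, NULL))
  A[cbind(seq_len(n), partition@labels)] <- 1L
  A
}

#' Stage 2: functional-similarity optimization of overlapping modules
#'
#' Builds per-gene potential-module lists from the stage-1 partition via
#' the box-plot distance rule, then evolves binary membership matrices
#' with the elite-crossover GA, maximizing `Sim * alpha + Sig`. The
#' stage-1 matrix seeds the population, so the elite's Target never falls
#' below the seed's.
#'
#' @param partition stage-1 [ModulePartition-class].
#' @param D distance matrix used in stage 1.
#' @param dag a [GoDag-class].
#' @param corpus an [AnnotationCorpus-class].
#' @param over overlap probability (no universal default; tune per
#'   dataset).
#' @param alpha similarity weight (no universal default; tune per
#'   dataset).
#' @param config a [gaConfig()]; enrichment dominates the cost, so keep
#'   the population moderate (hundreds to ~1000–2000).
#' @param alphaSig,top,sigNorm see [fsogaFitness()].
#' @return list with `membership` (a [ModuleMembership-class]), `fit` (a
#'   [GAFit-class]), and `seed` (the stage-1 matrix's target/sim/sig).
#' @export
runFsoGa <- function(partition, D, dag, corpus, over, alpha,
                     config = gaConfig(populationSize = 100L),
                     alphaSig = 0.05, top = 20L, sigNorm = "per_module") {
  if (missing(over) || missing(alpha) || is.null(over) || is.null(alpha))
    stop("'over' and 'alpha' have no universal defaults; set them for the dataset")
  if (!is.null(config$seed)) set.seed(config$seed)
  medoids <- partition@medoids
  potential <- buildPotentialModules(D, medoids, partition@labels)
  seedMatrix <- partitionToMatrix(partition)
  linFn <- .linCache(dag, corpus)
  fitFn <- function(A) {
    fsogaFitness(A, dag, corpus, alpha = alpha, alphaSig = alphaSig,
                 top = top, sigNorm = sigNorm, linFn = linFn)$target
  }
  pop <- fsogaInit(potential, over, config$populationSize, seedMatrix,
                   D, medoids)
  cfg <- config
  cfg$seed <- NULL
  fit <- gaEvolve(
    initialPopulation = pop,
    fitness = fitFn,
    crossover = function(a, elite) fsogaCrossover(a, elite, potential, D, medoids),
    mutate = function(a) fsogaMutate(a, cfg$mutationRate, potential, over,
                                     D, medoids),
    config = cfg,
    keyFn = function(A) paste(vapply(seq_len(ncol(A)), function(j) {
      paste(which(A[, j] == 1L), collapse = ",")
    }, character(1)), collapse = ";")
  )
  eliteParts <- fsogaFitness(fit@elite, dag, corpus, alpha = alpha,
                             alphaSig = alphaSig, top = top,
                             sigNorm = sigNorm, linFn = linFn)
  seedParts <- fsogaFitness(seedMatrix, dag, corpus, alpha = alpha,
                            alphaSig = alphaSig, top = top,
                            sigNorm = sigNorm, linFn = linFn)
  membership <- methods::new("ModuleMembership",
                             A = fit@elite, potential = as.list(potential),
                             sim = eliteParts$sim, sig = eliteParts$sig,
                             target = eliteParts$target,
                             alpha = alpha, over = over)
  list(membership = membership, fit = fit, seed = seedParts)
}
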
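#' Initial population for the medoid-set GA
#'
#' `P - 1` uniform-random k-subsets of the gene indices plus the PAM
#' solution, so the GA can only improve on plain PAM.
#'
#' @param n number of genes.
#' @param k medoid count.
#' @param P population size.
#' @param pamSolution integer medoid set from [pamRun()].
#' @return list of P integer medoid sets.
#' @export
pamgaInitPopulation <- function(n, k, P, pamSolution) {
  stopifnot(P >= 2L, length(pamSolution) == k)
  pop <- replicate(P - 1L, sample.int(n, k), simplify = FALSE)
  c(pop, list(as.integer(pamSolution)))
}

#' Medoid-set crossover
#'
#' Merges the elements of both parents and draws a uniform-random k-subset
#' of the union (all of it, when the parents coincide).
#'
#' @param parent,elite integer medoid sets of equal size k.
#' @return integer medoid set of size k.
#' @export
pamgaCrossover <- function(parent, elite) {
  pool <- union(parent, elite)
  k <- length(parent)
  if (length(pool) == k) return(pool)
  pool[sample.int(length(pool), k)]
}

#' Medoid-set mutation
#'
#' With probability `mu` (per individual), removes one uniformly chosen
#' element and adds one uniformly chosen gene not currently present, so the
#' result always holds k distinct indices. A no-op when `k = n`.
#'
#' @param ind integer medoid set.
#' @param mu mutation probability.
#' @param n total number of genes.
#' @return mutated medoid set.
#' @export
pamgaMutate <- function(ind, mu, n) {
  if (mu <= 0 || stats::runif(1) >= mu) return(ind)
  outside <- setdiff(seq_len(n), ind)
  if (length(outside) == 0L) return(ind)  # k = n: nothing to add
  ind[sample.int(length(ind), 1L)] <- outside[sample.int(length(outside), 1L)]
  ind
}

#' Stage 1: genetic-algorithm search over medoid sets
#'
#' Replaces PAM's blind random medoid updates with an elite-crossover GA
#' whose fitness is the mean silhouette of the nearest-medoid assignment.
#' The PAM solution is part of the initial population, so the returned
#' silhouette is never below the PAM seed's.
#'
#' @param D distance matrix.
#' @param k cluster count (normally the [scanK()] winner).
#' @param config a [gaConfig()]; the default population of 200 is sized
#'   for interactive use — genome-scale runs typically use populations in
#'   the thousands.
#' @param pamSolution optional medoid seed; computed by [pamRun()] when
#'   omitted.
#' @param pamMaxIter swap proposals for the internal PAM seed run.
#' @param bMode silhouette separation mode.
#' @return list with `partition` (a [ModulePartition-class]), `fit` (a
#'   [GAFit-class]) and `seedSilhouette` (the PAM seed's score).
#' @export
runPamGa <- function(D, k, config = gaConfig(), pamSolution = NULL,
                     pamMaxIter = 2000L, bMode = "nearest_other") {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(D)
  if (is.null(pamSolution))
    pamSolution <- pamRun(D, k, maxIter = pamMaxIter)$medoids
  seedS <- meanSilhouette(assignToMedoids(D, pamSolution), D, bMode = bMode)
  pop <- pamgaInitPopulation(n, k, config$populationSize, pamSolution)
  cfg <- config
  cfg$seed <- NULL  # already applied; evolve must not reset the stream
  fit <- gaEvolve(
    initialPopulation = pop,
    fitness = function(ind) meanSilhouette(assignToMedoids(D, ind), D,
                                           bMode = bMode),
    crossover = pamgaCrossover,
    mutate = function(ind) pamgaMutate(ind, cfg$mutationRate, n),
    config = cfg,
    keyFn = function(ind) paste(sort(ind), collapse = ",")
  )
  medoids <- as.integer(fit@elite)
  labels <- assignToMedoids(D, medoids)
  partition <- methods::new("ModulePartition",
                            geneIds = rownames(D), medoids = medoids,
                            labels = labels, k = as.integer(k),
                            silhouette = fit@eliteFitness)
  list(partition = partition, fit = fit, seedSilhouette = seedS)
}
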
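#' Genetic-algorithm configuration
#'
#' @param populationSize number of individuals per generation (>= 2 for
#'   meaningful crossover; >= 1 accepted).
#' @param generations maximum generations.
#' @param mutationRate per-individual mutation probability in \[0, 1\].
#' @param patience consecutive generations with unchanged elite fitness
#'   before stopping (default 3).
#' @param seed optional integer seed applied at the start of a run.
#' @return a `gaConfig` list.
#' @export
gaConfig <- function(populationSize = 200L, generations = 20L,
                     mutationRate = 0.1, patience = 3L, seed = NULL) {
  stopifnot(populationSize >= 1L, generations >= 1L,
            mutationRate >= 0, mutationRate <= 1, patience >= 1L)
  structure(list(populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 mutationRate = mutationRate,
                 patience = as.integer(patience),
                 seed = seed),
            class = "gaConfig")
}

#' Elite-crossover genetic algorithm
#'
#' Shared engine for both search stages. The elite is the best individual
#' found so far; every generation, each current individual is crossed with
#' the elite, the child is mutated and evaluated, and it replaces the elite
#' immediately when strictly fitter. The children form the next
#' generation's population. The run stops after `generations` generations
#' or once the elite fitness has been unchanged for `patience` consecutive
#' generations.
#'
#' @param initialPopulation non-empty list of individuals.
#' @param fitness function(individual) -> finite numeric (larger is
#'   better).
#' @param crossover function(individual, elite) -> individual.
#' @param mutate function(individual) -> individual (mutation probability
#'   is the closure's concern).
#' @param config a [gaConfig()].
#' @param keyFn optional function(individual) -> string; enables fitness
#'   memoization keyed on the canonical representation.
#' @return a [GAFit-class] object.
#' @export
gaEvolve <- function(initialPopulation, fitness, crossover, mutate, config,
                     keyFn = NULL) {
  stopifnot(length(initialPopulation) >= 1L)
  if (!is.null(config$seed)) set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  nEval <- 0L
  nHit <- 0L
  evalFit <- function(ind) {
    nEval <<- nEval + 1L
    if (!is.null(keyFn)) {
      key <- keyFn(ind)
      if (!is.null(cache[[key]])) {
        nHit <<- nHit + 1L
        return(cache[[key]])
      }
      f <- fitness(ind)
      if (!is.finite(f)) stop("non-finite fitness for individual ", key)
      cache[[key]] <- f
      return(f)
    }
    f <- fitness(ind)
    if (!is.finite(f))
      stop("non-finite fitness for an individual in the population")
    f
  }

  fits <- vapply(initialPopulation, evalFit, numeric(1))
  eliteIdx <- which.max(fits)
  elite <- initialPopulation[[eliteIdx]]
  eliteFit <- fits[eliteIdx]
  trace <- eliteFit
  pop <- initialPopulation
  stall <- 0L
  terminatedBy <- "max_generations"
  gen <- 0L

  for (g in seq_len(config$generations)) {
    gen <- g
    prevFit <- eliteFit
    newPop <- vector("list", length(pop))
    for (i in seq_along(pop)) {
      child <- mutate(crossover(pop[[i]], elite))
      f <- evalFit(child)
      if (f > eliteFit) {
        elite <- child
        eliteFit <- f
      }
      newPop[[i]] <- child
    }
    pop <- newPop
    trace <- c(trace, eliteFit)
    if (eliteFit == prevFit) stall <- stall + 1L else stall <- 0L
    if (stall >= config$patience) {
      terminatedBy <- "stall"
      break
    }
  }

  methods::new("GAFit", elite = elite, eliteFitness = eliteFit,
               trace = trace, generations = gen,
               terminatedBy = terminatedBy,
               evaluations = nEval, cacheHits = nHit)
}
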
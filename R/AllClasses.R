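#' @import methods
NULL

#' Gene Ontology DAG
#'
#' Directed acyclic graph of GO terms connected by is_a (and optionally
#' part_of) edges, restricted to a single namespace. Ancestor closures are
#' precomputed at construction and include the term itself.
#'
#' @slot terms character vector of term identifiers.
#' @slot termNames named character vector of human-readable term names.
#' @slot parents named list; for each term, the character vector of its
#'   direct parents (empty for roots).
#' @slot ancestors named list; for each term, all ancestors including the
#'   term itself.
#' @slot roots character vector of terms with no parents.
#' @slot namespace single string, e.g. `"biological_process"`.
#'
#' @seealso [loadObo()], [makeToyOntology()]
#' @export
setClass("GoDag",
  representation(
    terms = "character",
    termNames = "character",
    parents = "list",
    ancestors = "list",
    roots = "character",
    namespace = "character"
  )
)

setValidity("GoDag", function(object) {
  msg <- character()
  if (anyDuplicated(object@terms))
    msg <- c(msg, "duplicate term identifiers")
  if (!all(names(object@parents) == object@terms))
    msg <- c(msg, "parents list must be named by terms, in order")
  allParents <- unique(unlist(object@parents, use.names = FALSE))
  if (length(allParents) && !all(allParents %in% object@terms))
    msg <- c(msg, "parent identifiers missing from the term set")
  if (length(object@terms) && length(object@roots) == 0L)
    msg <- c(msg, "a non-empty DAG must have at least one root")
  if (length(msg)) msg else TRUE
})

#' Gene annotation corpus
#'
#' Gene-to-term annotations over a [GoDag], with ancestor-propagated
#' term membership. `p(t)` for a term is its propagated gene count over the
#' number of annotated genes, so the namespace root has `p = 1`.
#'
#' @slot gene2terms named list; directly annotated terms per gene.
#' @slot term2genes named list; genes annotated to each term after
#'   propagating annotations to all ancestors.
#' @slot termCounts named integer vector, `lengths(term2genes)`.
#' @slot totalGenes integer, number of genes with at least one annotation.
#'
#' @seealso [annotationCorpus()], [linSimilarity()], [enrichModule()]
#' @export
setClass("AnnotationCorpus",
  representation(
    gene2terms = "list",
    term2genes = "list",
    termCounts = "integer",
    totalGenes = "integer"
  )
)

setValidity("AnnotationCorpus", function(object) {
  msg <- character()
  if (object@totalGenes < 1L)
    msg <- c(msg, "corpus must annotate at least one gene")
  if (!identical(unname(lengths(object@term2genes)),
                 unname(object@termCounts)))
    msg <- c(msg, "termCounts must equal lengths(term2genes)")
  if (any(object@termCounts < 1L) || any(object@termCounts > object@totalGenes))
    msg <- c(msg, "term counts must lie in [1, totalGenes]")
  if (length(msg)) msg else TRUE
})

#' Stage-1 module partition
#'
#' A hard clustering of genes around medoids: the result of PAM or of the
#' medoid-set genetic algorithm. Every gene carries exactly one label and
#' each of the k clusters is represented by a medoid gene.
#'
#' @slot geneIds character vector of gene identifiers (row order of the
#'   distance matrix).
#' @slot medoids integer vector of k distinct gene indices.
#' @slot labels integer vector, one cluster index in `1:k` per gene.
#' @slot k integer cluster count.
#' @slot silhouette mean silhouette score of the partition.
#'
#' @seealso [pamRun()], [runPamGa()], [scanK()]
#' @export
setClass("ModulePartition",
  representation(
    geneIds = "character",
    medoids = "integer",
    labels = "integer",
    k = "integer",
    silhouette = "numeric"
  )
)

setValidity("ModulePartition", function(object) {
  n <- length(object@geneIds)
  k <- object@k
  msg <- character()
  if (length(object@medoids) != k || anyDuplicated(object@medoids))
    msg <- c(msg, "medoids must be k distinct indices")
  if (any(object@medoids < 1L) || any(object@medoids > n))
    msg <- c(msg, "medoid indices out of range")
  if (length(object@labels) != n)
    msg <- c(msg, "one label per gene required")
  if (length(object@labels) && !all(object@labels %in% seq_len(k)))
    msg <- c(msg, "labels must lie in 1:k")
  if (length(object@labels) && !all(seq_len(k) %in% object@labels))
    msg <- c(msg, "every cluster must contain at least one gene")
  if (length(msg)) msg else TRUE
})

#' Overlapping module membership
#'
#' Stage-2 result: a binary genes x modules membership matrix in which a
#' gene may belong to several modules, each membership licensed by the
#' gene's potential-module list (box-plot distance rule).
#'
#' @slot A binary integer matrix, rows = genes, columns = modules.
#' @slot potential named list; per gene, the module indices it may join.
#' @slot sim within-module functional similarity of the solution.
#' @slot sig enrichment-significance component of the solution.
#' @slot target fitness value `sim * alpha + sig`.
#' @slot alpha weighting factor used.
#' @slot over overlap probability used.
#'
#' @seealso [runFsoGa()], [buildPotentialModules()]
#' @export
setClass("ModuleMembership",
  representation(
    A = "matrix",
    potential = "list",
    sim = "numeric",
    sig = "numeric",
    target = "numeric",
    alpha = "numeric",
    over = "numeric"
  )
)

setValidity("ModuleMembership", function(object) {
  A <- object@A
  msg <- character()
  if (!all(A %in% c(0L, 1L)))
    msg <- c(msg, "membership matrix must be binary")
  if (any(rowSums(A) < 1L))
    msg <- c(msg, "every gene must belong to at least one module")
  if (any(colSums(A) < 1L))
    msg <- c(msg, "every module must contain at least one gene")
  if (length(object@potential) != nrow(A)) {
    msg <- c(msg, "one potential-module list per gene required")
  } else {
    ok <- vapply(seq_len(nrow(A)), function(i) {
      all(which(A[i, ] == 1L) %in% object@potential[[i]])
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "memberships outside the potential-module lists")
  }
  if (length(msg)) msg else TRUE
})

#' Genetic-algorithm fit
#'
#' Bookkeeping for one run of the elite-crossover GA engine.
#'
#' @slot elite the best individual ever evaluated.
#' @slot eliteFitness its fitness.
#' @slot trace numeric vector of elite fitness: initial value followed by
#'   one entry per generation (non-decreasing).
#' @slot generations number of generations actually run.
#' @slot terminatedBy `"max_generations"` or `"stall"`.
#' @slot evaluations number of fitness evaluations requested.
#' @slot cacheHits evaluations answered from the memoization cache.
#'
#' @seealso [gaEvolve()]
#' @export
setClass("GAFit",
  representation(
    elite = "ANY",
    eliteFitness = "numeric",
    trace = "numeric",
    generations = "integer",
    terminatedBy = "character",
    evaluations = "integer",
    cacheHits = "integer"
  )
)

setValidity("GAFit", function(object) {
  if (is.unsorted(object@trace))
    return("elite fitness trace must be non-decreasing")
  TRUE
})
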
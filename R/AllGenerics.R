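#' @describeIn ModulePartition medoid gene indices
#' @param object a \code{ModulePartition}
#' @export
setGeneric("medoids", function(object) standardGeneric("medoids"))

#' @describeIn ModulePartition per-gene cluster labels (named by gene)
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @describeIn ModulePartition mean silhouette score of the partition
#' @export
setGeneric("silhouetteScore", function(object) standardGeneric("silhouetteScore"))

#' @describeIn ModuleMembership the binary genes x modules matrix
#' @param object a \code{ModuleMembership}
#' @export
setGeneric("membershipMatrix", function(object) standardGeneric("membershipMatrix"))

#' @describeIn ModuleMembership gene identifiers of one module
#' @param module module (column) index
#' @export
setGeneric("moduleGenes", function(object, module) standardGeneric("moduleGenes"))

#' Number of GO terms in a DAG
#' @param object a \code{GoDag}
#' @export
setGeneric("nTerms", function(object) standardGeneric("nTerms"))

#' @rdname GoDag-class
#' @param object a \code{GoDag}
#' @export
setGeneric("dagRoots", function(object) standardGeneric("dagRoots"))

setMethod("medoids", "ModulePartition", function(object) object@medoids)

setMethod("clusterLabels", "ModulePartition", function(object) {
  stats::setNames(object@labels, object@geneIds)
})

setMethod("silhouetteScore", "ModulePartition", function(object) object@silhouette)

setMethod("membershipMatrix", "ModuleMembership", function(object) object@A)

setMethod("moduleGenes", "ModuleMembership", function(object, module) {
  rownames(object@A)[object@A[, module] == 1L]
})

setMethod("nTerms", "GoDag", function(object) length(object@terms))

setMethod("dagRoots", "GoDag", function(object) object@roots)

setMethod("show", "GoDag", function(object) {
  cat("GoDag:", length(object@terms), "terms,",
      sum(lengths(object@parents)), "edges,",
      length(object@roots), "root(s), namespace",
      object@namespace, "\n")
})

setMethod("show", "AnnotationCorpus", function(object) {
  cat("AnnotationCorpus:", object@totalGenes, "annotated genes,",
      length(object@term2genes), "terms with propagated annotations\n")
})

setMethod("show", "ModulePartition", function(object) {
  cat("ModulePartition: ", length(object@geneIds), " genes in ",
      object@k, " modules (mean silhouette ",
      format(object@silhouette, digits = 6), ")\n", sep = "")
  print(table(module = object@labels))
})

setMethod("show", "ModuleMembership", function(object) {
  cat("ModuleMembership: ", nrow(object@A), " genes x ", ncol(object@A),
      " modules; ", sum(rowSums(object@A) > 1L), " overlapping gene(s)\n",
      "  Sim = ", format(object@sim, digits = 6),
      ", Sig = ", format(object@sig, digits = 6),
      ", Target = ", format(object@target, digits = 6), "\n", sep = "")
})

setMethod("show", "GAFit", function(object) {
  cat("GAFit: elite fitness ", format(object@eliteFitness, digits = 6),
      " after ", object@generations, " generation(s), terminated by ",
      object@terminatedBy, "\n  ", object@evaluations, " evaluations (",
      object@cacheHits, " cache hits)\n", sep = "")
})
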
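## Orchestration helpers shared by the R interface and the CLI.

#' Write an expression matrix as TSV
#' @param x genes x samples matrix.
#' @param path output file.
#' @export
writeExpression <- function(x, path) {
  utils::write.table(cbind(gene_id = rownames(x), as.data.frame(x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stage-1 clustering of an expression matrix
#'
#' Computes the 1 - Pearson distance matrix, scans the cluster count by
#' silhouette, then refines the winning k's medoids with the genetic
#' algorithm.
#'
#' @param x genes x samples expression matrix.
#' @param kMin,kMax silhouette scan range.
#' @param config a [gaConfig()] for the medoid GA.
#' @param pamMaxIter swap proposals per PAM run.
#' @param seed integer seed governing the whole stage.
#' @return list with `partition`, `fit`, `seedSilhouette`, `scan`, `D`.
#' @export
clusterStage <- function(x, kMin = 8L, kMax = 20L, config = gaConfig(),
                         pamMaxIter = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- distanceMatrix(x)
  scan <- scanK(D, kMin = kMin, kMax = kMax, maxIter = pamMaxIter)
  cfg <- config
  cfg$seed <- NULL
  res <- runPamGa(D, scan$k, config = cfg, pamSolution = scan$medoids)
  c(res, list(scan = scan$scan, D = D))
}

#' Stage-2 overlap optimization of a stage-1 result
#'
#' @param stage1 result of [clusterStage()].
#' @param dag,corpus ontology and annotations.
#' @param over,alpha stage-2 tuning parameters (required).
#' @param config a [gaConfig()] for the membership GA.
#' @param ... passed to [runFsoGa()].
#' @return see [runFsoGa()].
#' @export
optimizeStage <- function(stage1, dag, corpus, over, alpha,
                          config = gaConfig(populationSize = 100L), ...) {
  runFsoGa(stage1$partition, stage1$D, dag, corpus, over = over,
           alpha = alpha, config = config, ...)
}

#' Full two-stage pipeline
#'
#' @inheritParams clusterStage
#' @inheritParams optimizeStage
#' @param kMin,kMax stage-1 scan range.
#' @param clusterConfig,optimizeConfig GA configurations for the two
#'   stages.
#' @param seed integer seed for the whole run.
#' @return list with `stage1` and `stage2` results.
#' @export
runPipeline <- function(x, dag, corpus, over, alpha, kMin = 8L, kMax = 20L,
                        clusterConfig = gaConfig(),
                        optimizeConfig = gaConfig(populationSize = 100L),
                        pamMaxIter = 2000L, seed = 1L) {
  set.seed(seed)
  stage1 <- clusterStage(x, kMin = kMin, kMax = kMax, config = clusterConfig,
                         pamMaxIter = pamMaxIter)
  stage2 <- optimizeStage(stage1, dag, corpus, over = over, alpha = alpha,
                          config = optimizeConfig)
  list(stage1 = stage1, stage2 = stage2)
}

#' Write stage-1 artifacts to a directory
#' @param stage1 result of [clusterStage()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStage1 <- function(stage1, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- stage1$partition
  utils::write.table(data.frame(module = seq_len(p@k),
                                medoid_gene = p@geneIds[p@medoids]),
                     file.path(dir, "medoids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = p@geneIds, module = p@labels),
                     file.path(dir, "assignment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(stage1$scan, file.path(dir, "kscan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- list(k = p@k, silhouette = p@silhouette,
                 pam_seed_silhouette = stage1$seedSilhouette,
                 generations = stage1$fit@generations,
                 terminated_by = stage1$fit@terminatedBy,
                 fitness_trace = stage1$fit@trace)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write stage-2 artifacts to a directory
#' @param stage2 result of [optimizeStage()].
#' @param dag,corpus used to re-derive the per-module enrichment tables.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStage2 <- function(stage2, dag, corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- stage2$membership
  A <- m@A
  out <- cbind(gene_id = rownames(A), as.data.frame(A))
  colnames(out) <- c("gene_id", paste0("module_", seq_len(ncol(A))))
  utils::write.table(out, file.path(dir, "membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (j in seq_len(ncol(A))) {
    prof <- enrichModule(rownames(A)[A[, j] == 1L], dag, corpus)
    utils::write.table(prof,
                       file.path(dir, sprintf("enrichment_module_%02d.tsv", j)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(sim = m@sim, sig = m@sig, target = m@target,
                 over = m@over, alpha = m@alpha,
                 seed_sim = stage2$seed$sim, seed_sig = stage2$seed$sig,
                 seed_target = stage2$seed$target,
                 generations = stage2$fit@generations,
                 terminated_by = stage2$fit@terminatedBy,
                 fitness_trace = stage2$fit@trace)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
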
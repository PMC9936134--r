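#' One-sided hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least `overlap`
#' annotated genes when `moduleSize` genes are sampled without replacement
#' from a background of `backgroundSize` genes of which `termSize` carry
#' the term.
#'
#' @param overlap module genes annotated to the term.
#' @param moduleSize number of (annotated) genes in the module.
#' @param termSize background genes annotated to the term (propagated).
#' @param backgroundSize size of the test universe.
#' @return p-value in (0, 1\].
#' @export
hypergeomTest <- function(overlap, moduleSize, termSize, backgroundSize) {
  if (overlap > moduleSize || overlap > termSize ||
      termSize > backgroundSize || moduleSize > backgroundSize ||
      min(overlap, moduleSize, termSize) < 0)
    stop("inconsistent hypergeometric counts")
  stats::phyper(overlap - 1, termSize, backgroundSize - termSize,
                moduleSize, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, order-preserving with
#' the input and capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' GO biological-process over-representation analysis of one module
#'
#' Tests every term annotated (after ancestor propagation) to at least one
#' module gene against the corpus background (all annotated genes of the
#' dataset), adjusts across the module's tested terms by
#' Benjamini-Hochberg, keeps terms with adjusted p below `alphaSig`, and
#' truncates to the `top` most significant (ties broken by term id).
#' Module genes without annotations are dropped from the test universe.
#'
#' @param moduleGenes character vector of gene ids.
#' @param dag a [GoDag-class] (reserved for interface symmetry; membership
#'   is read from the propagated corpus).
#' @param corpus an [AnnotationCorpus-class].
#' @param alphaSig significance cutoff on adjusted p (default 0.05).
#' @param top maximum number of retained terms (default 20).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return data.frame with columns term, overlap, moduleSize, termSize,
#'   backgroundSize, p, pAdj, sorted ascending by pAdj; zero rows when no
#'   module gene is annotated or nothing is significant.
#' @export
enrichModule <- function(moduleGenes, dag, corpus, alphaSig = 0.05,
                         top = 20L, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  empty <- data.frame(term = character(), overlap = integer(),
                      moduleSize = integer(), termSize = integer(),
                      backgroundSize = integer(), p = numeric(),
                      pAdj = numeric(), stringsAsFactors = FALSE)
  annotated <- intersect(moduleGenes, names(corpus@gene2terms))
  if (!length(annotated)) return(empty)
  m <- length(annotated)
  N <- corpus@totalGenes
  # a term is a candidate iff >= 1 module gene is in its propagated set
  cand <- names(corpus@term2genes)[vapply(corpus@term2genes,
                                          function(g) any(annotated %in% g),
                                          logical(1))]
  ov <- vapply(corpus@term2genes[cand],
               function(g) sum(annotated %in% g), integer(1))
  ts <- corpus@termCounts[cand]
  p <- stats::phyper(ov - 1, ts, N - ts, m, lower.tail = FALSE)
  pAdj <- if (adjust == "BH") bhAdjust(p) else pmin(1, p * length(p))
  res <- data.frame(term = cand, overlap = as.integer(ov),
                    moduleSize = m, termSize = as.integer(ts),
                    backgroundSize = N, p = as.numeric(p),
                    pAdj = as.numeric(pAdj), stringsAsFactors = FALSE)
  res <- res[res$pAdj < alphaSig, , drop = FALSE]
  res <- res[order(res$pAdj, res$term), , drop = FALSE]
  if (nrow(res) > top) res <- res[seq_len(top), , drop = FALSE]
  rownames(res) <- NULL
  res
}
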
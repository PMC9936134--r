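#' Design for planted-block synthetic expression data
#'
#' @param nGenes total gene count (split as evenly as possible across
#'   blocks; overlap genes are additional).
#' @param nSamples sample count.
#' @param kBlocks number of planted co-expression blocks.
#' @param withinBlockCorr target within-block Pearson correlation in
#'   (0, 1\]; the matching noise level is `sqrt(1/r - 1)` so that
#'   `r = 1 / (1 + sd^2)`.
#' @param nOverlapGenes genes planted in two blocks at once (their latent
#'   profile averages two block latents), giving stage 2 genuinely
#'   ambiguous genes.
#' @param seed integer seed.
#' @return a `plantedDesign` list.
#' @export
plantedDesign <- function(nGenes = 40L, nSamples = 60L, kBlocks = 4L,
                          withinBlockCorr = 0.9, nOverlapGenes = 0L,
                          seed = 1L) {
  stopifnot(kBlocks >= 2L, nGenes >= 2L * kBlocks,
            withinBlockCorr > 0, withinBlockCorr <= 1)
  structure(list(nGenes = as.integer(nGenes),
                 nSamples = as.integer(nSamples),
                 kBlocks = as.integer(kBlocks),
                 withinBlockCorr = withinBlockCorr,
                 noiseSd = sqrt(1 / withinBlockCorr - 1),
                 nOverlapGenes = as.integer(nOverlapGenes),
                 seed = as.integer(seed)),
            class = "plantedDesign")
}

#' Generate planted-block expression data
#'
#' Latent-factor model: each block has a standard-normal latent sample
#' profile; a member gene is the latent plus independent Gaussian noise, so
#' the expected within-block Pearson correlation equals the design target
#' while cross-block correlation is ~0. Overlap genes use the average of
#' two block latents. Values are shifted to be non-negative.
#'
#' @param design a [plantedDesign()].
#' @return list with `expression` (matrix, gene rownames `g1..`, sample
#'   colnames `s1..`), `labels` (integer planted block per gene; overlap
#'   genes carry the first of their two blocks), and `overlapPairs`
#'   (data.frame gene, block1, block2).
#' @export
makePlantedExpression <- function(design) {
  set.seed(design$seed)
  k <- design$kBlocks
  latent <- matrix(stats::rnorm(k * design$nSamples), k, design$nSamples)
  sizes <- rep(design$nGenes %/% k, k)
  extra <- design$nGenes - sum(sizes)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(seq_len(k), sizes)
  n <- design$nGenes + design$nOverlapGenes
  X <- matrix(0, n, design$nSamples)
  for (i in seq_len(design$nGenes)) {
    X[i, ] <- latent[labels[i], ] +
      design$noiseSd * stats::rnorm(design$nSamples)
  }
  overlapPairs <- data.frame(gene = character(), block1 = integer(),
                             block2 = integer(), stringsAsFactors = FALSE)
  if (design$nOverlapGenes > 0L) {
    for (o in seq_len(design$nOverlapGenes)) {
      b <- sort(sample.int(k, 2L))
      i <- design$nGenes + o
      X[i, ] <- (latent[b[1L], ] + latent[b[2L], ]) / sqrt(2) +
        design$noiseSd * stats::rnorm(design$nSamples)
      labels <- c(labels, b[1L])
      overlapPairs <- rbind(overlapPairs,
                            data.frame(gene = paste0("g", i),
                                       block1 = b[1L], block2 = b[2L]))
    }
  }
  X <- X - min(X)  # expression values are non-negative
  dimnames(X) <- list(paste0("g", seq_len(n)),
                      paste0("s", seq_len(design$nSamples)))
  attr(X, "units") <- "FPKM"
  list(expression = X, labels = labels, overlapPairs = overlapPairs)
}

#' Generate a toy GO DAG with block-aligned annotations
#'
#' One biological-process root, one subtree per planted block (an inner
#' block term with `termsPerBlock` leaf children, deeper chains when
#' `depth > 2`), and gene annotations aligned with the blocks: each gene is
#' annotated to leaves of its own block's subtree, and a `noise` fraction
#' of genes receives one extra annotation to a random leaf of a foreign
#' subtree.
#'
#' @param labels integer vector of planted block labels (one per gene,
#'   genes named `g1..` unless `geneIds` given).
#' @param termsPerBlock leaf terms per block subtree (default 3).
#' @param depth levels between root and leaves (default 2: root, block
#'   term, leaves).
#' @param annotationsPerGene leaf annotations per gene (default 2, capped
#'   at `termsPerBlock`).
#' @param noise fraction of genes with one cross-subtree annotation
#'   (default 0).
#' @param seed integer seed.
#' @param geneIds optional gene identifiers.
#' @return list with `dag` ([GoDag-class]), `corpus`
#'   ([AnnotationCorpus-class]), `block2terms` (list of leaf ids per
#'   block), and `annotations` (the (gene, term) data.frame).
#' @export
makeToyOntology <- function(labels, termsPerBlock = 3L, depth = 2L,
                            annotationsPerGene = 2L, noise = 0,
                            seed = 1L, geneIds = paste0("g", seq_along(labels))) {
  set.seed(seed)
  k <- max(labels)
  stopifnot(k >= 2L, depth >= 2L, termsPerBlock >= 1L)
  tid <- function(i) sprintf("GO:%07d", i)
  counter <- 1L
  root <- tid(counter)
  terms <- root
  names <- "biological_process root"
  parents <- list(character(0))
  block2terms <- vector("list", k)
  for (b in seq_len(k)) {
    # chain of depth-1 internal terms, then the leaves
    chain <- root
    for (d in seq_len(depth - 1L)) {
      counter <- counter + 1L
      node <- tid(counter)
      terms <- c(terms, node)
      names <- c(names, sprintf("block %d level %d", b, d))
      parents <- c(parents, list(chain))
      chain <- node
    }
    leaves <- character(termsPerBlock)
    for (l in seq_len(termsPerBlock)) {
      counter <- counter + 1L
      leaves[l] <- tid(counter)
      terms <- c(terms, leaves[l])
      names <- c(names, sprintf("block %d process %d", b, l))
      parents <- c(parents, list(chain))
    }
    block2terms[[b]] <- leaves
  }
  names(parents) <- terms
  dag <- .newGoDag(terms = terms,
                   termNames = stats::setNames(names, terms),
                   parents = parents, namespace = "biological_process")
  methods::validObject(dag)

  nAnn <- min(annotationsPerGene, termsPerBlock)
  ann <- do.call(rbind, lapply(seq_along(labels), function(i) {
    own <- block2terms[[labels[i]]]
    picks <- own[sample.int(length(own), nAnn)]
    data.frame(gene = geneIds[i], term = picks, stringsAsFactors = FALSE)
  }))
  if (noise > 0) {
    noisy <- which(stats::runif(length(labels)) < noise)
    for (i in noisy) {
      foreign <- setdiff(seq_len(k), labels[i])
      fb <- foreign[sample.int(length(foreign), 1L)]
      leaf <- block2terms[[fb]][sample.int(termsPerBlock, 1L)]
      ann <- rbind(ann, data.frame(gene = geneIds[i], term = leaf,
                                   stringsAsFactors = FALSE))
    }
  }
  corpus <- annotationCorpus(ann, dag)
  list(dag = dag, corpus = corpus, block2terms = block2terms,
       annotations = ann)
}
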
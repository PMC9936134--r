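#' Pearson-correlation distance between two expression profiles
#'
#' `1 - r`, with `r` the sample Pearson correlation; 0 for perfectly
#' positively correlated genes, 2 for perfectly anticorrelated ones.
#'
#' @param g1,g2 numeric vectors of equal length (>= 2 samples).
#' @return distance in \[0, 2\].
#' @export
pearsonDistance <- function(g1, g2) {
  if (length(g1) != length(g2) || length(g1) < 2L)
    stop("profiles must have equal length >= 2")
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0)
    stop("zero-variance profile: drop constant genes during preprocessing")
  1 - stats::cor(g1, g2)
}

#' Gene-gene distance matrix
#'
#' All pairwise `1 - Pearson r` distances between the rows of an expression
#' matrix; computed once and reused by clustering and silhouette scoring.
#'
#' @param x genes x samples matrix with >= 2 samples and no constant rows.
#' @return symmetric n x n matrix with zero diagonal, entries in \[0, 2\],
#'   gene identifiers as dimnames.
#' @export
distanceMatrix <- function(x) {
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant gene row(s): ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  D <- 1 - stats::cor(t(x))
  D[D < 0] <- 0      # guard against tiny negative rounding
  D[D > 2] <- 2
  diag(D) <- 0
  D <- (D + t(D)) / 2  # enforce exact symmetry
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}

#' Write a distance matrix as TSV
#' @param D distance matrix.
#' @param path output file.
#' @export
writeDistanceMatrix <- function(D, path) {
  utils::write.table(cbind(gene_id = rownames(D), as.data.frame(D)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Per-gene mean distance to every cluster: k x n matrix. For a gene's own
# cluster the self-distance (0) is excluded from the average.
.clusterMeanDistances <- function(labels, D, k) {
  n <- length(labels)
  sums <- matrix(0, nrow = k, ncol = n)
  sizes <- tabulate(labels, nbins = k)
  for (c in seq_len(k)) {
    members <- which(labels == c)
    sums[c, ] <- colSums(D[members, , drop = FALSE])
  }
  own <- cbind(labels, seq_len(n))
  means <- sums / sizes
  ownDen <- sizes[labels] - 1L
  means[own] <- ifelse(ownDen > 0L, sums[own] / ownDen, NA_real_)
  list(means = means, sizes = sizes)
}

#' Silhouette scores of all genes under a partition
#'
#' For gene i, `a_i` is its mean distance to the other members of its
#' cluster and `b_i` its separation from the remaining clusters;
#' `s_i = (b_i - a_i) / max(a_i, b_i)`. Genes in singleton clusters score 0
#' by convention, as do genes with `a_i = b_i = 0`.
#'
#' @param labels integer cluster labels in `1:k`, one per gene.
#' @param D distance matrix from [distanceMatrix()].
#' @param bMode how `b_i` is formed: `"nearest_other"` (standard; minimum
#'   over other clusters of the mean distance to that cluster) or
#'   `"pooled_other"` (mean distance to all genes outside i's cluster).
#' @return numeric vector of per-gene silhouettes in \[-1, 1\].
#' @export
silhouetteScores <- function(labels, D, bMode = c("nearest_other", "pooled_other")) {
  bMode <- match.arg(bMode)
  k <- max(labels)
  if (k < 2L) stop("silhouette requires at least two clusters")
  n <- length(labels)
  cm <- .clusterMeanDistances(labels, D, k)
  a <- cm$means[cbind(labels, seq_len(n))]
  if (bMode == "nearest_other") {
    b <- vapply(seq_len(n), function(i) {
      min(cm$means[-labels[i], i])
    }, numeric(1))
  } else {
    outSizes <- n - cm$sizes[labels]
    total <- colSums(D)
    ownSum <- vapply(seq_len(n), function(i) {
      sum(D[labels == labels[i], i])
    }, numeric(1))
    b <- (total - ownSum) / outSizes
  }
  s <- (b - a) / pmax(a, b)
  s[is.na(a)] <- 0          # singleton cluster convention
  s[!is.finite(s)] <- 0     # a = b = 0 (duplicated points)
  unname(s)
}

#' Silhouette score of a single gene
#'
#' @param i gene index.
#' @inheritParams silhouetteScores
#' @return silhouette of gene `i`.
#' @export
silhouetteGene <- function(i, labels, D, bMode = c("nearest_other", "pooled_other")) {
  bMode <- match.arg(bMode)
  silhouetteScores(labels, D, bMode)[i]
}

#' Mean silhouette of a partition
#'
#' Arithmetic mean of the per-gene silhouettes: the stage-1 clustering
#' fitness. Larger is better; values lie in \[-1, 1\].
#'
#' @inheritParams silhouetteScores
#' @return mean silhouette.
#' @export
meanSilhouette <- function(labels, D, bMode = c("nearest_other", "pooled_other")) {
  mean(silhouetteScores(labels, D, match.arg(bMode)))
}
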
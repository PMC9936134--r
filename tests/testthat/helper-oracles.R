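# Independent oracle implementations used for cross-checking. These are
# written straight from the definitions and never call the package's own
# computation paths.

# Silhouette straight from the definition: a_i = mean distance to the
# other members of i's cluster, b_i either the minimum over other clusters
# of the mean distance to that cluster, or the mean distance to everything
# outside i's cluster.
bruteSilhouette <- function(labels, D, bMode = "nearest_other") {
  n <- length(labels)
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) return(0)
    a <- mean(D[i, own])
    if (bMode == "nearest_other") {
      b <- min(vapply(setdiff(unique(labels), labels[i]), function(c) {
        mean(D[i, labels == c])
      }, numeric(1)))
    } else {
      b <- mean(D[i, labels != labels[i]])
    }
    if (max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
}

# Random symmetric "distance" matrix with zero diagonal, entries in [0, 2].
randomDistMatrix <- function(n) {
  D <- matrix(stats::runif(n * n, 0, 2), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("g", 1:n), paste0("g", 1:n))
  D
}

# Random labels guaranteed to use every cluster at least once.
randomLabels <- function(n, k) {
  repeat {
    l <- sample.int(k, n, replace = TRUE)
    if (length(unique(l)) == k) return(l)
  }
}

# Upper-tail hypergeometric probability by explicit enumeration of the
# favourable draws.
enumHypergeom <- function(overlap, moduleSize, termSize, backgroundSize) {
  js <- overlap:min(moduleSize, termSize)
  if (overlap > min(moduleSize, termSize)) return(0)
  sum(choose(termSize, js) * choose(backgroundSize - termSize, moduleSize - js)) /
    choose(backgroundSize, moduleSize)
}

# Benjamini-Hochberg step-up written from the definition: sort, scale by
# m/rank, enforce monotonicity from the largest p down, cap at 1, restore
# input order.
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Random DAG: term t's parents are a random subset of earlier terms
# (term 1 is the root), so acyclicity holds by construction.
randomToyDag <- function(nTerms, maxParents = 2L) {
  ids <- sprintf("T%03d", seq_len(nTerms))
  parents <- vector("list", nTerms)
  parents[[1L]] <- character(0)
  for (t in 2:nTerms) {
    np <- sample.int(maxParents, 1L)
    parents[[t]] <- ids[sample.int(t - 1L, min(np, t - 1L))]
  }
  names(parents) <- ids
  list(ids = ids, parents = parents)
}

# Ancestor closure (including self) by naive recursion over a parents list.
bruteAncestors <- function(term, parents) {
  out <- term
  for (p in parents[[term]]) out <- union(out, bruteAncestors(p, parents))
  out
}

# Lin similarity from first principles: propagate annotations through the
# brute-force closures, count genes per term, pick the common ancestor with
# the smallest probability.
bruteLin <- function(t1, t2, parents, gene2terms) {
  closures <- lapply(names(parents), function(t) bruteAncestors(t, parents))
  names(closures) <- names(parents)
  geneProp <- lapply(gene2terms, function(ts) {
    unique(unlist(closures[ts]))
  })
  total <- length(geneProp)
  pOf <- function(t) sum(vapply(geneProp, function(g) t %in% g, logical(1))) / total
  p1 <- pOf(t1); p2 <- pOf(t2)
  if (t1 == t2) return(if (p1 < 1) 1 else 0)
  common <- intersect(bruteAncestors(t1, parents), bruteAncestors(t2, parents))
  pc <- vapply(common, pOf, numeric(1))
  pc <- pc[pc > 0]
  if (!length(pc)) return(0)
  pm <- min(pc)
  if (pm >= 1) return(0)
  2 * log(pm) / (log(p1) + log(p2))
}

# All valid membership matrices under the potential-module constraints:
# per-gene non-empty subsets of its list, columns non-empty.
enumerateMemberships <- function(potential, k, geneIds) {
  allSubsets <- function(p) {
    unlist(lapply(seq_along(p), function(m) {
      utils::combn(seq_along(p), m, FUN = function(ix) p[ix], simplify = FALSE)
    }), recursive = FALSE)
  }
  subsets <- lapply(potential, allSubsets)
  grid <- do.call(expand.grid, lapply(subsets, seq_along))
  n <- length(potential)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    A <- matrix(0L, n, k, dimnames = list(geneIds, NULL))
    for (i in seq_len(n)) A[i, subsets[[i]][[grid[g, i]]]] <- 1L
    if (any(colSums(A) == 0L)) next
    out[[length(out) + 1L]] <- A
  }
  out
}

# Adjusted Rand index (mclust's implementation when available; the direct
# pair-counting formula otherwise).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(length(a), 2)
  (sumij - expected) / ((sumi + sumj) / 2 - expected)
}
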
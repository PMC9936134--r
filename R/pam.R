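#' k-means++-style medoid seeding
#'
#' First medoid uniform at random; each further medoid is drawn with
#' probability proportional to the squared distance to its nearest already
#' chosen medoid, spreading the initial medoids across the data.
#'
#' @param D distance matrix.
#' @param k number of medoids, `2 <= k <= n`.
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of k distinct gene indices.
#' @export
kmeansppSeed <- function(D, k, seed = NULL) {
  n <- nrow(D)
  if (k > n) stop("k must not exceed the number of genes")
  if (k < 1L) stop("k must be positive")
  if (!is.null(seed)) set.seed(seed)
  chosen <- sample.int(n, 1L)
  while (length(chosen) < k) {
    d2 <- apply(D[, chosen, drop = FALSE], 1L, min)^2
    d2[chosen] <- 0
    if (sum(d2) == 0) {
      cand <- setdiff(seq_len(n), chosen)
      nxt <- cand[sample.int(length(cand), 1L)]
    } else {
      nxt <- sample.int(n, 1L, prob = d2)
    }
    chosen <- c(chosen, nxt)
  }
  chosen
}

#' Assign genes to their nearest medoid
#'
#' Label of gene i is the medoid minimizing `D[i, medoid]`; ties go to the
#' medoid listed first. Medoid genes land in their own cluster.
#'
#' @param D distance matrix.
#' @param medoids integer vector of medoid gene indices.
#' @return integer labels in `1:k`.
#' @export
assignToMedoids <- function(D, medoids) {
  dm <- D[, medoids, drop = FALSE]
  labels <- apply(dm, 1L, which.min)
  as.integer(labels)
}

.dSum <- function(D, medoids, labels = NULL) {
  if (is.null(labels)) labels <- assignToMedoids(D, medoids)
  sum(D[cbind(seq_len(nrow(D)), medoids[labels])])
}

#' Partitioning around medoids with random-swap search
#'
#' Classic PAM under an arbitrary precomputed distance: after k-means++
#' seeding, each iteration proposes swapping one uniformly chosen medoid
#' for one uniformly chosen non-medoid and accepts the proposal only if it
#' strictly reduces the total within-cluster distance to medoids
#' (`d_sum`), so the `d_sum` trace is non-increasing.
#'
#' @param D distance matrix.
#' @param k cluster count.
#' @param maxIter number of swap proposals (default 2000).
#' @param seed optional integer seed.
#' @return list with `medoids`, `labels`, `dSum`, and the accepted-step
#'   trace `dSumTrace` (starting at the seeding's `d_sum`).
#' @export
pamRun <- function(D, k, maxIter = 2000L, seed = NULL) {
  n <- nrow(D)
  if (k < 2L || k > n) stop("need 2 <= k <= n")
  if (!is.null(seed)) set.seed(seed)
  medoids <- kmeansppSeed(D, k)
  best <- .dSum(D, medoids)
  trace <- best
  for (iter in seq_len(maxIter)) {
    out <- sample.int(k, 1L)
    nonMedoids <- setdiff(seq_len(n), medoids)
    cand <- medoids
    cand[out] <- nonMedoids[sample.int(length(nonMedoids), 1L)]
    dNew <- .dSum(D, cand)
    if (dNew < best) {
      medoids <- cand
      best <- dNew
      trace <- c(trace, best)
    }
  }
  labels <- assignToMedoids(D, medoids)
  list(medoids = medoids, labels = labels, dSum = best, dSumTrace = trace)
}

#' Choose the cluster count by silhouette scan
#'
#' Runs [pamRun()] for every k in `[kMin, kMax]` and keeps the k with the
#' largest mean silhouette; ties favor the smaller k.
#'
#' @param D distance matrix.
#' @param kMin,kMax scan range (defaults 8 and 20).
#' @param maxIter swap proposals per PAM run.
#' @param seed optional integer seed.
#' @param bMode silhouette separation mode, see [silhouetteScores()].
#' @return list with `k`, `medoids`, `labels`, `silhouette`, and the
#'   per-k score table `scan` (data.frame k, silhouette, dSum).
#' @export
scanK <- function(D, kMin = 8L, kMax = 20L, maxIter = 2000L, seed = NULL,
                  bMode = "nearest_other") {
  if (kMax > nrow(D)) stop("kMax must not exceed the number of genes")
  if (kMin > kMax) stop("kMin must not exceed kMax")
  if (!is.null(seed)) set.seed(seed)
  ks <- seq.int(kMin, kMax)
  runs <- vector("list", length(ks))
  scores <- numeric(length(ks))
  dsums <- numeric(length(ks))
  for (i in seq_along(ks)) {
    runs[[i]] <- pamRun(D, ks[i], maxIter = maxIter)
    scores[i] <- meanSilhouette(runs[[i]]$labels, D, bMode = bMode)
    dsums[i] <- runs[[i]]$dSum
  }
  bestIdx <- which.max(scores)  # first max: ties break to smaller k
  best <- runs[[bestIdx]]
  list(k = ks[bestIdx], medoids = best$medoids, labels = best$labels,
       silhouette = scores[bestIdx],
       scan = data.frame(k = ks, silhouette = scores, dSum = dsums))
}
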
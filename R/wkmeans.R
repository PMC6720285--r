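# Feature-weighted K-means with "anomalous cluster" (intelligent)
# initialization. Feature weights follow the Huang-style update: each
# feature's weight is inversely tied to its within-cluster dispersion, so
# noisy, uninformative slots are down-weighted. Initialization extracts
# anomalous clusters iteratively: the point farthest from the grand mean
# seeds a candidate cluster that is refined against the grand mean and then
# removed; repeated until K seeds exist.

.wk_dist <- function(X, center, w2) {
  # squared weighted Euclidean distance of every row of X to `center`
  d <- sweep(X, 2, center)
  as.vector(d^2 %*% w2)
}

# Anomalous-pattern seeding: returns a K x d matrix of initial centers.
.anomalous_init <- function(X, k) {
  grand <- colMeans(X)
  centers <- matrix(0, nrow = 0, ncol = ncol(X))
  remaining <- seq_len(nrow(X))
  w2 <- rep(1 / ncol(X), ncol(X))
  while (nrow(centers) < k && length(remaining) > 0) {
    Xr <- X[remaining, , drop = FALSE]
    far <- remaining[which.max(.wk_dist(Xr, grand, w2))]
    cand <- X[far, ]
    members <- far
    repeat {
      d_cand <- .wk_dist(Xr, cand, w2)
      d_grand <- .wk_dist(Xr, grand, w2)
      new_members <- remaining[d_cand < d_grand]
      if (length(new_members) == 0) new_members <- far
      if (setequal(new_members, members)) break
      members <- new_members
      cand <- colMeans(X[members, , drop = FALSE])
    }
    centers <- rbind(centers, cand)
    remaining <- setdiff(remaining, members)
  }
  # pad with farthest remaining points if the data exhausted early
  while (nrow(centers) < k) {
    if (length(remaining) == 0) {
      centers <- rbind(centers, centers[nrow(centers), ])
    } else {
      far <- remaining[which.max(.wk_dist(X[remaining, , drop = FALSE], grand, w2))]
      centers <- rbind(centers, X[far, ])
      remaining <- setdiff(remaining, far)
    }
  }
  unname(centers)
}

#' Feature-weighted K-means with anomalous-cluster initialization
#'
#' Clusters rows of `X` into `k` groups under a weighted squared Euclidean
#' distance whose per-feature weights are re-estimated each iteration from
#' the within-cluster dispersions (features that separate clusters cleanly
#' gain weight; noisy features lose it). Initial centers come from iterative
#' anomalous-pattern extraction rather than random seeding, so the procedure
#' is deterministic.
#'
#' @param X Numeric matrix (observations x features).
#' @param k Number of clusters (default 2: a dominant "normal" cluster plus
#'   a deviating one).
#' @param beta Weight exponent of the weighted distance (default 2).
#' @param max_iter Iteration cap (default 50).
#' @param weight_clamp Bound on how far a feature weight may deviate from
#'   uniform (weights are clipped to `[1/(clamp*d), clamp/d]` and
#'   renormalized). Behavioral slots are legitimately high-dispersion even
#'   within a homogeneous cluster (the same slot holds different activities
#'   on different days), so an unbounded inverse-dispersion update would
#'   suppress exactly the slots a behavioral change lives in; the clamp keeps
#'   the noise down-weighting while bounding that suppression.
#' @return List with `cluster` (integer assignments), `centers` (k x d),
#'   `weights` (feature weights summing to 1), `iterations`, and `withinss`.
#' @export
weighted_kmeans <- function(X, k = 2L, beta = 2, max_iter = 50L,
                            weight_clamp = 4) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= k, k >= 1)
  centers <- .anomalous_init(X, k)
  w <- rep(1 / d, d)
  assign_old <- rep(0L, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dist <- sapply(seq_len(k), function(j) .wk_dist(X, centers[j, ], w^beta))
    if (k == 1L) dist <- matrix(dist, ncol = 1L)
    cl <- max.col(-dist, ties.method = "first")
    for (j in seq_len(k))
      if (any(cl == j))
        centers[j, ] <- colMeans(X[cl == j, , drop = FALSE])
    # per-feature within-cluster dispersion
    D <- numeric(d)
    for (j in seq_len(k)) {
      mem <- which(cl == j)
      if (length(mem) > 0)
        D <- D + colSums(sweep(X[mem, , drop = FALSE], 2, centers[j, ])^2)
    }
    if (all(D <= 0)) {
      w <- rep(1 / d, d) # degenerate: constant data
    } else {
      D <- D + 1e-12 * mean(D[D > 0])
      w <- (1 / D)^(1 / (beta - 1))
      w <- w / sum(w)
      w <- pmin(pmax(w, 1 / (weight_clamp * d)), weight_clamp / d)
      w <- w / sum(w)
    }
    if (identical(cl, assign_old) || iter >= max_iter) break
    assign_old <- cl
  }
  withinss <- vapply(seq_len(k), function(j) {
    mem <- which(cl == j)
    if (length(mem) == 0) return(0)
    sum(.wk_dist(X[mem, , drop = FALSE], centers[j, ], w^beta))
  }, numeric(1))
  list(cluster = cl, centers = centers, weights = w,
       iterations = iter, withinss = withinss)
}
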
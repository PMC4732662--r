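#' K-means clustering of principal coordinates
#'
#' Clusters lines in the space of the first principal coordinates (the axes
#' returned by [pcoa()]), the standard choice for marker-based subpopulation
#' assignment: the leading coordinates concentrate the between-group signal
#' and drop the high-dimensional noise of the raw marker matrix. Runs
#' `n_restarts` independent starts and keeps the solution with the smallest
#' total within-cluster sum of squares; deterministic given `seed`.
#'
#' @param pcoa a `pcoa_result` (or a plain coordinate matrix).
#' @param k number of clusters, `2 <= k <= n`.
#' @param n_restarts independent random starts (default 50).
#' @param seed RNG seed.
#' @param axes number of leading coordinate axes to use (default: all
#'   available in `pcoa`).
#' @return object of class `cluster_solution`: `k`, `labels` (named integer
#'   vector), `centroids`, `ch_score` (Calinski-Harabasz), `tot_withinss`,
#'   `seed`.
#' @export
kmeans_cluster <- function(pcoa, k, n_restarts = 50L, seed = 1L,
                           axes = NULL) {
  coords <- if (inherits(pcoa, "pcoa_result")) pcoa$coordinates else as.matrix(pcoa)
  if (!is.null(axes)) coords <- coords[, seq_len(min(axes, ncol(coords))), drop = FALSE]
  n <- nrow(coords)
  abort_if(k < 2, "k must be at least 2")
  abort_if(k > n, "k (%d) exceeds number of lines (%d)", k, n)
  if (k == n) {
    # one point per cluster: the partition is forced and exact
    labels <- setNames(seq_len(n), rownames(coords))
    return(structure(list(k = k, labels = labels, centroids = coords,
                          ch_score = NA_real_, tot_withinss = 0,
                          seed = seed),
                     class = "cluster_solution"))
  }
  km <- with_seed(stage_seed(seed, paste0("kmeans_k", k)),
                  kmeans(coords, centers = k, nstart = n_restarts,
                         iter.max = 100L))
  labels <- setNames(km$cluster, rownames(coords))
  structure(list(k = k,
                 labels = labels,
                 centroids = km$centers,
                 ch_score = calinski_harabasz(coords, labels),
                 tot_withinss = km$tot.withinss,
                 seed = seed),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("<cluster_solution> k = %d, sizes = %s, CH = %.2f\n",
              x$k, paste(as.integer(sizes), collapse = "/"), x$ch_score))
  invisible(x)
}

#' Calinski-Harabasz index of a clustering
#'
#' `CH = (B / (k - 1)) / (W / (n - k))` where `B` is the between-cluster and
#' `W` the within-cluster sum of squared deviations about centroids. Larger
#' values indicate better-separated, more compact clusters.
#'
#' @param coords numeric matrix of coordinates (n x axes).
#' @param labels cluster assignment, one per row of `coords`.
#' @return the CH score (scalar).
#' @export
calinski_harabasz <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.integer(factor(labels))
  n <- nrow(coords)
  abort_if(length(labels) != n, "labels length != number of points")
  k <- length(unique(labels))
  abort_if(k < 2, "need at least 2 clusters")
  sizes <- tabulate(labels, nbins = k)
  abort_if(any(sizes == 0L), "empty cluster")
  grand <- colMeans(coords)
  W <- 0; B <- 0
  for (c in seq_len(k)) {
    xc <- coords[labels == c, , drop = FALSE]
    ctr <- colMeans(xc)
    W <- W + sum(sweep(xc, 2, ctr)^2)
    B <- B + sizes[c] * sum((ctr - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of clusters by the Calinski-Harabasz criterion
#'
#' Runs [kmeans_cluster()] for each `k` in `k_range` and returns the solution
#' maximising the CH index. Ties are broken toward the smallest `k`.
#'
#' @inheritParams kmeans_cluster
#' @param k_range integer vector of candidate cluster counts, each in
#'   `[2, n - 1]`.
#' @return list with `k` (selected), `solution` (the winning
#'   `cluster_solution`) and `ch_scores` (named vector over `k_range`).
#' @export
select_k <- function(pcoa, k_range = 2:8, n_restarts = 50L, seed = 1L,
                     axes = NULL) {
  abort_if(length(k_range) == 0L, "empty k_range")
  k_range <- sort(unique(as.integer(k_range)))
  sols <- lapply(k_range, function(k)
    kmeans_cluster(pcoa, k, n_restarts = n_restarts, seed = seed, axes = axes))
  ch <- vapply(sols, `[[`, numeric(1), "ch_score")
  names(ch) <- k_range
  best <- which(ch == max(ch))[1]   # smallest k on ties (k_range sorted)
  list(k = k_range[best], solution = sols[[best]], ch_scores = ch)
}
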
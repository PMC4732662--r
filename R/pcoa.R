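#' Principal coordinate analysis (classical MDS) of a distance matrix
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Coordinates are the eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Genetic distances such as Rogers' need not be
#' Euclidean, so negative eigenvalues can occur; they are excluded from both
#' the coordinates and the explained-variance denominator.
#'
#' @param dist a `distance_matrix` (from [rogers_distance()]), a [stats::dist]
#'   object, or a symmetric matrix.
#' @param n_axes number of coordinate axes to return (default 4). Truncated
#'   with a warning if fewer positive eigenvalues exist.
#' @return object of class `pcoa_result`: `coordinates` (lines x axes),
#'   `eigenvalues` (all, non-increasing), `explained_variance_pct` (per
#'   returned axis, over the positive eigenvalues).
#' @export
pcoa <- function(dist, n_axes = 4L) {
  D <- if (inherits(dist, "distance_matrix")) dist$d else as.matrix(dist)
  abort_if(nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8,
           "distance matrix must be symmetric")
  n <- nrow(D)
  abort_if(n < 2, "need at least two points")
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  ee <- eigen(B, symmetric = TRUE)
  lambda <- ee$values
  pos <- lambda > max(lambda[1], 0) * 1e-12 & lambda > 0
  n_pos <- sum(pos)
  if (n_pos == 0L) {
    warning("no positive eigenvalues; explained variance undefined, reported as 0")
    coords <- matrix(0, n, n_axes,
                     dimnames = list(rownames(D),
                                     paste0("PCo", seq_len(n_axes))))
    return(structure(list(coordinates = coords, eigenvalues = lambda,
                          explained_variance_pct = rep(0, n_axes)),
                     class = "pcoa_result"))
  }
  if (n_axes > n_pos) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes instead of %d",
                    n_pos, n_pos, n_axes))
    n_axes <- n_pos
  }
  idx <- seq_len(n_axes)
  coords <- ee$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(lambda[idx]), n_axes, n_axes)
  dimnames(coords) <- list(rownames(D), paste0("PCo", idx))
  structure(list(coordinates = coords,
                 eigenvalues = lambda,
                 explained_variance_pct = 100 * lambda[idx] / sum(lambda[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d points, %d axes; explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.2f%%", x$explained_variance_pct), collapse = ", ")))
  invisible(x)
}
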
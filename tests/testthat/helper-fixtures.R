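# Shared fixtures and small independent oracles used across test files.

withr_local_tempfile <- function(ext = "") tempfile(fileext = ext)

# Plain Rand index between two labelings (pair-counting agreement).
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  1 - (0.5 * (sum(rowSums(tab)^2) + sum(colSums(tab)^2)) - sum(tab^2)) /
    choose(n, 2)
}

# Random +/-1 genotype matrix with ids.
rand_geno <- function(n, m, seed) {
  set.seed(seed)
  matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m,
         dimnames = list(sprintf("L%03d", seq_len(n)),
                         sprintf("M%04d", seq_len(m))))
}

# Additive phenotype on a subset of markers, heritability-controlled.
# h2 = 1 gives a noiseless trait.
rand_trait <- function(X, n_qtl, h2, seed, effect_sd = 1) {
  set.seed(seed)
  qtl <- sample(ncol(X), n_qtl)
  a <- rnorm(n_qtl, 0, effect_sd)
  g <- drop(X[, qtl, drop = FALSE] %*% a)
  e <- if (h2 >= 1) 0 else rnorm(nrow(X), 0, sd(g) * sqrt((1 - h2) / h2))
  list(y = stats::setNames(g + e, rownames(X)), g = g, qtl = qtl, a = a)
}

# Small marker panel with hand-chosen calls (markers as named list of
# call vectors over the same lines).
panel_from_cols <- function(cols, line_ids = NULL) {
  m <- do.call(cbind, cols)
  if (is.null(line_ids)) line_ids <- sprintf("L%03d", seq_len(nrow(m)))
  marker_panel(m, line_ids = line_ids, marker_ids = names(cols))
}

# Independent brute-force three-rule QC recount (mirrors the documented
# order: missingness, monomorphic, MAF; first rule wins).
qc_brute_counts <- function(calls, maf_min = 0.05, max_missing = 0.20) {
  n_miss <- 0L; n_mono <- 0L; n_maf <- 0L; n_keep <- 0L
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    if (mean(is.na(x)) > max_missing) { n_miss <- n_miss + 1L; next }
    xo <- x[!is.na(x)]
    f <- mean((xo + 1) / 2); maf <- min(f, 1 - f)
    if (length(xo) == 0L || maf == 0) { n_mono <- n_mono + 1L; next }
    if (maf < maf_min) { n_maf <- n_maf + 1L; next }
    n_keep <- n_keep + 1L
  }
  list(miss = n_miss, mono = n_mono, maf = n_maf, keep = n_keep)
}

# Brute-force Calinski-Harabasz from the definition, written independently
# of the package implementation.
ch_brute <- function(coords, labels) {
  coords <- as.matrix(coords)
  labs <- unique(labels)
  n <- nrow(coords); k <- length(labs)
  grand <- colMeans(coords)
  W <- 0; B <- 0
  for (lb in labs) {
    pts <- coords[labels == lb, , drop = FALSE]
    ctr <- colMeans(pts)
    for (i in seq_len(nrow(pts))) W <- W + sum((pts[i, ] - ctr)^2)
    B <- B + nrow(pts) * sum((ctr - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# GBLUP predictions via the kinship formulation: given the variance ratio
# lambda for K0 = X X', an equivalent kinship model uses K = X X' / c with
# ratio lambda / c. Independent route used to cross-check marker-space
# predictions.
gblup_predict <- function(y, X_train, X_new, lambda, c_scale = 1) {
  K <- tcrossprod(X_train) / c_scale
  Knew <- X_new %*% t(X_train) / c_scale
  n <- length(y)
  H <- K + (lambda / c_scale) * diag(n)
  Hi <- solve(H)
  one <- rep(1, n)
  mu <- drop((t(one) %*% Hi %*% y) / (t(one) %*% Hi %*% one))
  g <- drop(Knew %*% Hi %*% (y - mu))
  mu + g
}
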
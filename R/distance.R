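#' Rogers genetic distances among inbred lines
#'
#' For each pair of lines the per-locus Euclidean distance between their
#' within-individual allele-frequency vectors is averaged over loci:
#' `D(i,j) = (1/m) * sum_l sqrt(0.5 * sum_u (p_ilu - p_jlu)^2)`. With
#' additive coding a homozygote contributes frequencies `{1, 0}` and an
#' imputed intermediate value `x` contributes `{(1+x)/2, (1-x)/2}`, so the
#' per-locus term reduces to `|x_i - x_j| / 2` and the distance is bounded
#' in `[0, 1]`: 0 for identical lines, 1 for opposite homozygotes at every
#' locus.
#'
#' @param genotypes a [genotype_matrix()] (coded, imputed) or numeric matrix
#'   with values in `[-1, 1]` and no `NA`.
#' @return an object of class `distance_matrix`: list with `line_ids` and the
#'   symmetric matrix `d`.
#' @export
rogers_distance <- function(genotypes) {
  X <- coded_matrix(genotypes)
  abort_if(ncol(X) == 0L, "cannot compute distances on 0 markers")
  abort_if(anyNA(X), "genotype matrix contains NA; impute first")
  abort_if(max(abs(X)) > 1 + 1e-12, "coded values must lie in [-1, 1]")
  D <- rogers_dist_cpp(t(X))
  dimnames(D) <- list(rownames(X), rownames(X))
  structure(list(line_ids = rownames(X), d = D), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d lines, Rogers distance range [%.3f, %.3f]\n",
              nrow(x$d), min(x$d[upper.tri(x$d)]), max(x$d)))
  invisible(x)
}
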
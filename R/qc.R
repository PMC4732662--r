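#' Minor-allele frequency of a marker
#'
#' Frequencies are computed on non-missing calls only, counting two alleles
#' per (diploid, inbred) line: a `+1` call contributes two copies of the
#' "plus" allele, `0` one copy, `-1` none. The minor-allele convention
#' `min(f, 1 - f)` is applied, so the result lies in `[0, 0.5]`.
#'
#' @param panel a [marker_panel()] (or coded matrix).
#' @param marker marker id or column index. Omit to get all markers at once.
#' @return frequency (or named vector of frequencies). An all-missing marker
#'   yields `NA` with a warning.
#' @export
allele_frequency <- function(panel, marker = NULL) {
  m <- if (inherits(panel, "marker_panel")) panel$calls else as.matrix(panel)
  if (!is.null(marker)) {
    abort_if(is.character(marker) && !(marker %in% colnames(m)),
             "marker '%s' not in panel", marker)
    x <- m[, marker]
    if (all(is.na(x))) {
      warning("marker has no non-missing calls; frequency undefined")
      return(NA_real_)
    }
    f <- mean((x + 1) / 2, na.rm = TRUE)
    return(min(f, 1 - f))
  }
  f <- colMeans((m + 1) / 2, na.rm = TRUE)
  out <- pmin(f, 1 - f)
  allna <- colSums(!is.na(m)) == 0L
  if (any(allna)) {
    warning(sprintf("%d marker(s) have no non-missing calls", sum(allna)))
    out[allna] <- NA_real_
  }
  out
}

#' Marker quality control: missingness, monomorphism, MAF, mean imputation
#'
#' Applies, in order: (1) removal of markers with a missing-call fraction
#' strictly greater than `max_missing`; (2) removal of monomorphic markers
#' (no allelic variation among non-missing calls); (3) removal of markers
#' with minor-allele frequency strictly below `maf_min` (MAF on non-missing
#' calls). Each marker is attributed to the first rule that removes it.
#' Remaining missing calls are replaced by the marker's mean coded value,
#' which preserves every marker's mean exactly. Lines are never filtered.
#'
#' @param panel a [marker_panel()].
#' @param maf_min minimum minor-allele frequency (default 0.05); markers at
#'   exactly the threshold are retained.
#' @param max_missing maximum missing fraction (default 0.20); markers at
#'   exactly the threshold are retained.
#' @return list with `genotypes` ([genotype_matrix()]) and `report`
#'   (`qc_report`: per-stage removal counts and thresholds).
#' @export
qc_pipeline <- function(panel, maf_min = 0.05, max_missing = 0.20) {
  if (inherits(panel, "genotype_matrix")) {
    # re-applying QC to an already coded/imputed matrix (idempotence check):
    # imputed real values are legal here, missingness is zero by construction
    panel <- structure(list(line_ids = panel$line_ids,
                            marker_ids = panel$marker_ids,
                            calls = panel$coded),
                       class = "marker_panel")
  }
  stopifnot(inherits(panel, "marker_panel"))
  calls <- panel$calls
  n_input <- ncol(calls)
  abort_if(n_input == 0L, "empty panel")

  miss_frac <- colMeans(is.na(calls))
  keep1 <- miss_frac <= max_missing
  abort_if(!any(keep1),
           "QC removed every marker at the missingness stage (> %g missing)",
           max_missing)
  calls1 <- calls[, keep1, drop = FALSE]

  # all-missing markers that slip past stage 1 (max_missing = 1) count as
  # monomorphic: they carry no allelic information
  nonmiss <- colSums(!is.na(calls1))
  maf1 <- suppressWarnings(allele_frequency(calls1))
  mono <- nonmiss == 0L | (!is.na(maf1) & maf1 == 0)
  abort_if(all(mono),
           "QC removed every marker at the monomorphic stage")
  calls2 <- calls1[, !mono, drop = FALSE]
  maf2 <- maf1[!mono]

  keep3 <- maf2 >= maf_min
  abort_if(!any(keep3),
           "QC removed every marker at the MAF stage (< %g)", maf_min)
  calls3 <- calls2[, keep3, drop = FALSE]
  maf3 <- maf2[keep3]

  coded <- impute_marker_means(calls3)

  report <- structure(list(
    n_input_markers = n_input,
    n_removed_missingness = sum(!keep1),
    n_removed_monomorphic = sum(mono),
    n_removed_maf = sum(!keep3),
    n_retained = ncol(coded),
    maf_min = maf_min,
    max_missing = max_missing), class = "qc_report")
  stopifnot(report$n_input_markers - report$n_removed_missingness -
              report$n_removed_monomorphic - report$n_removed_maf ==
              report$n_retained)

  list(genotypes = genotype_matrix(coded, allele_freqs = maf3),
       report = report)
}

# Replace NA entries of each column by that column's non-missing mean.
impute_marker_means <- function(m) {
  if (!anyNA(m)) return(m)
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 2]]
  m
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<qc_report> %d markers in\n",
    "  removed: %d missingness (> %g), %d monomorphic, %d MAF (< %g)\n",
    "  retained: %d\n"),
    x$n_input_markers, x$n_removed_missingness, x$max_missing,
    x$n_removed_monomorphic, x$n_removed_maf, x$maf_min, x$n_retained))
  invisible(x)
}
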
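#' Construct a raw marker panel
#'
#' A marker panel holds raw biallelic SNP calls for a set of inbred lines in
#' additive coding: `-1` and `+1` for the two homozygotes, `0` for a
#' heterozygote, `NA` for a missing call. Rows are lines, columns markers.
#'
#' @param calls numeric matrix (lines x markers) with values in
#'   `{-1, 0, 1, NA}`.
#' @param line_ids,marker_ids optional identifiers; taken from `dimnames(calls)`
#'   when omitted.
#' @return an object of class `marker_panel`.
#' @export
marker_panel <- function(calls, line_ids = rownames(calls),
                         marker_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(line_ids)) line_ids <- sprintf("L%04d", seq_len(nrow(calls)))
  if (is.null(marker_ids)) marker_ids <- sprintf("M%05d", seq_len(ncol(calls)))
  abort_if(length(line_ids) != nrow(calls), "line_ids length != nrow(calls)")
  abort_if(length(marker_ids) != ncol(calls), "marker_ids length != ncol(calls)")
  abort_if(anyDuplicated(line_ids) > 0, "duplicate line ids")
  abort_if(anyDuplicated(marker_ids) > 0, "duplicate marker ids")
  bad <- !is.na(calls) & !(calls %in% c(-1, 0, 1))
  abort_if(any(bad), "calls must be in {-1, 0, 1, NA}; %d invalid entries",
           sum(bad))
  dimnames(calls) <- list(line_ids, marker_ids)
  structure(list(line_ids = as.character(line_ids),
                 marker_ids = as.character(marker_ids),
                 calls = calls),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d lines x %d markers, %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Construct a coded, imputed genotype matrix
#'
#' The quality-controlled form of a [marker_panel()]: no missing entries
#' (mean-imputed), no monomorphic markers, per-marker minor-allele frequencies
#' attached. This is the `X` of the RR-BLUP model.
#'
#' @param coded numeric matrix (lines x markers), imputed, no `NA`.
#' @param allele_freqs per-marker minor-allele frequency (computed on the
#'   non-missing calls before imputation).
#' @param line_ids,marker_ids identifiers, defaulting to `dimnames(coded)`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(coded, allele_freqs,
                            line_ids = rownames(coded),
                            marker_ids = colnames(coded)) {
  coded <- as.matrix(coded)
  storage.mode(coded) <- "double"
  abort_if(anyNA(coded), "coded genotype matrix must not contain NA")
  abort_if(length(allele_freqs) != ncol(coded),
           "allele_freqs length != number of markers")
  dimnames(coded) <- list(line_ids, marker_ids)
  structure(list(line_ids = as.character(line_ids),
                 marker_ids = as.character(marker_ids),
                 coded = coded,
                 allele_freqs = as.numeric(allele_freqs)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers (imputed), MAF range [%.3f, %.3f]\n",
              nrow(x$coded), ncol(x$coded),
              min(x$allele_freqs), max(x$allele_freqs)))
  invisible(x)
}

#' Read / write genotype matrices as TSV
#'
#' Dialect: tab-separated, header row of marker ids, first column `line_id`,
#' empty fields or `NA` for missing calls.
#'
#' @param path file path.
#' @return `read_genotypes` returns a [marker_panel()].
#' @export
read_genotypes <- function(path) {
  abort_if(!file.exists(path), "genotype file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  abort_if(ncol(df) < 2, "genotype TSV needs a line_id column plus markers")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  marker_panel(m, line_ids = ids, marker_ids = colnames(df)[-1])
}

#' @param x a `marker_panel` or `genotype_matrix` (or plain matrix).
#' @rdname read_genotypes
#' @export
write_genotypes <- function(x, path) {
  m <- if (inherits(x, "marker_panel")) x$calls
       else if (inherits(x, "genotype_matrix")) x$coded
       else as.matrix(x)
  df <- data.frame(line_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: pull the coded matrix out of whatever genotype container is passed.
coded_matrix <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) return(genotypes$coded)
  if (inherits(genotypes, "marker_panel")) {
    abort_if(anyNA(genotypes$calls),
             "marker panel contains missing calls; run qc_pipeline() first")
    return(genotypes$calls)
  }
  as.matrix(genotypes)
}
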
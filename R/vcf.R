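#' Import biallelic SNPs from a VCF file
#'
#' Maps GT fields to additive coding: homozygous reference to `-1`,
#' heterozygous to `0`, homozygous alternate to `+1`, missing (`./.`) to
#' `NA`. Multi-allelic records are skipped; the skip count is attached as
#' attribute `n_skipped_multiallelic` and reported via a message.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return a [marker_panel()] (lines = samples, markers = records).
#' @export
import_vcf <- function(path) {
  abort_if(!file.exists(path), "VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0L) {
    message("empty VCF body: 0 markers imported")
    p <- marker_panel(matrix(numeric(0), nrow = 0, ncol = 0,
                             dimnames = list(NULL, NULL)),
                      line_ids = character(0), marker_ids = character(0))
    attr(p, "n_skipped_multiallelic") <- 0L
    return(p)
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  n_skip <- sum(multi)
  if (n_skip > 0)
    message(sprintf("skipped %d multi-allelic record(s)", n_skip))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  ids <- fix[!multi, "ID"]
  pos_ids <- paste0(fix[!multi, "CHROM"], ":", fix[!multi, "POS"])
  ids[is.na(ids) | ids == "."] <- pos_ids[is.na(ids) | ids == "."]

  # additive coding on two alleles: (# alt) - 1 maps 0/0->-1, 0/1->0, 1/1->+1
  code1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(as.integer(al) > 0) - 1
  }
  calls <- t(apply(gt, c(1, 2), code1))   # samples x markers
  dimnames(calls) <- list(colnames(gt), ids)
  p <- marker_panel(calls)
  attr(p, "n_skipped_multiallelic") <- n_skip
  p
}
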
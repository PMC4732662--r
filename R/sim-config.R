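#' Configuration for the synthetic testcross study generator
#'
#' Defaults emulate a diverse spring-type canola pollinator panel evaluated as
#' testcrosses: 475 fully inbred lines in three subpopulations of 286/147/42,
#' ~24k biallelic array markers, two male-sterile testers, four field
#' locations, a largely additive (GCA-dominated) genetic architecture and a
#' broad-sense heritability that can be dialled per trait (real traits in such
#' trials span roughly 0.3-0.9).
#'
#' @param n_lines number of inbred pollinator lines.
#' @param subpop_sizes integer vector of subpopulation sizes; must sum to
#'   `n_lines`.
#' @param n_markers number of biallelic markers.
#' @param fst Balding-Nichols divergence parameter per subpopulation, in
#'   `[0, 1)`. `0` means no systematic divergence. May be a single value or
#'   one per subpopulation.
#' @param n_qtl number of causal markers per trait.
#' @param qtl_effect_sd standard deviation of additive QTL effects
#'   (trait units per allele substitution).
#' @param h2_target broad-sense heritability on an n-location trial-mean
#'   basis, in `(0, 1]`; the residual variance is calibrated to realise it.
#' @param n_testers number of testers (default 2).
#' @param n_locations number of field locations (default 4).
#' @param sca_variance_fraction specific-combining-ability variance as a
#'   fraction of the pollinator GCA variance. The generator default (0.1)
#'   reflects the empirical finding that GCA variance dominates SCA variance
#'   in canola testcrosses.
#' @param missing_rate fraction of genotype calls set missing, in `[0, 1)`.
#'   Default 0.02, a typical post-calling array missing rate.
#' @param trait trait name attached to simulated phenotype records.
#' @param trait_mean overall trait mean `mu` (trait units).
#' @param seed master RNG seed; every stage derives its own stream via
#'   [stage_seed()].
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_lines = 475L,
                       subpop_sizes = c(286L, 147L, 42L),
                       n_markers = 24403L,
                       fst = 0.15,
                       n_qtl = 100L,
                       qtl_effect_sd = 1,
                       h2_target = 0.7,
                       n_testers = 2L,
                       n_locations = 4L,
                       sca_variance_fraction = 0.1,
                       missing_rate = 0.02,
                       trait = "trait",
                       trait_mean = 0,
                       seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines),
              subpop_sizes = as.integer(subpop_sizes),
              n_markers = as.integer(n_markers),
              fst = as.numeric(fst),
              n_qtl = as.integer(n_qtl),
              qtl_effect_sd = as.numeric(qtl_effect_sd),
              h2_target = as.numeric(h2_target),
              n_testers = as.integer(n_testers),
              n_locations = as.integer(n_locations),
              sca_variance_fraction = as.numeric(sca_variance_fraction),
              missing_rate = as.numeric(missing_rate),
              trait = as.character(trait),
              trait_mean = as.numeric(trait_mean),
              seed = as.integer(seed))
  abort_if(sum(cfg$subpop_sizes) != cfg$n_lines,
           "subpop_sizes sum to %d but n_lines is %d",
           sum(cfg$subpop_sizes), cfg$n_lines)
  abort_if(any(cfg$fst < 0 | cfg$fst >= 1), "fst must lie in [0, 1)")
  abort_if(!(length(cfg$fst) %in% c(1L, length(cfg$subpop_sizes))),
           "fst must be length 1 or one value per subpopulation")
  abort_if(cfg$n_qtl > cfg$n_markers, "n_qtl (%d) exceeds n_markers (%d)",
           cfg$n_qtl, cfg$n_markers)
  abort_if(cfg$h2_target <= 0 || cfg$h2_target > 1,
           "h2_target must lie in (0, 1]")
  abort_if(cfg$missing_rate < 0 || cfg$missing_rate >= 1,
           "missing_rate must lie in [0, 1)")
  abort_if(cfg$n_testers < 1 || cfg$n_locations < 1,
           "need at least one tester and one location")
  abort_if(cfg$sca_variance_fraction < 0,
           "sca_variance_fraction must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}
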
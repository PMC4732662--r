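#' Simulate structured inbred genotypes with a known trait architecture
#'
#' Draws per-subpopulation allele frequencies from a Balding-Nichols beta
#' model around a shared ancestral frequency in `[0.1, 0.9]`, then samples
#' fully homozygous lines (calls `-1`/`+1`; heterozygous `0` only ever arises
#' later from mean imputation). A trait architecture (QTL positions, additive
#' effects and per-line true breeding values) is drawn alongside, and missing
#' calls are injected at `missing_rate` after truth is computed.
#'
#' @param config a [sim_config()].
#' @return a list of class `geno_sim` with elements
#'   \describe{
#'     \item{panel}{[marker_panel()] with missingness injected,}
#'     \item{truth}{`truth_record`: `qtl_indices`, `qtl_effects`, `true_gca`
#'       (centred breeding values), `subpop_labels`, `true_h2` (filled in by
#'       [simulate_testcross_phenotypes()]),}
#'     \item{complete}{the complete (pre-missingness) call matrix, kept so
#'       further trait architectures can be drawn on the same genotypes,}
#'     \item{config}{the configuration used.}
#'   }
#' @seealso [simulate_testcross_phenotypes()], [draw_trait_truth()]
#' @export
simulate_structured_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines; m <- config$n_markers
  sizes <- config$subpop_sizes
  k <- length(sizes)
  fst <- rep_len(config$fst, k)

  X <- with_seed(stage_seed(config$seed, "genotypes"), {
    p_anc <- runif(m, 0.1, 0.9)
    X <- matrix(NA_real_, n, m)
    row0 <- 0L
    for (s in seq_len(k)) {
      p_s <- if (fst[s] == 0) p_anc else {
        f <- fst[s]
        ps <- rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
        pmin(pmax(ps, 0), 1)
      }
      ns <- sizes[s]
      u <- matrix(runif(ns * m), ns, m)
      X[row0 + seq_len(ns), ] <- ifelse(u < rep(p_s, each = ns), 1, -1)
      row0 <- row0 + ns
    }
    X
  })
  rownames(X) <- sprintf("L%04d", seq_len(n))
  colnames(X) <- sprintf("M%05d", seq_len(m))

  truth <- draw_truth_from_complete(X, config, stream = "qtl")
  truth$subpop_labels <- setNames(rep(seq_len(k), sizes), rownames(X))

  calls <- X
  if (config$missing_rate > 0) {
    calls <- with_seed(stage_seed(config$seed, "missingness"), {
      calls[runif(length(calls)) < config$missing_rate] <- NA_real_
      calls
    })
  }

  structure(list(panel = marker_panel(calls),
                 truth = truth,
                 complete = X,
                 config = config),
            class = "geno_sim")
}

# Internal: sample a QTL architecture and the implied centred breeding values
# from a complete (no-NA) +/-1 call matrix.
draw_truth_from_complete <- function(X, config, stream) {
  with_seed(stage_seed(config$seed, stream), {
    qtl <- sort(sample.int(ncol(X), config$n_qtl))
    a <- rnorm(config$n_qtl, 0, config$qtl_effect_sd)
    g <- drop(X[, qtl, drop = FALSE] %*% a)
    structure(list(qtl_indices = qtl,
                   qtl_effects = a,
                   true_gca = setNames(g - mean(g), rownames(X)),
                   true_h2 = NA_real_,
                   subpop_labels = NULL),
              class = "truth_record")
  })
}

#' Draw an additional trait architecture on existing simulated genotypes
#'
#' Used for multi-trait studies: each trait gets its own QTL sample and
#' effects on the same genotype matrix, under its own named RNG stream.
#'
#' @param sim a `geno_sim` from [simulate_structured_genotypes()].
#' @param config a [sim_config()] (typically the sim's config with a new
#'   `trait`, `h2_target` etc.).
#' @return a `truth_record`.
#' @export
draw_trait_truth <- function(sim, config) {
  stopifnot(inherits(sim, "geno_sim"), inherits(config, "sim_config"))
  truth <- draw_truth_from_complete(sim$complete, config,
                                    stream = paste0("qtl_", config$trait))
  truth$subpop_labels <- sim$truth$subpop_labels
  truth
}

#' Simulate multi-location testcross phenotypes
#'
#' Generates one record per (pollinator, tester, location):
#' `y = mu + GCA_p + T_t + SCA_pt + L_l + e`, where `GCA_p` is the
#' pollinator's simulated breeding value, tester and location effects are
#' fixed offsets (nuisance parameters to be absorbed by BLUE estimation),
#' `SCA_pt ~ N(0, sca_variance_fraction * var(GCA_p))`, and the per-plot
#' residual variance is calibrated against the realised hybrid genetic
#' variance so that the broad-sense heritability on the n-location mean
#' basis, `H2 = s2_g / (s2_g + s2_e / n)`, equals `h2_target` exactly.
#'
#' @param genotypes a `geno_sim` or [marker_panel()] (line ids only are used).
#' @param truth a `truth_record` matching the genotypes.
#' @param config a [sim_config()].
#' @return list with `trials` (long-format data frame: `pollinator`, `tester`,
#'   `location`, `trait`, `value`) and `truth` (input truth with `true_h2`,
#'   `sigma2_g`, `sigma2_e` recorded).
#' @export
simulate_testcross_phenotypes <- function(genotypes, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_record"))
  abort_if(config$h2_target <= 0, "h2_target must be positive")
  line_ids <- if (inherits(genotypes, "geno_sim")) genotypes$panel$line_ids
              else if (inherits(genotypes, "marker_panel")) genotypes$line_ids
              else rownames(genotypes)
  abort_if(!identical(sort(line_ids), sort(names(truth$true_gca))),
           "truth does not match genotypes (line ids differ)")

  gca <- truth$true_gca[line_ids]
  n <- length(gca)
  Tn <- config$n_testers; Ln <- config$n_locations
  sd_g <- sd(gca)
  if (!is.finite(sd_g) || sd_g == 0) sd_g <- 1
  tester_eff <- (seq_len(Tn) - (Tn + 1) / 2) * 0.5 * sd_g
  loc_eff <- (seq_len(Ln) - (Ln + 1) / 2) * 1.0 * sd_g

  out <- with_seed(stage_seed(config$seed, paste0("pheno_", config$trait)), {
    sca_var <- config$sca_variance_fraction * var(gca)
    sca <- matrix(rnorm(n * Tn, 0, sqrt(sca_var)), n, Tn)
    G <- outer(gca, tester_eff, `+`) + sca          # hybrid genetic values
    sigma2_g <- var(as.vector(G))
    h2 <- config$h2_target
    sigma2_e <- if (h2 >= 1) 0 else Ln * sigma2_g * (1 - h2) / h2
    eps <- array(rnorm(n * Tn * Ln, 0, sqrt(sigma2_e)), dim = c(n, Tn, Ln))
    list(G = G, sigma2_g = sigma2_g, sigma2_e = sigma2_e, eps = eps)
  })

  idx <- expand.grid(p = seq_len(n), t = seq_len(Tn), l = seq_len(Ln))
  value <- config$trait_mean + out$G[cbind(idx$p, idx$t)] +
    loc_eff[idx$l] + out$eps[cbind(idx$p, idx$t, idx$l)]
  trials <- data.frame(pollinator = line_ids[idx$p],
                       tester = sprintf("T%d", idx$t),
                       location = sprintf("Loc%d", idx$l),
                       trait = config$trait,
                       value = value,
                       stringsAsFactors = FALSE)

  truth$sigma2_g <- out$sigma2_g
  truth$sigma2_e <- out$sigma2_e
  truth$true_h2 <- out$sigma2_g / (out$sigma2_g + out$sigma2_e / Ln)
  list(trials = trials, truth = truth)
}

#' Write simulated study artefacts to plain-text files
#'
#' @param sim a `geno_sim`.
#' @param trials long-format phenotype data frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_sim_study <- function(sim, trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gfile <- file.path(dir, "genotypes.tsv")
  pfile <- file.path(dir, "phenotypes.csv")
  tfile <- file.path(dir, "truth.json")
  write_genotypes(sim$panel, gfile)
  write.table(trials, pfile, sep = ",", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(seed = sim$config$seed,
         qtl_indices = truth$qtl_indices,
         qtl_effects = truth$qtl_effects,
         true_gca = as.list(truth$true_gca),
         true_h2 = truth$true_h2,
         subpop_labels = as.list(truth$subpop_labels)),
    tfile, auto_unbox = TRUE, digits = NA)
  invisible(c(gfile, pfile, tfile))
}
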
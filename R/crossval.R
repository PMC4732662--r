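#' Genomic prediction accuracy
#'
#' The Pearson correlation `r(y, y_hat)` between predicted and observed
#' values in a validation set.
#'
#' @param predicted,observed aligned numeric vectors, length >= 3.
#' @return the correlation, or `NA` (with a warning) when either vector has
#'   zero variance.
#' @export
accuracy <- function(predicted, observed) {
  abort_if(length(predicted) != length(observed),
           "predicted and observed differ in length")
  abort_if(length(predicted) < 3, "need at least 3 pairs")
  if (var(predicted) == 0 || var(observed) == 0) {
    warning("zero variance; prediction accuracy undefined")
    return(NA_real_)
  }
  cor(predicted, observed)
}

#' Specification of a cross-validation scenario
#'
#' @param name one of `"whole_population"`, `"within_cluster"`,
#'   `"cross_cluster_train"`, `"structure_covariate"`.
#' @param target_cluster cluster id for the within/cross variants.
#' @param tp_fraction training-population fraction, strictly in `(0, 1)`
#'   (default 0.70).
#' @param n_rounds number of random cross-validation rounds (default 500).
#' @param seed master seed; each round derives its own stream.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(name = c("whole_population", "within_cluster",
                                   "cross_cluster_train",
                                   "structure_covariate"),
                          target_cluster = NULL,
                          tp_fraction = 0.70,
                          n_rounds = 500L,
                          seed = 1L) {
  name <- match.arg(name)
  abort_if(tp_fraction <= 0 || tp_fraction >= 1,
           "tp_fraction must lie strictly in (0, 1)")
  abort_if(!is_count(n_rounds), "n_rounds must be a positive integer")
  if (name %in% c("within_cluster", "cross_cluster_train"))
    abort_if(is.null(target_cluster),
             "scenario '%s' needs a target_cluster", name)
  structure(list(name = name, target_cluster = target_cluster,
                 tp_fraction = tp_fraction, n_rounds = as.integer(n_rounds),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# Per-round seed, re-derivable in isolation from the master seed.
round_seed <- function(master, round) stage_seed(master, paste0("round_", round))

#' Repeated random-split cross-validation of RR-BLUP prediction
#'
#' Per round: draw a training population of `round(tp_fraction * N)` lines
#' uniformly without replacement from the sampling frame, fit the RR-BLUP
#' model on it, predict the held-out validation lines, and record the
#' prediction accuracy [accuracy()]. Rounds whose validation correlation is
#' undefined (zero variance) are excluded from the mean and counted.
#'
#' @param gca a `gca_table` (or named numeric vector of per-line response
#'   values — GCAs or BLUEs).
#' @param genotypes a [genotype_matrix()] covering those lines.
#' @param spec a [scenario_spec()]; for plain `run_cv` only `tp_fraction`,
#'   `n_rounds` and `seed` are used and the frame is all shared lines.
#' @param frame optional character vector restricting the lines sampled
#'   (defaults to all lines shared between `gca` and `genotypes`).
#' @param vp_frame optional character vector: validation lines are the
#'   members of `vp_frame` not drawn into the training set (defaults to
#'   `frame`). Used by the cross-subpopulation scenario.
#' @param tp_size optional explicit training-set size overriding
#'   `round(tp_fraction * length(frame))`.
#' @param covariates optional per-line fixed covariate matrix (rows named by
#'   line id) passed through to [fit_rrblup()].
#' @return a `cv_result`: `trait`, `scenario`, `accuracies` (per round, `NA`
#'   for excluded rounds), `mean_r_gpa`, `se` (sd of the retained round
#'   accuracies over the square root of their count), `n_rounds`,
#'   `n_excluded`, `seed`.
#' @export
run_cv <- function(gca, genotypes, spec, frame = NULL, vp_frame = NULL,
                   tp_size = NULL, covariates = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  y_all <- gca_vector(gca)
  X_all <- coded_matrix(genotypes)
  shared <- intersect(names(y_all), rownames(X_all))
  abort_if(length(shared) < 10,
           "only %d lines shared between phenotypes and genotypes",
           length(shared))
  if (is.null(frame)) frame <- shared
  abort_if(!all(frame %in% shared), "frame contains lines without data")
  if (is.null(vp_frame)) vp_frame <- frame
  n_frame <- length(frame)
  if (is.null(tp_size)) tp_size <- round(spec$tp_fraction * n_frame)
  abort_if(tp_size < 3 || tp_size >= n_frame + length(setdiff(vp_frame, frame)),
           "training size %d leaves no usable split", tp_size)

  sample_from <- union(frame, character(0))
  acc <- rep(NA_real_, spec$n_rounds)
  n_excluded <- 0L
  for (r in seq_len(spec$n_rounds)) {
    tp <- with_seed(round_seed(spec$seed, r),
                    sample(sample_from, size = tp_size))
    vp <- setdiff(vp_frame, tp)
    abort_if(length(vp) < 3,
             "validation population smaller than 3 (round %d)", r)
    fit <- fit_rrblup(y_all[tp], X_all[tp, , drop = FALSE],
                      covariates = if (is.null(covariates)) NULL
                                   else covariates[tp, , drop = FALSE])
    pred <- predict(fit, X_all[vp, , drop = FALSE],
                    covariates_new = if (is.null(covariates)) NULL
                                     else covariates[vp, , drop = FALSE])
    a <- withCallingHandlers(
      accuracy(pred$predicted, y_all[vp]),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(a)) n_excluded <- n_excluded + 1L else acc[r] <- a
  }
  ok <- !is.na(acc)
  structure(list(trait = attr(gca, "trait", exact = TRUE) %||%
                   (if (inherits(gca, "gca_table")) gca$trait[1] else NA_character_),
                 scenario = spec$name,
                 accuracies = acc,
                 mean_r_gpa = mean(acc[ok]),
                 se = sd(acc[ok]) / sqrt(sum(ok)),
                 n_rounds = spec$n_rounds,
                 n_excluded = n_excluded,
                 seed = spec$seed),
            class = "cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s: mean r_GPA = %.3f +/- %.3f (%d rounds, %d excluded)\n",
              x$scenario, x$trait %||% "?", x$mean_r_gpa, x$se,
              x$n_rounds, x$n_excluded))
  invisible(x)
}

#' Run one of the prediction scenarios
#'
#' * `whole_population`: training and validation both drawn from all lines.
#' * `within_cluster`: both restricted to the target cluster (refused for
#'   clusters of fewer than 15 lines — too small for a meaningful split).
#' * `cross_cluster_train`: training drawn from the whole population,
#'   validation restricted to target-cluster lines not drawn; the training
#'   size is matched to the corresponding within-cluster scenario so the two
#'   are size-comparable.
#' * `structure_covariate`: whole-population split with cluster-membership
#'   indicator columns added as fixed covariates to fit and prediction.
#'
#' @inheritParams run_cv
#' @param spec a [scenario_spec()].
#' @param clusters a `cluster_solution` (or named label vector) covering all
#'   lines.
#' @return a `cv_result`.
#' @export
run_scenario <- function(spec, gca, genotypes, clusters) {
  stopifnot(inherits(spec, "scenario_spec"))
  labels <- if (inherits(clusters, "cluster_solution")) clusters$labels
            else clusters
  y_all <- gca_vector(gca)
  X_ids <- rownames(coded_matrix(genotypes))
  shared <- intersect(names(y_all), X_ids)
  abort_if(!all(shared %in% names(labels)),
           "cluster labels do not cover all lines")
  labels <- labels[shared]

  if (spec$name == "whole_population")
    return(run_cv(gca, genotypes, spec))

  if (spec$name == "within_cluster") {
    members <- shared[labels == spec$target_cluster]
    abort_if(length(members) == 0, "cluster '%s' not found or empty",
             spec$target_cluster)
    abort_if(length(members) < 15,
             "cluster '%s' has only %d lines; too small for within-cluster prediction",
             spec$target_cluster, length(members))
    return(run_cv(gca, genotypes, spec, frame = members))
  }

  if (spec$name == "cross_cluster_train") {
    members <- shared[labels == spec$target_cluster]
    abort_if(length(members) < 15,
             "cluster '%s' has only %d lines; too small for validation",
             spec$target_cluster, length(members))
    tp_size <- round(spec$tp_fraction * length(members))
    return(run_cv(gca, genotypes, spec, frame = shared,
                  vp_frame = members, tp_size = tp_size))
  }

  # structure_covariate
  Z <- model.matrix(~ factor(labels))[, -1, drop = FALSE]
  colnames(Z) <- paste0("cluster_", sort(unique(labels))[-1])
  rownames(Z) <- shared
  run_cv(gca, genotypes, spec, covariates = Z)
}

#' Training-population size sweep
#'
#' Repeats [run_cv()] for each training fraction, with an independent seed
#' stream per fraction derived from the master seed, and returns the
#' accuracy-versus-fraction curve.
#'
#' @inheritParams run_cv
#' @param fractions training fractions (default `seq(0.1, 0.9, by = 0.1)`).
#' @param n_rounds rounds per fraction.
#' @param seed master seed.
#' @return a `tp_sweep` list: `curve` (data frame `fraction`, `mean_r_gpa`,
#'   `se`) and `results` (per-fraction `cv_result`s). Fractions that leave a
#'   validation set smaller than 3 are skipped with a warning.
#' @export
tp_sweep <- function(gca, genotypes, fractions = seq(0.1, 0.9, by = 0.1),
                     n_rounds = 100L, seed = 1L) {
  abort_if(any(fractions <= 0 | fractions >= 1),
           "fractions must lie strictly in (0, 1)")
  y_all <- gca_vector(gca)
  X_ids <- rownames(coded_matrix(genotypes))
  n <- length(intersect(names(y_all), X_ids))
  results <- list()
  for (f in fractions) {
    if (n - round(f * n) < 3) {
      warning(sprintf("fraction %.2f leaves a validation set < 3; skipped", f))
      next
    }
    spec <- scenario_spec("whole_population", tp_fraction = f,
                          n_rounds = n_rounds,
                          seed = stage_seed(seed, sprintf("frac_%d",
                                                          round(100 * f))))
    results[[sprintf("%.2f", f)]] <- run_cv(gca, genotypes, spec)
  }
  curve <- data.frame(
    fraction = as.numeric(names(results)),
    mean_r_gpa = vapply(results, `[[`, numeric(1), "mean_r_gpa"),
    se = vapply(results, `[[`, numeric(1), "se"),
    row.names = NULL)
  structure(list(curve = curve, results = results), class = "tp_sweep")
}

# Internal: accept a gca_table, a blue-style table, or a named vector.
gca_vector <- function(gca) {
  if (inherits(gca, "gca_table") ||
      (is.data.frame(gca) && all(c("pollinator", "gca") %in% names(gca)))) {
    v <- setNames(gca$gca, gca$pollinator)
    attr(v, "trait") <- if ("trait" %in% names(gca)) gca$trait[1] else NA_character_
    return(v)
  }
  abort_if(is.null(names(gca)), "response vector must be named by line id")
  gca
}
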
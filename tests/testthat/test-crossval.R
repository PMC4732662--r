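test_that("accuracy is the Pearson correlation with degenerate guards", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(accuracy(x, x), 1)
  expect_equal(accuracy(x, -x), -1)
  expect_error(accuracy(x, x[1:3]), "length")
  expect_error(accuracy(1:2, 2:1), "at least 3")
  expect_warning(a <- accuracy(rep(1, 5), x), "zero variance")
  expect_true(is.na(a))
  set.seed(1)
  expect_lt(abs(accuracy(rnorm(10000), rnorm(10000))), 0.05)
})

test_that("scenario_spec validates its fields", {
  expect_error(scenario_spec(tp_fraction = 0), "strictly")
  expect_error(scenario_spec(tp_fraction = 1), "strictly")
  expect_error(scenario_spec("within_cluster"), "target_cluster")
  expect_error(scenario_spec("bogus"))
})

test_that("run_cv is bit-identical under the same seed and reports a valid se", {
  X <- rand_geno(80, 300, seed = 40)
  tr <- rand_trait(X, n_qtl = 40, h2 = 0.7, seed = 41)
  spec <- scenario_spec("whole_population", tp_fraction = 0.7,
                        n_rounds = 15, seed = 99)
  r1 <- run_cv(tr$y, X, spec)
  r2 <- run_cv(tr$y, X, spec)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$mean_r_gpa, r2$mean_r_gpa)
  ok <- !is.na(r1$accuracies)
  expect_equal(r1$se, sd(r1$accuracies[ok]) / sqrt(sum(ok)))
  expect_lte(abs(r1$mean_r_gpa), 1)
  expect_equal(length(r1$accuracies), 15L)
})

test_that("every round's training and validation sets partition the frame", {
  X <- rand_geno(50, 200, seed = 44)
  tr <- rand_trait(X, n_qtl = 30, h2 = 0.8, seed = 45)
  spec <- scenario_spec("whole_population", tp_fraction = 0.6,
                        n_rounds = 8, seed = 7)
  res <- run_cv(tr$y, X, spec)
  frame <- rownames(X)
  # the documented derivation makes each round's split independently
  # re-constructible from the master seed
  for (r in 1:8) {
    tp <- withr::with_seed(stage_seed(7, paste0("round_", r)),
                           sample(frame, size = round(0.6 * 50)))
    vp <- setdiff(frame, tp)
    expect_length(intersect(tp, vp), 0)
    expect_setequal(union(tp, vp), frame)
  }
})

test_that("mean accuracy increases with heritability (paired designs)", {
  X <- rand_geno(250, 800, seed = 50)
  hi <- rand_trait(X, n_qtl = 80, h2 = 0.9, seed = 51)
  lo_g <- hi$g   # identical genetic signal, more noise
  set.seed(52)
  lo_y <- setNames(lo_g + rnorm(250, 0, sd(lo_g) * sqrt(0.7 / 0.3)),
                   rownames(X))
  spec <- scenario_spec("whole_population", n_rounds = 25, seed = 8)
  r_hi <- run_cv(hi$y, X, spec)
  r_lo <- run_cv(lo_y, X, spec)
  expect_gt(r_hi$mean_r_gpa, r_lo$mean_r_gpa)
})

test_that("noiseless oligogenic traits are predicted almost perfectly", {
  X <- rand_geno(200, 60, seed = 53)
  tr <- rand_trait(X, n_qtl = 20, h2 = 1, seed = 54)
  res <- run_cv(tr$y, X, scenario_spec("whole_population", tp_fraction = 0.7,
                                       n_rounds = 20, seed = 3))
  expect_gt(res$mean_r_gpa, 0.95)
})

test_that("within-cluster scenarios restrict the frame and guard small clusters", {
  X <- rand_geno(120, 400, seed = 60)
  tr <- rand_trait(X, n_qtl = 50, h2 = 0.8, seed = 61)
  labels <- setNames(rep(c(1, 2, 3), c(70, 40, 10)), rownames(X))

  expect_error(
    run_scenario(scenario_spec("within_cluster", target_cluster = "3",
                               n_rounds = 5, seed = 1), tr$y, X, labels),
    "too small")

  # a single all-covering cluster reproduces the whole-population result
  one <- setNames(rep(1, 120), rownames(X))
  spec <- scenario_spec("within_cluster", target_cluster = "1",
                        n_rounds = 10, seed = 5)
  wp <- run_cv(tr$y, X, scenario_spec("whole_population", n_rounds = 10,
                                      seed = 5))
  wc <- run_scenario(spec, tr$y, X, one)
  expect_identical(wc$accuracies, wp$accuracies)
})

test_that("cross-cluster training with flipped linkage phase loses accuracy", {
  cfg <- sim_config(n_lines = 150, subpop_sizes = c(90, 60), n_markers = 1500,
                    fst = 0.4, n_qtl = 60, missing_rate = 0, seed = 42)
  sim <- simulate_structured_genotypes(cfg)
  qc <- qc_pipeline(sim$panel)
  lab <- sim$truth$subpop_labels
  Xq <- sim$complete[, sim$truth$qtl_indices]
  # opposite marker-QTL phase in the second subpopulation
  g <- drop(Xq %*% sim$truth$qtl_effects) * ifelse(lab == 1, 1, -1)
  gca <- setNames(g - mean(g), names(lab))

  cross <- run_scenario(scenario_spec("cross_cluster_train",
                                      target_cluster = "1",
                                      tp_fraction = 0.7, n_rounds = 50,
                                      seed = 9),
                        gca, qc$genotypes, lab)
  expect_lt(abs(cross$mean_r_gpa), 0.15)

  # within-cluster prediction on the same data retains signal
  within <- run_scenario(scenario_spec("within_cluster", target_cluster = "1",
                                       tp_fraction = 0.7, n_rounds = 20,
                                       seed = 9),
                         gca, qc$genotypes, lab)
  expect_gt(within$mean_r_gpa, 0.15)
  expect_gt(within$mean_r_gpa - cross$mean_r_gpa, 0.1)
})

test_that("a structure covariate absorbs pure between-cluster signal", {
  cfg <- sim_config(n_lines = 150, subpop_sizes = c(90, 60), n_markers = 1500,
                    fst = 0.4, missing_rate = 0, seed = 42)
  sim <- simulate_structured_genotypes(cfg)
  qc <- qc_pipeline(sim$panel)
  lab <- sim$truth$subpop_labels
  set.seed(71)
  # cluster mean shifts only: no within-cluster genetic signal
  gca <- setNames(ifelse(lab == 1, 2, -2) + rnorm(150, 0, 0.2), names(lab))

  X <- qc$genotypes$coded
  train <- rownames(X)[c(1:60, 91:130)]
  test_lines <- setdiff(rownames(X), train)
  fit_plain <- fit_rrblup(gca[train], X[train, ])
  Z <- cbind(c2 = as.numeric(lab == 2))
  rownames(Z) <- names(lab)
  fit_cov <- fit_rrblup(gca[train], X[train, ], covariates = Z[train, , drop = FALSE])

  marker_part <- function(fit) drop(X[test_lines, ] %*% fit$effects)
  r_plain <- cor(marker_part(fit_plain), gca[test_lines])
  # without the covariate the markers proxy cluster membership and predict
  # the shift; with it, the marker component shrinks to almost nothing
  expect_gt(r_plain, 0.8)
  expect_lt(sd(marker_part(fit_cov)), 0.3 * sd(marker_part(fit_plain)))

  # full predictions including the covariate remain accurate
  full <- run_scenario(scenario_spec("structure_covariate", n_rounds = 10,
                                     seed = 4), gca, qc$genotypes, lab)
  expect_gt(full$mean_r_gpa, 0.8)
})

test_that("tp_sweep traces the accuracy-versus-training-size curve", {
  X <- rand_geno(150, 500, seed = 80)
  tr <- rand_trait(X, n_qtl = 60, h2 = 0.7, seed = 81)
  sw <- tp_sweep(tr$y, X, fractions = c(0.3, 0.5, 0.7), n_rounds = 10,
                 seed = 5)
  expect_equal(nrow(sw$curve), 3L)
  expect_true(all(diff(sw$curve$mean_r_gpa) > -0.1))   # broadly increasing

  # a single fraction is exactly one run_cv under the derived seed
  one <- tp_sweep(tr$y, X, fractions = 0.5, n_rounds = 10, seed = 5)
  direct <- run_cv(tr$y, X,
                   scenario_spec("whole_population", tp_fraction = 0.5,
                                 n_rounds = 10,
                                 seed = stage_seed(5, "frac_50")))
  expect_identical(one$results[["0.50"]]$accuracies, direct$accuracies)

  expect_error(tp_sweep(tr$y, X, fractions = c(0, 0.5)), "strictly")
  expect_warning(tp_sweep(tr$y, X, fractions = 0.99, n_rounds = 2), "skipped")
})
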
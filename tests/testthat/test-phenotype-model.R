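make_trials <- function(gvals, loc_eff, noise_sd = 0, seed = 1,
                        trait = "yield") {
  # gvals: named vector of hybrid genetic values ("pollinator:tester")
  set.seed(seed)
  grid <- expand.grid(hybrid = names(gvals),
                      location = paste0("Loc", seq_along(loc_eff)),
                      stringsAsFactors = FALSE)
  parts <- strsplit(grid$hybrid, ":", fixed = TRUE)
  data.frame(pollinator = vapply(parts, `[`, "", 1),
             tester = vapply(parts, `[`, "", 2),
             location = grid$location,
             trait = trait,
             value = gvals[grid$hybrid] +
               loc_eff[match(grid$location, paste0("Loc", seq_along(loc_eff)))] +
               rnorm(nrow(grid), 0, noise_sd),
             stringsAsFactors = FALSE)
}

test_that("fit_blues equals location-adjusted means on balanced data", {
  gvals <- setNames(c(10, 12, 8, 11), c("P1:T1", "P1:T2", "P2:T1", "P2:T2"))
  loc <- c(2, -1, 0, 3)          # non-zero location effects
  tr <- make_trials(gvals, loc, noise_sd = 0)
  bl <- fit_blues(tr)
  got <- setNames(bl$blue, paste(bl$pollinator, bl$tester, sep = ":"))
  # with balanced complete data the BLUE recovers g + mean(location effects)
  expect_equal(got[names(gvals)], gvals + mean(loc), tolerance = 1e-10)

  # brute-force two-way decomposition: row means after removing column means
  wide <- tapply(tr$value, list(paste(tr$pollinator, tr$tester, sep = ":"),
                                tr$location), mean)
  col_dev <- colMeans(wide) - mean(wide)
  brute <- rowMeans(sweep(wide, 2, col_dev))
  expect_equal(got[names(brute)], brute, tolerance = 1e-10)
})

test_that("fit_blues adjusts for location effects with missing cells", {
  gvals <- setNames(seq(8, 16, by = 2), paste0("P", 1:5, ":T1"))
  loc <- c(5, -5, 1, -1)
  tr <- make_trials(gvals, loc, noise_sd = 0)
  # drop P1 at the high-effect location: a plain mean would be biased low
  tr <- tr[!(tr$pollinator == "P1" & tr$location == "Loc1"), ]
  bl <- fit_blues(tr)
  got <- setNames(bl$blue, paste0(bl$pollinator, ":", bl$tester))
  expect_equal(got[names(gvals)], gvals + mean(loc), tolerance = 1e-8)
  naive <- mean(tr$value[tr$pollinator == "P1"])
  expect_gt(abs(naive - got["P1:T1"]), 1)   # the naive mean is indeed off
})

test_that("single-location data return observations and refuse variances", {
  gvals <- setNames(c(10, 12, 8), paste0("P", 1:3, ":T1"))
  tr <- make_trials(gvals, loc_eff = 0)
  bl <- fit_blues(tr)
  expect_equal(setNames(bl$blue, paste0(bl$pollinator, ":", bl$tester))[names(gvals)],
               gvals)
  expect_error(estimate_variance_components(tr), "2 locations")
})

test_that("REML variance components recover simulated truth", {
  # zero residual: sigma2_e ~ 0 and sigma2_g ~ var of the true values
  gvals <- setNames(rnorm(200, 30, 2), paste0("P", 1:200, ":T1"))
  tr0 <- make_trials(gvals, loc_eff = c(1, -1, 2, -2), noise_sd = 0.01)
  vc0 <- suppressWarnings(estimate_variance_components(tr0))
  expect_lt(vc0$sigma2_e, 1e-3)
  expect_equal(vc0$sigma2_g, var(gvals), tolerance = 0.01)

  # identical hybrids: sigma2_g = 0
  tr_flat <- make_trials(setNames(rep(5, 30), paste0("P", 1:30, ":T1")),
                         loc_eff = c(0, 0), noise_sd = 1, seed = 3)
  expect_lt(estimate_variance_components(tr_flat)$sigma2_g, 0.2)

  # recovery at realistic seed-yield-like components over seeds
  est <- t(sapply(1:10, function(s) {
    set.seed(s)
    g <- setNames(rnorm(300, 31, sqrt(1.56)),
                  paste0("P", 1:150, ":T", rep(1:2, each = 150)))
    tr <- make_trials(g, loc_eff = c(1, -2, 0.5, 0.5), noise_sd = sqrt(7.95),
                      seed = 1000 + s)
    vc <- suppressWarnings(estimate_variance_components(tr))
    c(vc$sigma2_g, vc$sigma2_e)
  }))
  expect_equal(mean(est[, 1]), 1.56, tolerance = 0.15)
  expect_equal(mean(est[, 2]), 7.95, tolerance = 0.05)
})

test_that("broad-sense heritability follows the n-location formula", {
  # printed variance components from a real multi-location canola trial;
  # H2 = 100 * s2g / (s2g + s2e / 4) rounds to the published integers
  tab <- data.frame(
    trait = c("seed_yield", "oil_yield", "oil_content", "gsl",
              "emergence", "lodging", "dtf"),
    s2g = c(1.56, 0.56, 1.91, 1.35, 0.048, 0.119, 0.808),
    s2e = c(7.95, 0.95, 0.81, 3.12, 0.41, 0.47, 5.26),
    h2 = c(44, 70, 90, 63, 32, 50, 38))
  got <- broad_sense_heritability(tab$s2g, tab$s2e, n_locations = 4)
  expect_equal(round(got), tab$h2)

  expect_equal(broad_sense_heritability(2.5, 0, 4), 100)
  expect_error(broad_sense_heritability(0, 0, 4), "undefined")
  expect_error(broad_sense_heritability(-1, 1, 4), "non-negative")
})

test_that("GCA is the tester-mean BLUE expressed against the grand mean", {
  bl <- structure(data.frame(
    pollinator = c("P1", "P1", "P2", "P2", "P3", "P3"),
    tester = rep(c("T1", "T2"), 3),
    trait = "yield",
    blue = c(32, 30, 31, 33, 30.5, 30.52)),
    class = c("blue_table", "data.frame"))
  g <- compute_gca(bl)
  grand <- mean(bl$blue)
  expect_equal(g$gca[g$pollinator == "P1"], 31 - grand)
  expect_equal(sum(g$gca), 0, tolerance = 1e-8)

  # hand case with a typical grand mean: BLUEs (32, 30) against 31.17
  bl2 <- bl; bl2$blue <- c(32, 30, 31.17, 31.17, 31.17, 31.17)
  g2 <- compute_gca(bl2)
  expect_equal(g2$gca[g2$pollinator == "P1"], 31 - mean(bl2$blue),
               tolerance = 1e-10)

  # identical hybrids: every GCA 0
  bl3 <- bl; bl3$blue <- rep(7, 6)
  expect_true(all(compute_gca(bl3)$gca == 0))
})

test_that("GCA recovers true breeding values in the purely additive limit", {
  cfg <- sim_config(n_lines = 100, subpop_sizes = 100, n_markers = 400,
                    h2_target = 1, sca_variance_fraction = 0,
                    missing_rate = 0, seed = 14)
  sim <- simulate_structured_genotypes(cfg)
  ph <- simulate_testcross_phenotypes(sim, sim$truth, cfg)
  g <- compute_gca(fit_blues(ph$trials))
  expect_gt(cor(g$gca, sim$truth$true_gca[g$pollinator]), 0.9999)
})

test_that("trait correlations are pairwise Pearson on shared hybrids", {
  set.seed(77)
  n <- 950
  # bivariate normal with correlation 0.66 (oil content vs oil yield scale)
  r <- 0.66
  z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  hy <- paste0("P", rep(1:(n / 2), each = 2), ":T", rep(1:2, n / 2))
  parts <- strsplit(hy, ":", fixed = TRUE)
  bl <- data.frame(
    pollinator = rep(vapply(parts, `[`, "", 1), 2),
    tester = rep(vapply(parts, `[`, "", 2), 2),
    trait = rep(c("a", "b"), each = n),
    blue = c(48 + z1, 14 + 2 * z2))
  cm <- trait_correlations(bl)
  expect_equal(dim(cm), c(2L, 2L))
  expect_equal(diag(cm), setNames(c(1, 1), c("a", "b")))
  expect_equal(cm["a", "b"], r, tolerance = 0.05)
  expect_equal(cm, t(cm))

  # y against -y
  bl2 <- bl
  bl2$blue[bl2$trait == "b"] <- -bl2$blue[bl2$trait == "a"]
  expect_equal(trait_correlations(bl2)["a", "b"], -1)

  # zero-variance trait flagged
  bl3 <- bl
  bl3$blue[bl3$trait == "b"] <- 3
  expect_warning(cm3 <- trait_correlations(bl3), "zero variance")
  expect_true(is.na(cm3["a", "b"]))
})
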
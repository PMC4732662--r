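#' Best linear unbiased estimates of hybrid performance across locations
#'
#' Fits the two-way additive fixed-effect model
#' `value = mu + hybrid_i + location_l + e` by least squares with sum-to-zero
#' location contrasts and returns `BLUE_i = mu_hat + hybrid_i_hat`, i.e. the
#' hybrid's expected value averaged over locations. With complete balanced
#' data this equals the hybrid's plain mean across locations; with missing
#' location cells it adjusts for the location effects. The design is
#' unreplicated within location, so no hybrid x location interaction is
#' estimable.
#'
#' @param trials long-format data frame with columns `pollinator`, `tester`,
#'   `location`, `trait`, `value`.
#' @param trait trait name to extract (default: the single trait present).
#' @return a `blue_table` data frame with columns `pollinator`, `tester`,
#'   `trait`, `blue`, one row per hybrid.
#' @export
fit_blues <- function(trials, trait = NULL) {
  d <- select_trait(trials, trait)
  d$hybrid <- interaction(d$pollinator, d$tester, sep = ":", drop = TRUE)
  n_loc <- length(unique(d$location))

  if (n_loc == 1L) {
    # single location: the observation is the estimate
    out <- d[, c("pollinator", "tester", "trait")]
    out$blue <- d$value
    return(structure(out[order(out$pollinator, out$tester), ],
                     class = c("blue_table", "data.frame"),
                     row.names = seq_len(nrow(out))))
  }

  d$location <- factor(d$location)
  fit <- lm(value ~ 0 + hybrid + location, data = d,
            contrasts = list(location = "contr.sum"))
  cf <- coef(fit)
  hyb_levels <- levels(d$hybrid)
  blue <- cf[paste0("hybrid", hyb_levels)]
  dropped <- is.na(blue)
  if (any(dropped))
    warning(sprintf("%d hybrid(s) not estimable; omitted", sum(dropped)))

  key <- unique(d[, c("pollinator", "tester", "trait")])
  key$hybrid <- interaction(key$pollinator, key$tester, sep = ":")
  key$blue <- blue[paste0("hybrid", as.character(key$hybrid))]
  out <- key[!is.na(key$blue), c("pollinator", "tester", "trait", "blue")]
  structure(out[order(out$pollinator, out$tester), ],
            class = c("blue_table", "data.frame"),
            row.names = seq_len(sum(!is.na(key$blue))))
}

#' REML variance components for a multi-location trial
#'
#' Fits `value = mu + location (fixed) + hybrid (random) + e` by REML and
#' returns the genotypic (hybrid) and residual variance components. REML
#' estimates are non-negative by construction of the fit.
#'
#' @inheritParams fit_blues
#' @return a `variance_components` list: `trait`, `sigma2_g`, `sigma2_e`,
#'   `n_locations`, `method`.
#' @export
estimate_variance_components <- function(trials, trait = NULL) {
  d <- select_trait(trials, trait)
  n_loc <- length(unique(d$location))
  abort_if(n_loc < 2,
           "variance components need >= 2 locations (found %d)", n_loc)
  d$hybrid <- interaction(d$pollinator, d$tester, sep = ":", drop = TRUE)
  d$location <- factor(d$location)
  fit <- tryCatch(
    lme4::lmer(value ~ location + (1 | hybrid), data = d, REML = TRUE),
    error = function(e) stop("REML fit failed: ", conditionMessage(e),
                             call. = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "hybrid"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  structure(list(trait = d$trait[1],
                 sigma2_g = max(s2g, 0),
                 sigma2_e = max(s2e, 0),
                 n_locations = n_loc,
                 method = "REML (lmer, location fixed, hybrid random)"),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> %s: sigma2_g = %.4g, sigma2_e = %.4g (n = %d locations)\n",
              x$trait, x$sigma2_g, x$sigma2_e, x$n_locations))
  invisible(x)
}

#' Broad-sense heritability on a trial-mean basis
#'
#' `H2(%) = 100 * sigma2_g / (sigma2_g + sigma2_e / n)`: the residual
#' variance is divided by the number of locations because the unit of
#' selection is the hybrid mean over the `n` locations.
#'
#' @param vc a `variance_components` object, or the genotypic variance as a
#'   plain number (then supply `sigma2_e` and `n_locations` too).
#' @param sigma2_e residual (per-plot) variance; ignored when `vc` is a
#'   `variance_components`.
#' @param n_locations number of locations.
#' @return heritability as a percentage (not rounded).
#' @export
broad_sense_heritability <- function(vc, sigma2_e = NULL, n_locations = NULL) {
  if (inherits(vc, "variance_components")) {
    s2g <- vc$sigma2_g; s2e <- vc$sigma2_e; n <- vc$n_locations
  } else {
    s2g <- vc; s2e <- sigma2_e; n <- n_locations
  }
  abort_if(is.null(s2e) || is.null(n), "sigma2_e and n_locations required")
  abort_if(any(s2g < 0 | s2e < 0), "variance components must be non-negative")
  abort_if(any(n < 1), "n_locations must be >= 1")
  abort_if(any(s2g == 0 & s2e == 0),
           "heritability undefined: both variance components are zero")
  100 * s2g / (s2g + s2e / n)
}

#' General combining ability from hybrid BLUEs
#'
#' `GCA_p` is the mean of the pollinator's hybrid BLUEs over its available
#' testers, expressed as a deviation from the grand mean of all hybrid BLUEs
#' for the trait. When every pollinator is crossed to every tester the GCA
#' values sum to zero (to numerical tolerance).
#'
#' @param blues a `blue_table` (from [fit_blues()] or [read_blues()]).
#' @param trait trait to extract (default: single trait present).
#' @return a `gca_table` data frame: `pollinator`, `trait`, `gca`, plus the
#'   grand mean as attribute `grand_mean`.
#' @export
compute_gca <- function(blues, trait = NULL) {
  d <- select_trait(blues, trait, value_col = "blue")
  grand <- mean(d$blue)
  ag <- aggregate(blue ~ pollinator, data = d, FUN = mean)
  out <- data.frame(pollinator = ag$pollinator,
                    trait = d$trait[1],
                    gca = ag$blue - grand,
                    stringsAsFactors = FALSE)
  structure(out[order(out$pollinator), ],
            class = c("gca_table", "data.frame"),
            row.names = seq_len(nrow(out)),
            grand_mean = grand)
}

#' Pearson correlations between traits on hybrid BLUEs
#'
#' Pairwise correlation over the hybrids shared by each trait pair.
#'
#' @param blues a `blue_table` holding two or more traits.
#' @return symmetric trait x trait correlation matrix with unit diagonal.
#'   Zero-variance traits yield `NA` rows/columns with a warning.
#' @export
trait_correlations <- function(blues) {
  d <- as.data.frame(blues)
  abort_if(!all(c("pollinator", "tester", "trait", "blue") %in% names(d)),
           "blue table needs columns pollinator, tester, trait, blue")
  d$hybrid <- paste(d$pollinator, d$tester, sep = ":")
  traits <- unique(d$trait)
  abort_if(length(traits) < 2, "need >= 2 traits for correlations")
  wide <- matrix(NA_real_, length(unique(d$hybrid)), length(traits),
                 dimnames = list(unique(d$hybrid), traits))
  wide[cbind(d$hybrid, d$trait)] <- d$blue
  degenerate <- apply(wide, 2, function(x) var(x, na.rm = TRUE) == 0)
  if (any(degenerate))
    warning(sprintf("zero variance in trait(s): %s",
                    paste(traits[degenerate], collapse = ", ")))
  suppressWarnings(cor(wide, use = "pairwise.complete.obs"))
}

#' Read / write long-format phenotype and BLUE tables
#'
#' `read_trials` expects CSV with header
#' `pollinator,tester,location,trait,value`; `read_blues` accepts either the
#' long layout `pollinator,tester,trait,blue` or a wide hybrid-by-trait
#' layout (columns `pollinator,tester,<trait1>,<trait2>,...`), which it
#' reshapes to long.
#'
#' @param path CSV file path.
#' @return a data frame (`blue_table` for `read_blues`).
#' @export
read_trials <- function(path) {
  abort_if(!file.exists(path), "phenotype file not found: %s", path)
  d <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("pollinator", "tester", "location", "trait", "value")
  abort_if(!all(need %in% names(d)),
           "phenotype CSV needs columns %s", paste(need, collapse = ","))
  d$value <- as.numeric(d$value)
  dup <- duplicated(d[, c("pollinator", "tester", "location", "trait")])
  abort_if(any(dup), "duplicate (pollinator,tester,location,trait) records")
  d
}

#' @rdname read_trials
#' @export
read_blues <- function(path) {
  abort_if(!file.exists(path), "BLUE file not found: %s", path)
  d <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (all(c("pollinator", "tester", "trait", "blue") %in% names(d))) {
    out <- d
  } else {
    abort_if(!all(c("pollinator", "tester") %in% names(d)),
             "BLUE CSV needs pollinator,tester plus trait columns")
    traits <- setdiff(names(d), c("pollinator", "tester"))
    out <- do.call(rbind, lapply(traits, function(tr)
      data.frame(pollinator = d$pollinator, tester = d$tester,
                 trait = tr, blue = as.numeric(d[[tr]]),
                 stringsAsFactors = FALSE)))
    out <- out[!is.na(out$blue), ]
  }
  structure(out, class = c("blue_table", "data.frame"),
            row.names = seq_len(nrow(out)))
}

# Internal: subset a long table to one trait, with validation.
select_trait <- function(x, trait, value_col = "value") {
  d <- as.data.frame(x)
  need <- c("pollinator", "tester", "trait", value_col)
  abort_if(!all(need %in% names(d)),
           "table needs columns %s", paste(need, collapse = ", "))
  if (is.null(trait)) {
    tr <- unique(d$trait)
    abort_if(length(tr) != 1L,
             "multiple traits present (%s); specify one",
             paste(tr, collapse = ", "))
    trait <- tr
  }
  d <- d[d$trait == trait, , drop = FALSE]
  abort_if(nrow(d) == 0L, "trait '%s' not present", trait)
  d
}
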
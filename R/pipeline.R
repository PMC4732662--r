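#' Run the full testcross genomic-selection analysis
#'
#' Orchestrates the stages in methods order: data (simulate or ingest) ->
#' marker QC -> population structure -> phenotype modelling (BLUEs, variance
#' components, heritability, GCA, trait correlations) -> cross-validated
#' genomic prediction (scenarios and optional training-size sweep). All
#' artefacts are written as plain-text files under `config$outdir` together
#' with a reproducibility manifest (config echo, package version, per-stage
#' seeds, per-file checksums, warnings). A stage whose configuration hash
#' matches a previous run's manifest, and whose output files are all present
#' with matching checksums, is skipped and reloaded from disk.
#'
#' @param config a named list (or path to a YAML/JSON file) with elements:
#'   \describe{
#'     \item{seed}{master seed (required),}
#'     \item{outdir}{output directory (required),}
#'     \item{simulate}{list of [sim_config()] fields plus an optional
#'       `traits` list of per-trait overrides (`trait`, `h2_target`,
#'       `trait_mean`, ...); mutually exclusive with `inputs`,}
#'     \item{inputs}{list with `genotypes` (TSV path) and either `trials`
#'       (long CSV) or `blues` (CSV),}
#'     \item{qc}{`maf_min`, `max_missing`,}
#'     \item{structure}{`axes`, `k_range`, `n_restarts`,}
#'     \item{cv}{`scenarios` (character), `tp_fraction`, `n_rounds`,}
#'     \item{sweep}{`fractions`, `n_rounds`, or `NULL` to skip.}
#'   }
#' @return the run manifest (list of class `run_manifest`), invisibly also
#'   written to `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("tcrossgs")),
                   stages = list(), files = list(), warnings = list())
  prev <- read_manifest(file.path(outdir, "manifest.json"))

  logline <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }

  stage_cached <- function(stage, files, hash) {
    if (is.null(prev$stages[[stage]])) return(FALSE)
    if (!identical(prev$stages[[stage]]$hash, hash)) return(FALSE)
    paths <- file.path(outdir, files)
    if (!all(file.exists(paths))) return(FALSE)
    sums <- unname(tools::md5sum(paths))
    identical(sums, unlist(prev$stages[[stage]]$checksums, use.names = FALSE))
  }
  register <- function(stage, files, hash, seed, cached) {
    paths <- file.path(outdir, files)
    manifest$stages[[stage]] <<- list(hash = hash, seed = seed,
                                      cached = cached,
                                      outputs = files,
                                      checksums = unname(tools::md5sum(paths)))
    for (i in seq_along(files))
      manifest$files[[files[i]]] <<- unname(tools::md5sum(paths[i]))
  }
  cfg_hash <- function(...) substr(digest_obj(list(...)), 1, 16)

  ## ---- stage: data -------------------------------------------------------
  sim_mode <- !is.null(config$simulate)
  h_data <- cfg_hash("data", config$simulate, config$inputs, config$seed)
  data_files <- if (sim_mode) c("genotypes.tsv", "phenotypes.csv", "truth.json")
                else character(0)
  truth_list <- NULL
  if (sim_mode) {
    base_cfg <- do.call(sim_config,
                        modifyList(config$simulate[setdiff(names(config$simulate), "traits")],
                                   list(seed = config$seed)))
    traits_cfg <- config$simulate$traits %||%
      list(list(trait = base_cfg$trait, h2_target = base_cfg$h2_target))
    if (stage_cached("data", data_files, h_data)) {
      logline("data", "cached; reloading simulated study from disk")
      panel <- read_genotypes(file.path(outdir, "genotypes.tsv"))
      trials <- read_trials(file.path(outdir, "phenotypes.csv"))
      truth_list <- NULL   # truths reload not needed downstream
      register("data", data_files, h_data, config$seed, cached = TRUE)
    } else {
      logline("data", sprintf("simulating %d lines x %d markers, %d trait(s) [seed %d]",
                              base_cfg$n_lines, base_cfg$n_markers,
                              length(traits_cfg), config$seed))
      sim <- simulate_structured_genotypes(base_cfg)
      panel <- sim$panel
      trials_all <- list(); truth_list <- list()
      for (tc in traits_cfg) {
        cfg_t <- do.call(sim_config,
                         modifyList(unclass(base_cfg)[setdiff(names(unclass(base_cfg)), NULL)],
                                    tc))
        truth_t <- draw_trait_truth(sim, cfg_t)
        ph <- simulate_testcross_phenotypes(sim, truth_t, cfg_t)
        trials_all[[cfg_t$trait]] <- ph$trials
        truth_list[[cfg_t$trait]] <- ph$truth
      }
      trials <- do.call(rbind, trials_all)
      rownames(trials) <- NULL
      write_sim_study(sim, trials, outdir)
      jsonlite::write_json(
        lapply(truth_list, function(tt)
          list(true_h2 = tt$true_h2, sigma2_g = tt$sigma2_g,
               sigma2_e = tt$sigma2_e, qtl_indices = tt$qtl_indices)),
        file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
      register("data", data_files, h_data, config$seed, cached = FALSE)
    }
  } else {
    abort_if(is.null(config$inputs$genotypes),
             "config needs either 'simulate' or 'inputs$genotypes'")
    abort_if(!file.exists(config$inputs$genotypes),
             "genotype path does not exist: %s", config$inputs$genotypes)
    logline("data", paste("reading", config$inputs$genotypes))
    panel <- read_genotypes(config$inputs$genotypes)
    trials <- NULL
    if (!is.null(config$inputs$trials)) {
      abort_if(!file.exists(config$inputs$trials),
               "trials path does not exist: %s", config$inputs$trials)
      trials <- read_trials(config$inputs$trials)
    }
  }

  ## ---- stage: qc ---------------------------------------------------------
  qc_cfg <- config$qc %||% list()
  maf_min <- qc_cfg$maf_min %||% 0.05
  max_missing <- qc_cfg$max_missing %||% 0.20
  h_qc <- cfg_hash("qc", h_data, maf_min, max_missing)
  qc_files <- c("genotypes_coded.tsv", "qc_report.json")
  if (stage_cached("qc", qc_files, h_qc)) {
    logline("qc", "cached")
    df <- read.table(file.path(outdir, "genotypes_coded.tsv"), header = TRUE,
                     sep = "\t", check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    geno <- genotype_matrix(m, allele_freqs = pmin(colMeans((m + 1) / 2),
                                                   1 - colMeans((m + 1) / 2)))
    register("qc", qc_files, h_qc, NA, cached = TRUE)
  } else {
    qc <- qc_pipeline(panel, maf_min = maf_min, max_missing = max_missing)
    geno <- qc$genotypes
    logline("qc", sprintf("%d markers in, %d retained",
                          qc$report$n_input_markers, qc$report$n_retained))
    write_genotypes(geno, file.path(outdir, "genotypes_coded.tsv"))
    jsonlite::write_json(unclass(qc$report),
                         file.path(outdir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    register("qc", qc_files, h_qc, NA, cached = FALSE)
    # re-read the written matrix so cached re-runs see identical doubles
    geno <- genotype_matrix(
      local({
        df <- read.table(file.path(outdir, "genotypes_coded.tsv"),
                         header = TRUE, sep = "\t", check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE]); rownames(m) <- df[[1]]
        storage.mode(m) <- "double"; m
      }),
      allele_freqs = geno$allele_freqs)
  }

  ## ---- stage: structure --------------------------------------------------
  st_cfg <- config$structure %||% list()
  axes <- st_cfg$axes %||% 4L
  k_range <- st_cfg$k_range %||% 2:8
  n_restarts <- st_cfg$n_restarts %||% 50L
  st_seed <- stage_seed(config$seed, "structure")
  h_st <- cfg_hash("structure", h_qc, axes, k_range, n_restarts)
  st_files <- c("pcoa_coordinates.csv", "pcoa_eigenvalues.csv",
                "cluster_labels.csv", "ch_scores.csv")
  if (stage_cached("structure", st_files, h_st)) {
    logline("structure", "cached")
    lab_df <- read.table(file.path(outdir, "cluster_labels.csv"),
                         header = TRUE, sep = ",")
    clusters <- setNames(lab_df$cluster, lab_df$line_id)
    pc <- NULL
    register("structure", st_files, h_st, st_seed, cached = TRUE)
  } else {
    logline("structure", "Rogers distances + PCoA + K-means")
    D <- rogers_distance(geno)
    pc <- pcoa(D, n_axes = axes)
    sel <- select_k(pc, k_range = k_range, n_restarts = n_restarts,
                    seed = st_seed)
    clusters <- sel$solution$labels
    logline("structure",
            sprintf("selected k = %d (sizes %s); PCo1 %.2f%% variance",
                    sel$k, paste(as.integer(table(clusters)), collapse = "/"),
                    pc$explained_variance_pct[1]))
    write.table(data.frame(line_id = rownames(pc$coordinates),
                           pc$coordinates, check.names = FALSE),
                file.path(outdir, "pcoa_coordinates.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    write.table(data.frame(axis = seq_along(pc$eigenvalues),
                           eigenvalue = pc$eigenvalues),
                file.path(outdir, "pcoa_eigenvalues.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    write.table(data.frame(line_id = names(clusters), cluster = clusters),
                file.path(outdir, "cluster_labels.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    write.table(data.frame(k = as.integer(names(sel$ch_scores)),
                           ch = sel$ch_scores),
                file.path(outdir, "ch_scores.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    register("structure", st_files, h_st, st_seed, cached = FALSE)
  }

  ## ---- stage: phenotype --------------------------------------------------
  blues <- NULL
  if (!is.null(config$inputs$blues)) {
    blues <- read_blues(config$inputs$blues)
  } else if (!is.null(trials)) {
    h_ph <- cfg_hash("phenotype", h_data)
    traits <- unique(trials$trait)
    ph_files <- c("blues.csv", "gca.csv", "variance_components.csv",
                  if (length(traits) >= 2) "trait_correlations.csv")
    if (stage_cached("phenotype", ph_files, h_ph)) {
      logline("phenotype", "cached")
      blues <- read_blues(file.path(outdir, "blues.csv"))
      register("phenotype", ph_files, h_ph, NA, cached = TRUE)
    } else {
      logline("phenotype", sprintf("BLUEs/variance components/GCA for %d trait(s)",
                                   length(traits)))
      blues_l <- list(); gca_l <- list(); vc_l <- list()
      for (tr in traits) {
        blues_l[[tr]] <- fit_blues(trials, tr)
        vc <- estimate_variance_components(trials, tr)
        vc_l[[tr]] <- data.frame(trait = tr, sigma2_g = vc$sigma2_g,
                                 sigma2_e = vc$sigma2_e,
                                 n_locations = vc$n_locations,
                                 h2_pct = broad_sense_heritability(vc))
        gca_l[[tr]] <- compute_gca(blues_l[[tr]], tr)
      }
      blues <- do.call(rbind, blues_l)
      class(blues) <- c("blue_table", "data.frame")
      gca_df <- do.call(rbind, gca_l)
      vc_df <- do.call(rbind, vc_l)
      write.table(blues, file.path(outdir, "blues.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)
      write.table(gca_df, file.path(outdir, "gca.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)
      write.table(vc_df, file.path(outdir, "variance_components.csv"),
                  sep = ",", quote = FALSE, row.names = FALSE)
      if (length(traits) >= 2) {
        cm <- trait_correlations(blues)
        write.table(data.frame(trait = rownames(cm), cm, check.names = FALSE),
                    file.path(outdir, "trait_correlations.csv"),
                    sep = ",", quote = FALSE, row.names = FALSE)
      }
      register("phenotype", ph_files, h_ph, NA, cached = FALSE)
      # downstream stages consume the written table so that re-runs from
      # cache are byte-identical
      blues <- read_blues(file.path(outdir, "blues.csv"))
    }
  }

  ## ---- stage: cross-validation ------------------------------------------
  if (!is.null(blues) && !is.null(config$cv)) {
    cv_cfg <- config$cv
    scenarios <- cv_cfg$scenarios %||% "whole_population"
    tp_fraction <- cv_cfg$tp_fraction %||% 0.70
    n_rounds <- cv_cfg$n_rounds %||% 500L
    cv_seed <- stage_seed(config$seed, "crossval")
    traits <- unique(blues$trait)
    summary_rows <- list()
    for (tr in traits) {
      gca_tr <- compute_gca(blues, tr)
      for (sc in scenarios) {
        targets <- if (sc %in% c("within_cluster", "cross_cluster_train")) {
          big <- names(which(table(clusters) >= 15))
          big
        } else NA
        for (tg in targets) {
          spec <- scenario_spec(sc,
                                target_cluster = if (is.na(tg)) NULL else tg,
                                tp_fraction = tp_fraction,
                                n_rounds = n_rounds,
                                seed = stage_seed(cv_seed,
                                                  paste(tr, sc, tg, sep = "_")))
          res <- run_scenario(spec, gca_tr, geno, clusters)
          tag <- if (is.na(tg)) sc else paste0(sc, "_C", tg)
          logline("cv", sprintf("%s / %s: mean r_GPA = %.3f +/- %.3f",
                                tr, tag, res$mean_r_gpa, res$se))
          f <- sprintf("cv_%s_%s.csv", tr, tag)
          write.table(data.frame(round = seq_along(res$accuracies),
                                 r_gpa = res$accuracies),
                      file.path(outdir, f), sep = ",", quote = FALSE,
                      row.names = FALSE)
          manifest$files[[f]] <- unname(tools::md5sum(file.path(outdir, f)))
          summary_rows[[paste(tr, tag)]] <-
            data.frame(trait = tr, scenario = tag,
                       mean_r_gpa = res$mean_r_gpa, se = res$se,
                       n_rounds = res$n_rounds,
                       n_excluded = res$n_excluded, seed = res$seed)
        }
      }
    }
    cv_summary <- do.call(rbind, summary_rows)
    jsonlite::write_json(cv_summary, file.path(outdir, "cv_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    manifest$files[["cv_summary.json"]] <-
      unname(tools::md5sum(file.path(outdir, "cv_summary.json")))
    manifest$stages[["cv"]] <- list(seed = cv_seed, cached = FALSE)
  }

  ## ---- stage: sweep ------------------------------------------------------
  if (!is.null(blues) && !is.null(config$sweep)) {
    sw <- config$sweep
    tr <- sw$trait %||% unique(blues$trait)[1]
    gca_tr <- compute_gca(blues, tr)
    res <- tp_sweep(gca_tr, geno,
                    fractions = sw$fractions %||% seq(0.1, 0.9, by = 0.1),
                    n_rounds = sw$n_rounds %||% 100L,
                    seed = stage_seed(config$seed, "sweep"))
    logline("sweep", sprintf("%s: %d fractions", tr, nrow(res$curve)))
    write.table(res$curve, file.path(outdir, "tp_sweep.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    manifest$files[["tp_sweep.csv"]] <-
      unname(tools::md5sum(file.path(outdir, "tp_sweep.csv")))
  }

  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

# Load a run configuration from a list or a YAML/JSON file and validate it.
load_run_config <- function(config) {
  if (is.character(config)) {
    abort_if(!file.exists(config), "config file not found: %s", config)
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  abort_if(!is.list(config), "config must be a list or a YAML/JSON path")
  abort_if(is.null(config$seed), "config$seed is required")
  abort_if(is.null(config$outdir), "config$outdir is required")
  abort_if(is.null(config$simulate) && is.null(config$inputs),
           "config needs either 'simulate' or 'inputs'")
  if (!is.null(config$inputs)) {
    for (p in unlist(config$inputs))
      abort_if(!file.exists(p), "configured input path does not exist: %s", p)
  }
  config$seed <- as.integer(config$seed)
  config
}

read_manifest <- function(path) {
  if (!file.exists(path)) return(list(stages = list()))
  tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
           error = function(e) list(stages = list()))
}

# Content hash of an R object via its serialized bytes (md5).
digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
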
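# End-to-end orchestration: simulate -> preprocess -> variance -> ewas ->
# composite -> mediation -> index, with a single global seed spawned into
# per-stage child seeds, delimited-text artifacts and a hashed manifest.

#' Pipeline configuration
#'
#' @param stages character vector of stages to run, a contiguous prefix-free
#'   subset of `simulate`, `preprocess`, `variance`, `ewas`, `composite`,
#'   `mediate`, `index` (the `index` stage requires `mediate`).
#' @param synthetic a [synthetic_config()] or argument list for it (used by
#'   the `simulate` stage).
#' @param qc a [qc_params()].
#' @param n_perm PERMANOVA permutations (default 999).
#' @param n_boot mediation bootstrap draws (default 1000).
#' @param composite_k_start starting cluster count (default 2).
#' @param index_exposures exposures to build indexes for (`NULL` = every
#'   exposure with classified mediation records).
#' @param seed global integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "preprocess", "variance",
                                       "ewas", "composite", "mediate", "index"),
                            synthetic = synthetic_config(),
                            qc = qc_params(),
                            n_perm = 999L,
                            n_boot = 1000L,
                            composite_k_start = 2L,
                            index_exposures = NULL,
                            seed = 1L) {
  known <- c("simulate", "preprocess", "variance", "ewas", "composite",
             "mediate", "index")
  if (!all(stages %in% known)) stop_config("stages", "contains unknown stage names")
  if ("index" %in% stages && !("mediate" %in% stages))
    stop_config("stages", "includes 'index' but not its dependency 'mediate'")
  if (n_perm < 1) stop_config("n_perm", "must be >= 1")
  if (n_boot < 1) stop_config("n_boot", "must be >= 1")
  structure(list(stages = stages, synthetic = synthetic, qc = qc,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 composite_k_start = as.integer(composite_k_start),
                 index_exposures = index_exposures,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration file or object
#'
#' @param config a `pipeline_config`, a plain list, or the path of a JSON
#'   file holding one.
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  problems <- character(0)
  if (is.null(config$seed)) problems <- c(problems, "missing required field: seed")
  if (!is.null(config$n_boot) && config$n_boot < 1)
    problems <- c(problems, "n_boot must be >= 1")
  if (!is.null(config$n_perm) && config$n_perm < 1)
    problems <- c(problems, "n_perm must be >= 1")
  if (!is.null(config$stages)) {
    known <- c("simulate", "preprocess", "variance", "ewas", "composite",
               "mediate", "index")
    bad <- setdiff(config$stages, known)
    if (length(bad)) problems <- c(problems, sprintf("unknown stage(s): %s",
                                                     paste(bad, collapse = ", ")))
    if ("index" %in% config$stages && !("mediate" %in% config$stages))
      problems <- c(problems, "'index' stage requires 'mediate'")
  }
  problems
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in order, writing one delimited artifact
#' per result plus `manifest.json` (file name -> MD5 hash). Each stochastic
#' stage receives a child seed derived from the global seed, so stages are
#' independently reproducible and two runs with the same config are
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest data frame.
#' @export
run_pipeline <- function(config, out_dir) {
  problems <- validate_config(config)
  if (length(problems)) stop(paste(problems, collapse = "; "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(i) derive_seed(config$seed, i)
  files <- character(0)
  res <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if ("simulate" %in% config$stages) {
    res$cohort <- run_stage("simulate", {
      syn <- config$synthetic
      if (!inherits(syn, "synthetic_config")) syn <- do.call(synthetic_config, syn)
      syn$seed <- stage_seed(1L)
      generate_cohort(syn)
    })
    files <- c(files, write_cohort(res$cohort, file.path(out_dir, "cohort")))
  }
  cohort <- res$cohort
  if (is.null(cohort)) stop("pipeline currently requires the simulate stage as data source",
                            call. = FALSE)
  covars <- make_covariate_frame(cohort$covariates)

  if ("preprocess" %in% config$stages) {
    res$preprocess <- run_stage("preprocess", {
      pp <- preprocess_phenotypes(cohort$phenotypes,
                                  day_labels = cohort$covariates$sampling_day,
                                  params = config$qc)
      ex <- knn_impute(apply(cohort$exposures, 2, function(v)
        tryCatch(standardize(v), error = function(e) v)), config$qc$knn_k)
      om <- clip_sd_outliers(cohort$omics, config$qc$sd_clip)$matrix
      om <- knn_impute(om, config$qc$knn_k)
      list(phenotypes = pp$matrix, report = pp$report, exposures = ex, omics = om)
    })
    files <- c(files,
               write_tsv(data.frame(sample_id = rownames(res$preprocess$phenotypes),
                                    res$preprocess$phenotypes, check.names = FALSE),
                         file.path(out_dir, "phenotypes_clean.tsv")),
               write_tsv(res$preprocess$report, file.path(out_dir, "qc_report.tsv")))
  }
  pheno <- if (!is.null(res$preprocess)) res$preprocess$phenotypes else cohort$phenotypes
  expos <- if (!is.null(res$preprocess)) res$preprocess$exposures else cohort$exposures
  omics <- if (!is.null(res$preprocess)) res$preprocess$omics else cohort$omics

  if ("variance" %in% config$stages) {
    res$variance <- run_stage("variance", {
      adj <- residualize_covariates(pheno, covars)
      d <- euclidean_distance(adj)
      scr <- permanova_screen(d, expos, n_perm = config$n_perm, seed = stage_seed(3L))
      pruned <- screen_and_prune(scr, expos)
      list(screen = scr, pruned = pruned)
    })
    files <- c(files, write_tsv(res$variance$pruned$table,
                                file.path(out_dir, "variance_screen.tsv")))
  }

  if ("ewas" %in% config$stages) {
    res$ewas <- run_stage("ewas", run_ewas(pheno, expos, covars))
    files <- c(files, write_tsv(res$ewas, file.path(out_dir, "ewas.tsv")))
  }

  if ("composite" %in% config$stages) {
    res$composite <- run_stage("composite", {
      sel <- select_cluster_count(expos, k_start = config$composite_k_start)
      assoc <- composite_ewas(sel$model, pheno, covars)
      list(selection = sel, associations = assoc)
    })
    files <- c(files,
               write_tsv(data.frame(exposure = names(res$composite$selection$model$clusters),
                                    cluster = res$composite$selection$model$clusters),
                         file.path(out_dir, "composite_clusters.tsv")),
               write_tsv(res$composite$associations,
                         file.path(out_dir, "composite_ewas.tsv")))
  }

  if ("mediate" %in% config$stages) {
    res$mediation <- run_stage("mediate", {
      ew <- res$ewas
      if (is.null(ew)) ew <- run_ewas(pheno, expos, covars)
      pairs <- ew[ew$significant, c("exposure", "phenotype")]
      run_bidirectional_scan(pairs, pheno, expos, omics,
                             covariates = covars, n_boot = config$n_boot,
                             seed = stage_seed(5L))
    })
    files <- c(files, write_tsv(res$mediation, file.path(out_dir, "mediation.tsv")))
  }

  if ("index" %in% config$stages) {
    res$indexes <- run_stage("index", {
      rec <- res$mediation
      targets <- config$index_exposures %||%
        unique(rec$exposure[rec$direction != "none"])
      out <- list()
      for (ex in targets) {
        w <- suppressWarnings(compute_weights(rec, ex))
        if (nrow(w$weights) == 0) next
        sc <- compute_index(omics, w)
        out[[ex]] <- list(weights = w, scores = sc)
      }
      out
    })
    for (ex in names(res$indexes)) {
      files <- c(files,
                 write_tsv(res$indexes[[ex]]$weights$weights,
                           file.path(out_dir, sprintf("index_weights_%s.tsv", ex))),
                 write_tsv(data.frame(sample_id = names(res$indexes[[ex]]$scores$scores),
                                      index = res$indexes[[ex]]$scores$scores),
                           file.path(out_dir, sprintf("index_scores_%s.tsv", ex))))
    }
  }

  manifest <- data.frame(
    file = sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out_dir), "/?"),
               "", files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(manifest = manifest)))
}
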
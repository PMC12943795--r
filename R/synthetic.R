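# Synthetic cohort generator.
#
# Emulates the statistical structure of a deep-phenotyping cohort of ~1,000
# healthy adults: immunophenotypes affected by age/gender/season and a
# sampling-day batch effect, block-correlated self-reported exposures,
# right-skewed phenotype distributions, MCAR missingness, and planted
# exposure -> mediator -> outcome chains in both directions (omic mediator
# or immunophenotype mediator). Every planted effect is recorded in
# `ground_truth` so downstream recovery tests can audit it.

#' Specification of one planted mediation chain
#'
#' @param direction `"D1"` (exposure -> omic -> immunophenotype) or `"D2"`
#'   (exposure -> immunophenotype -> omic).
#' @param exposure_id column index of the driving exposure.
#' @param mediator_id column index of the mediator (omics matrix for D1,
#'   phenotype matrix for D2).
#' @param outcome_id column index of the outcome (phenotype matrix for D1,
#'   omics matrix for D2).
#' @param a_path exposure -> mediator slope.
#' @param b_path mediator -> outcome slope.
#' @param direct_path exposure -> outcome direct slope.
#' @param interaction exposure x mediator interaction slope on the outcome.
#' @param noise_sd residual SD of mediator and outcome models (>= 0; 0 gives
#'   the deterministic limit used by identity tests).
#' @return an object of class `chain_spec`.
#' @export
chain_spec <- function(direction, exposure_id, mediator_id, outcome_id,
                       a_path, b_path, direct_path = 0,
                       interaction = 0, noise_sd = 1) {
  direction <- match.arg(direction, c("D1", "D2"))
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  structure(list(direction = direction,
                 exposure_id = as.integer(exposure_id),
                 mediator_id = as.integer(mediator_id),
                 outcome_id = as.integer(outcome_id),
                 a_path = a_path, b_path = b_path,
                 direct_path = direct_path,
                 interaction = interaction, noise_sd = noise_sd),
            class = "chain_spec")
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the generating world assumed throughout the test suite:
#' 1,000 donors aged 20-60 sampled across 12 months and `batch_count`
#' sampling days, exposures organised in correlated blocks (shared latent
#' factor per block), weak age/gender effects on all phenotypes, a seasonal
#' cosine and a day-level batch shift, 30% of phenotype columns right-skewed,
#' and 5% missingness completely at random.
#'
#' @param n_samples number of donors.
#' @param n_exposures number of exposure variables.
#' @param exposure_block_sizes integer vector; sizes of correlated exposure
#'   blocks (sum must be <= `n_exposures`; remaining exposures independent).
#' @param within_block_r target pairwise correlation within a block, in `[0,1)`.
#' @param n_phenotypes number of immunophenotype columns.
#' @param n_omics number of omics feature columns.
#' @param covariate_effects named numeric vector of standardized effect sizes
#'   added to every phenotype column; names among `age`, `gender`, `bmi`.
#' @param seasonal_amplitude amplitude of the seasonal cosine on phenotypes.
#' @param seasonal_phase peak month in `[0,12)`.
#' @param batch_count number of sampling days.
#' @param batch_sd SD of the per-day batch shift (>= 0).
#' @param mediation_chains list of [chain_spec()] objects.
#' @param missing_rate MCAR missingness proportion in `[0,1)` applied to
#'   phenotype, exposure and omics tables.
#' @param skew_fraction fraction of phenotype columns passed through
#'   `exp(x/2)` to induce right skew, in `[0,1]`.
#' @param seed integer seed; identical configs give identical cohorts.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 1000L,
                             n_exposures = 30L,
                             exposure_block_sizes = c(5L, 5L, 5L),
                             within_block_r = 0.6,
                             n_phenotypes = 50L,
                             n_omics = 100L,
                             covariate_effects = c(age = 0.1, gender = 0.1),
                             seasonal_amplitude = 0.2,
                             seasonal_phase = 3,
                             batch_count = 50L,
                             batch_sd = 0.3,
                             mediation_chains = list(),
                             missing_rate = 0.05,
                             skew_fraction = 0.3,
                             seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_exposures = as.integer(n_exposures),
              exposure_block_sizes = as.integer(exposure_block_sizes),
              within_block_r = within_block_r,
              n_phenotypes = as.integer(n_phenotypes),
              n_omics = as.integer(n_omics),
              covariate_effects = covariate_effects,
              seasonal_amplitude = seasonal_amplitude,
              seasonal_phase = seasonal_phase,
              batch_count = as.integer(batch_count),
              batch_sd = batch_sd,
              mediation_chains = mediation_chains,
              missing_rate = missing_rate,
              skew_fraction = skew_fraction,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 2) stop_config("n_samples", "must be >= 2")
    if (n_exposures < 1) stop_config("n_exposures", "must be >= 1")
    if (sum(exposure_block_sizes) > n_exposures)
      stop_config("exposure_block_sizes", "sum exceeds n_exposures")
    if (within_block_r < 0 || within_block_r >= 1)
      stop_config("within_block_r", "must lie in [0, 1)")
    if (missing_rate < 0 || missing_rate >= 1)
      stop_config("missing_rate", "must lie in [0, 1)")
    if (skew_fraction < 0 || skew_fraction > 1)
      stop_config("skew_fraction", "must lie in [0, 1]")
    if (batch_sd < 0) stop_config("batch_sd", "must be >= 0")
    if (batch_count < 1) stop_config("batch_count", "must be >= 1")
    if (seasonal_phase < 0 || seasonal_phase >= 12)
      stop_config("seasonal_phase", "must lie in [0, 12)")
    if (length(covariate_effects) &&
        !all(names(covariate_effects) %in% c("age", "gender", "bmi")))
      stop_config("covariate_effects", "names must be among age, gender, bmi")
    for (ch in mediation_chains) {
      if (!inherits(ch, "chain_spec")) stop_config("mediation_chains", "entries must be chain_spec objects")
      med_max <- if (ch$direction == "D1") n_omics else n_phenotypes
      out_max <- if (ch$direction == "D1") n_phenotypes else n_omics
      if (ch$exposure_id > n_exposures) stop_config("mediation_chains", "exposure_id out of range")
      if (ch$mediator_id > med_max) stop_config("mediation_chains", "mediator_id out of range")
      if (ch$outcome_id > out_max) stop_config("mediation_chains", "outcome_id out of range")
    }
  })
  invisible(cfg)
}

#' Add sampling-day batch shifts and a seasonal cosine to a matrix
#'
#' Draws one `Normal(0, batch_sd^2)` shift per sampling day and adds it to all
#' of that day's rows, then adds `amplitude * cos(2*pi*(month - phase)/12)`
#' per row. Uses the current RNG state unless `seed` is given.
#'
#' @param mat samples x features numeric matrix.
#' @param sampling_day per-sample day label.
#' @param month per-sample month of year (1-12).
#' @param batch_sd SD of the day shift (>= 0).
#' @param amplitude,phase seasonal cosine amplitude and peak month.
#' @param seed optional integer seed for the day draws.
#' @return the shifted matrix, with the drawn per-day effects in
#'   `attr(, "day_effects")`.
#' @export
inject_batch_and_season <- function(mat, sampling_day, month,
                                    batch_sd = 0, amplitude = 0, phase = 0,
                                    seed = NULL) {
  mat <- as_num_matrix(mat, "mat")
  if (length(sampling_day) != nrow(mat) || length(month) != nrow(mat))
    stop("day and month labels must align with the rows of 'mat'", call. = FALSE)
  if (batch_sd < 0) stop("'batch_sd' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  days <- sort(unique(sampling_day))
  eff <- if (batch_sd > 0) stats::rnorm(length(days), 0, batch_sd) else numeric(length(days))
  names(eff) <- as.character(days)
  shift <- eff[as.character(sampling_day)] +
    amplitude * cos(2 * pi * (month - phase) / 12)
  out <- mat + shift   # recycled column-wise: same shift for every feature
  attr(out, "day_effects") <- eff
  out
}

#' Generate a seeded synthetic cohort
#'
#' @param config a [synthetic_config()].
#' @return a `cohort_bundle` list with elements `phenotypes`, `exposures`,
#'   `omics` (numeric matrices with shared sample-ID rownames),
#'   `covariates` (data frame: age, gender, month, sampling_day, bmi,
#'   genetic PCs), `feature_categories`, and `ground_truth` (planted blocks,
#'   chains, day effects, seasonal and covariate parameters, skewed columns).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%05d", seq_len(n))

  covars <- data.frame(
    age = stats::runif(n, 20, 60),
    gender = factor(ifelse(stats::rbinom(n, 1, 0.5) == 1, "male", "female"),
                    levels = c("female", "male")),
    month = sample.int(12L, n, replace = TRUE),
    sampling_day = sample.int(config$batch_count, n, replace = TRUE),
    bmi = stats::rnorm(n, 23, 3),
    row.names = ids
  )
  for (j in 1:5) covars[[paste0("PC", j)]] <- stats::rnorm(n)

  # exposures: shared latent factor per block, loading sqrt(r) so the
  # expected pairwise within-block correlation equals within_block_r
  expo <- matrix(stats::rnorm(n * config$n_exposures), n, config$n_exposures,
                 dimnames = list(ids, sprintf("expo_%03d", seq_len(config$n_exposures))))
  blocks <- list()
  col <- 1L
  lam <- sqrt(config$within_block_r)
  for (b in seq_along(config$exposure_block_sizes)) {
    s <- config$exposure_block_sizes[b]
    f <- stats::rnorm(n)
    idx <- col:(col + s - 1L)
    expo[, idx] <- lam * f + sqrt(1 - config$within_block_r) * expo[, idx]
    blocks[[b]] <- list(columns = idx, r = config$within_block_r, factor_scores = f)
    col <- col + s
  }

  pheno <- matrix(stats::rnorm(n * config$n_phenotypes), n, config$n_phenotypes,
                  dimnames = list(ids, sprintf("pheno_%03d", seq_len(config$n_phenotypes))))
  omics <- matrix(stats::rnorm(n * config$n_omics), n, config$n_omics,
                  dimnames = list(ids, sprintf("omic_%03d", seq_len(config$n_omics))))

  # planted mediation chains overwrite their mediator/outcome columns
  chain_cols <- integer(0)
  for (ch in config$mediation_chains) {
    x <- expo[, ch$exposure_id]
    m <- ch$a_path * x + ch$noise_sd * stats::rnorm(n)
    y <- ch$direct_path * x + ch$b_path * m +
      ch$interaction * x * m + ch$noise_sd * stats::rnorm(n)
    if (ch$direction == "D1") {
      omics[, ch$mediator_id] <- m
      pheno[, ch$outcome_id] <- y
      chain_cols <- c(chain_cols, ch$outcome_id)
    } else {
      pheno[, ch$mediator_id] <- m
      omics[, ch$outcome_id] <- y
      chain_cols <- c(chain_cols, ch$mediator_id)
    }
  }

  # covariate effects on every phenotype column, in standardized units
  ce <- config$covariate_effects
  if (length(ce)) {
    for (nm in names(ce)) {
      v <- switch(nm,
                  age = covars$age,
                  gender = as.numeric(covars$gender == "male"),
                  bmi = covars$bmi)
      z <- (v - mean(v)) / stats::sd(v)
      pheno <- pheno + ce[[nm]] * z
    }
  }

  pheno <- inject_batch_and_season(pheno, covars$sampling_day, covars$month,
                                   batch_sd = config$batch_sd,
                                   amplitude = config$seasonal_amplitude,
                                   phase = config$seasonal_phase)
  day_effects <- attr(pheno, "day_effects")
  attr(pheno, "day_effects") <- NULL

  # right skew on a fraction of non-chain phenotype columns (monotone map,
  # rank-preserving, so INT-based pipelines can undo it)
  eligible <- setdiff(seq_len(config$n_phenotypes), unique(chain_cols))
  n_skew <- round(config$skew_fraction * config$n_phenotypes)
  skew_cols <- if (n_skew > 0 && length(eligible))
    sort(sample(eligible, min(n_skew, length(eligible)))) else integer(0)
  for (j in skew_cols) pheno[, j] <- exp(pheno[, j] / 2)

  if (config$missing_rate > 0) {
    for (nm in c("pheno", "expo", "omics")) {
      m <- get(nm)
      mask <- matrix(stats::runif(length(m)) < config$missing_rate, nrow(m), ncol(m))
      m[mask] <- NA_real_
      assign(nm, m)
    }
  }

  categories <- list(
    phenotypes = rep(c("proportion", "MFI", "morphology", "cytokine"),
                     length.out = config$n_phenotypes),
    exposures = rep(c("sleep", "diet", "physical_activity", "smoking",
                      "alcohol", "mental_health"),
                    length.out = config$n_exposures)
  )

  structure(list(
    phenotypes = pheno,
    exposures = expo,
    omics = omics,
    covariates = covars,
    feature_categories = categories,
    ground_truth = list(
      blocks = blocks,
      chains = config$mediation_chains,
      day_effects = day_effects,
      seasonal = list(amplitude = config$seasonal_amplitude,
                      phase = config$seasonal_phase),
      covariate_effects = config$covariate_effects,
      skewed_columns = skew_cols
    ),
    config = config
  ), class = "cohort_bundle")
}

#' Write a cohort bundle to delimited text files
#'
#' One tab-separated table per data block (samples as rows, `NA` for
#' missing) plus `ground_truth.json`.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths,
             wr(bundle$phenotypes, "phenotypes"),
             wr(bundle$exposures, "exposures"),
             wr(bundle$omics, "omics"),
             wr(as.data.frame(lapply(bundle$covariates, function(v)
               if (is.factor(v)) as.character(v) else v),
               row.names = rownames(bundle$covariates)), "covariates"))
  gt <- bundle$ground_truth
  gt$chains <- lapply(gt$chains, unclass)
  gt$blocks <- lapply(gt$blocks, function(b) b[c("columns", "r")])
  gtp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gtp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, gtp))
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing the tables.
#' @return a list with the same matrix/data-frame elements.
#' @export
read_cohort <- function(dir) {
  rd <- function(name) {
    df <- utils::read.table(file.path(dir, paste0(name, ".tsv")),
                            header = TRUE, sep = "\t", check.names = FALSE)
    rn <- df$sample_id
    m <- as.matrix(df[setdiff(names(df), "sample_id")])
    rownames(m) <- rn
    m
  }
  cov <- utils::read.table(file.path(dir, "covariates.tsv"),
                           header = TRUE, sep = "\t", check.names = FALSE)
  rownames(cov) <- cov$sample_id
  cov$sample_id <- NULL
  cov$gender <- factor(cov$gender, levels = c("female", "male"))
  list(phenotypes = rd("phenotypes"), exposures = rd("exposures"),
       omics = rd("omics"), covariates = cov)
}
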
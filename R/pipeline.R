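#' Full-run configuration
#'
#' Exactly one input source: a cohort CSV path or a synthetic
#' [cohort_config()]. A single master seed fans out to per-stage seeds
#' by fixed offsets, so stages stay reproducible in isolation.
#'
#' @param input_csv Path to a cohort CSV, or `NULL` to simulate.
#' @param synthetic A [cohort_config()], or `NULL` to read `input_csv`.
#' @param grouping_spec See [default_grouping_spec()].
#' @param income_schema An [income_schema()].
#' @param density_map Named state -> density vector.
#' @param missing_mode Design-matrix missing handling; see
#'   [build_design_matrix()].
#' @param tuning A [tuning_config()]; its seed is overridden from the
#'   master seed.
#' @param bootstrap A [bootstrap_config()]; its seed is overridden from
#'   the master seed.
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_csv = NULL, synthetic = NULL,
                       grouping_spec = default_grouping_spec(),
                       income_schema = prepbarriers::income_schema(),
                       density_map = default_density_map(),
                       missing_mode = "separate_category",
                       tuning = tuning_config(),
                       bootstrap = bootstrap_config(),
                       seed = 1L, out_dir = NULL) {
  if (is.null(input_csv) == is.null(synthetic)) {
    stop("exactly one of `input_csv` and `synthetic` must be given",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  if (!is.null(synthetic)) synthetic$seed <- derive_seed(seed, "simulate")
  tuning$seed <- derive_seed(seed, "tune")
  bootstrap$seed <- derive_seed(seed, "bootstrap")
  structure(list(input_csv = input_csv, synthetic = synthetic,
                 grouping_spec = grouping_spec,
                 income_schema = income_schema, density_map = density_map,
                 missing_mode = missing_mode, tuning = tuning,
                 bootstrap = bootstrap, seed = seed, out_dir = out_dir),
            class = "run_config")
}

# fixed per-stage offsets from the master seed; kept below 2^31
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, tune = 211L, bootstrap = 307L)
  ((abs(seed) %% 2000000L) * 1009L + offsets[[stage]]) %% 2147483647L
}

#' Run the whole analysis
#'
#' Executes the pipeline stages in fixed order: simulate or load the
#' cohort, recode declined/don't-know answers as missing, apply the
#' selection flow, derive grouped covariates, build the design matrix,
#' tune and choose the elastic-net model, bootstrap its coefficients,
#' and run the stratified reasons-for-non-use analyses plus the
#' per-state user-proportion table. A rerun with an identical
#' configuration reproduces the report exactly.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: list with `ledger`, `chosen`
#'   (hyperparameters and coefficients), `bootstrap` (the
#'   [bootstrap_summary()]), `reasons_by_indication`,
#'   `reasons_by_density`, `user_proportion` and `fingerprint`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  records <- stage("input", {
    if (!is.null(config$synthetic)) {
      inject_missingness(generate_cohort(config$synthetic),
                         config$synthetic$missing_rate,
                         seed = config$synthetic$seed)
    } else {
      read_cohort_csv(config$input_csv)
    }
  })
  records <- stage("recode_missing", recode_missing(records))
  cohort <- stage("selection", apply_selection_flow(records))
  analysis <- stage("covariates", {
    prepare_covariates(cohort$records, config$income_schema,
                       config$density_map)
  })
  dm <- stage("design_matrix", {
    build_design_matrix(analysis, config$grouping_spec, config$missing_mode)
  })
  selection_fit <- stage("model_selection", tune_and_choose(dm, config$tuning))
  chosen <- selection_fit$chosen
  reps <- stage("bootstrap", {
    bootstrap_coefficients(dm, chosen$mixing, chosen$strength,
                           config$bootstrap)
  })
  boot <- stage("bootstrap_summary",
                bootstrap_summary(reps, chosen, config$bootstrap$ci_level))
  reasons_ind <- stage("reasons_by_indication",
                       build_reason_analysis(analysis, "indication"))
  reasons_den <- stage("reasons_by_density",
                       build_reason_analysis(analysis, "density"))
  props <- stage("user_proportion", {
    counts <- stats::aggregate(
      cbind(n_participants = rep(1, nrow(analysis)),
            n_users = analysis$prep_status == "current"),
      by = list(state = analysis$federal_state), FUN = sum)
    user_proportion(counts[counts$state != "missing", , drop = FALSE])
  })
  report <- structure(list(
    ledger = cohort$ledger,
    chosen = list(mixing = chosen$mixing, strength = chosen$strength,
                  intercept = chosen$intercept,
                  n_nonzero = chosen$n_nonzero, aic = chosen$aic,
                  beta = as.list(chosen$beta)),
    tuning_grid = selection_fit$grid,
    bootstrap = boot,
    reasons_by_indication = reasons_ind,
    reasons_by_density = reasons_den,
    user_proportion = props,
    fingerprint = list(
      package = "prepbarriers",
      version = as.character(utils::packageVersion("prepbarriers")),
      seed = config$seed,
      missing_mode = config$missing_mode,
      n_bootstrap = config$bootstrap$n_samples
    )
  ), class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a run report to disk
#'
#' JSON report plus the main tables as CSV.
#'
#' @param report A [run_full()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (tab in c("ledger", "tuning_grid", "bootstrap",
                "reasons_by_indication", "reasons_by_density",
                "user_proportion")) {
    utils::write.csv(report[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$fingerprint$seed, ")\n")
  cat("  selection:", x$ledger$n_after[nrow(x$ledger)], "records retained\n")
  cat(sprintf("  chosen model: mixing %.2f, strength %.4g, %d non-zero\n",
              x$chosen$mixing, x$chosen$strength, x$chosen$n_nonzero))
  cat("  bootstrap columns:", nrow(x$bootstrap), "\n")
  invisible(x)
}
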
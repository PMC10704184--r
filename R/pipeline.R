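#' Build a pipeline run configuration
#'
#' Collects every knob of an end-to-end run (generate -> sequester ->
#' evaluate) into one serializable list. The effective configuration is
#' echoed as JSON into the output directory, and together with the seed it
#' fully determines every numeric output.
#'
#' @param out_dir Output directory for reports.
#' @param scheme_path Path to a scheme JSON, or `NULL` for the default
#'   scheme.
#' @param batch_path Path to an input batch CSV, or `NULL` to generate a
#'   synthetic cohort of `n_patients`.
#' @param registry_path Path to a persistent registry CSV, or `NULL` to
#'   start empty (the updated registry is written next to the reports).
#' @param n_patients Cohort size when generating.
#' @param exact_marginals Generate the synthetic cohort with exact
#'   reference marginal counts instead of sampling them.
#' @param open_fraction Target open fraction (overrides the scheme's when
#'   non-NULL).
#' @param n_trials Evaluation trials per sampler.
#' @param seed Master seed.
#' @param alpha Family-wise significance level.
#' @param arm Arm on which scaled differences are evaluated.
#' @param make_figures Write per-variable histogram figures.
#' @param device Graphics device for figures.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, scheme_path = NULL, batch_path = NULL,
                       registry_path = NULL, n_patients = 5000,
                       exact_marginals = FALSE, open_fraction = NULL,
                       n_trials = 2000, seed = 1L, alpha = 0.05,
                       arm = "open", make_figures = FALSE,
                       device = "pdf") {
  structure(list(out_dir = out_dir, scheme_path = scheme_path,
                 batch_path = batch_path, registry_path = registry_path,
                 n_patients = n_patients,
                 exact_marginals = exact_marginals,
                 open_fraction = open_fraction, n_trials = n_trials,
                 seed = as.integer(seed), alpha = alpha, arm = arm,
                 make_figures = make_figures, device = device),
            class = "run_config")
}

#' Run the full sequestration and evaluation pipeline
#'
#' Loads (or generates) a batch, sequesters it against the registry,
#' evaluates both samplers over repeated trials, and writes
#' `assignments.csv`, `registry.csv`, `prevalence_summary.csv` (mean (SD)
#' prevalence per subcategory and arm), `comparison.csv` (per-subcategory
#' Mann-Whitney results with Holm flags), optional histogram figures, and
#' `config.json`. Progress and diagnostics — batch size, instantiated vs.
#' theoretical strata, realized open fraction — are logged via
#' [message()].
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the report paths and the in-memory
#'   results (`assignment`, `prevalence`, `comparison`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  scheme <- if (is.null(config$scheme_path)) default_scheme() else
    read_scheme(config$scheme_path)
  f <- config$open_fraction %||% scheme$open_fraction

  batch <- if (is.null(config$batch_path)) {
    message("Generating synthetic cohort of ", config$n_patients,
            " patients (seed ", config$seed, ")")
    if (config$exact_marginals) {
      exact_marginal_cohort(seed = config$seed, scheme = scheme)
    } else {
      generate_cohort(cohort_spec(config$n_patients, scheme = scheme),
                      seed = config$seed)
    }
  } else {
    read_batch(config$batch_path)
  }
  message("Batch: ", nrow(batch), " patients")

  registry <- if (is.null(config$registry_path)) new_registry() else
    read_registry(config$registry_path)
  assignment <- sequester_batch(batch, registry, scheme,
                                seed = config$seed,
                                open_fraction = f)
  n_open <- sum(assignment$assignments$arm == "open")
  n_strata <- length(unique(stats::na.omit(assignment$assignments$stratum)))
  message("Instantiated strata: ", n_strata, " of ", count_strata(scheme),
          " theoretical")
  message(sprintf("Realized open fraction: %.4f (target %.2f)",
                  n_open / nrow(batch), f))

  write_assignment(assignment, file.path(config$out_dir, "assignments.csv"))
  write_registry(assignment$registry,
                 file.path(config$out_dir, "registry.csv"))

  message("Evaluating ", config$n_trials, " trials per sampler")
  strat <- run_trials(batch, scheme, "stratified", config$n_trials,
                      config$seed, f)
  naiv <- run_trials(batch, scheme, "naive", config$n_trials,
                     config$seed, f)
  prevalence <- prevalence_summary(strat)
  comparison <- compare_samplers(batch, scheme, config$n_trials,
                                 config$seed, config$alpha, f, config$arm)
  message("Mann-Whitney comparisons evaluated: ",
          attr(comparison, "n_comparisons"))

  paths <- list(
    prevalence = write_report_csv(
      prevalence, file.path(config$out_dir, "prevalence_summary.csv"),
      config$seed, config$n_trials),
    comparison = write_report_csv(
      dplyr::mutate(tibble::as_tibble(comparison),
                    p_formatted = format_p_value(.data$p_value)),
      file.path(config$out_dir, "comparison.csv"),
      config$seed, config$n_trials))

  if (isTRUE(config$make_figures)) {
    paths$figures <- save_histogram_reports(
      strat, naiv, scheme, file.path(config$out_dir, "figures"),
      arm = config$arm, device = config$device)
  }

  cfg <- unclass(config)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, assignment = assignment,
                 prevalence = prevalence, comparison = comparison))
}
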
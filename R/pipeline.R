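# End-to-end orchestration of the synthetic study: generate a cohort,
# apply the behavioural exclusion rules, refit every retained subject's
# choice model, run the inter-individual correlations, the mediations and
# the serial path model, and collect everything in one reproducible report.

#' Pipeline configuration
#'
#' Bundles the task design, cohort generator and fitting options under a
#' single master seed from which every stage draws its own substream, so the
#' whole synthetic study is reproducible from one integer.
#'
#' @param task A [task_config()].
#' @param cohort A [cohort_config()] (its `task` field is overridden by
#'   `task`).
#' @param seed Master seed (integer).
#' @param refit Refit each retained subject's parameters with [fit_map()]
#'   (default TRUE); the refitted `kEp_hat`/`kEm_hat` — not the generating
#'   values — enter the inter-individual statistics, as they would with real
#'   data.
#' @param fit_restarts Restarts per subject fit.
#' @param out_dir Optional directory; when given, the cohort table, the
#'   correlation table and a JSON report are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(task = task_config(), cohort = cohort_config(),
                       seed = 1, refit = TRUE, fit_restarts = 5,
                       out_dir = NULL) {
  stopifnot(inherits(task, "task_config"), inherits(cohort, "cohort_config"))
  cohort$task <- task
  structure(list(task = task, cohort = cohort, seed = as.integer(seed),
                 refit = refit, fit_restarts = fit_restarts,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full synthetic study
#'
#' Stages, in order: (1) generate the cohort with [generate_cohort()];
#' (2) apply the near-exclusive high-effort subject rule
#' ([subject_exclusion()]) and the single-option block rule
#' ([block_exclusion()]); (3) refit each retained subject by MAP on the
#' retained blocks; (4) compute the lactate-vs-behaviour correlation table
#' with per-analysis outlier filtering; (5) run the mediations
#' (dmPFC/dACC lactate -> neural effort sensitivity -> physical-effort
#' choices, and the same for fitted kEp) and the serial path model
#' (plasma -> dmPFC/dACC lactate -> neural sensitivity -> behaviour).
#' Every excluded subject or block is attributed to its rule in the report.
#'
#' @param config A [run_config()].
#' @return An object of class `effort_run`: `subjects` (analysis table with
#'   fitted parameters), `excluded` (per-rule lists), `heatmap`
#'   (correlation table), `mediation_hpe`, `mediation_kep`, `path_hpe`,
#'   `analysis_n` (complete-case Ns per analysis), `fit_failures`, `seed`,
#'   `config`, and the package `version`.
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(cohort = cohort_config(n_subjects = 20),
#'                                seed = 1, fit_restarts = 2))
#' run$mediation_hpe
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  withr::local_seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 3)

  cohort <- generate_cohort(config$cohort, seed = stage_seeds[1])
  subjects <- cohort$subjects

  excl_subj <- subject_exclusion(cohort$choices)
  excl_blocks <- lapply(cohort$choices, block_exclusion)
  excl_blocks <- excl_blocks[vapply(excl_blocks, length, integer(1)) > 0]

  keep <- !(subjects$id %in% excl_subj)
  subjects <- subjects[keep, , drop = FALSE]

  fit_failures <- character(0)
  if (config$refit && length(cohort$choices)) {
    withr::local_seed(stage_seeds[2])
    fit_seeds <- sample.int(.Machine$integer.max, nrow(subjects))
    subjects$kEp_hat <- subjects$kEm_hat <- NA_real_
    for (i in seq_len(nrow(subjects))) {
      id <- subjects$id[i]
      rec <- cohort$choices[[id]]
      bad <- excl_blocks[[id]]
      if (!is.null(bad)) rec <- rec[!rec$block_index %in% bad, , drop = FALSE]
      fit <- tryCatch(
        fit_map(rec, seed = fit_seeds[i], n_restarts = config$fit_restarts),
        error = function(e) NULL)
      if (is.null(fit) || !fit$convergence) {
        fit_failures <- c(fit_failures, id)
        next
      }
      subjects$kEp_hat[i] <- fit$estimates[["kEp"]]
      subjects$kEm_hat[i] <- fit$estimates[["kEm"]]
    }
  }

  lactate_vars <- c("plasma_lactate", "dmpfc_lactate", "ains_lactate")
  behav_vars <- intersect(c("prop_HE", "prop_HPE", "prop_HME",
                            "kEp_hat", "kEm_hat"), names(subjects))
  behav_vars <- behav_vars[colSums(!is.na(subjects[behav_vars])) >= 4]
  heat <- if (length(behav_vars)) {
    correlation_heatmap(subjects, rows = lactate_vars, cols = behav_vars)
  }

  run_mediation <- function(xv, mv, yv) {
    vars <- c(xv, mv, yv)
    keep <- outlier_filter(subjects, vars = vars)
    res <- simple_mediation(subjects[[xv]][keep], subjects[[mv]][keep],
                            subjects[[yv]][keep])
    res$variables <- stats::setNames(vars, c("x", "m", "y"))
    res
  }
  mediation_hpe <- mediation_kep <- path_hpe <- NULL
  analysis_n <- list()
  if (length(cohort$choices)) {
    mediation_hpe <- run_mediation("dmpfc_lactate", "ech_beta_dmpfc",
                                   "prop_HPE")
    analysis_n$mediation_hpe <- mediation_hpe$n
    if ("kEp_hat" %in% behav_vars) {
      mediation_kep <- run_mediation("dmpfc_lactate", "ech_beta_dmpfc",
                                     "kEp_hat")
      analysis_n$mediation_kep <- mediation_kep$n
    }
    pvars <- c("plasma_lactate", "dmpfc_lactate", "ech_beta_dmpfc",
               "prop_HPE")
    pkeep <- outlier_filter(subjects, vars = pvars)
    path_hpe <- serial_path_model(
      subjects$plasma_lactate[pkeep], subjects$dmpfc_lactate[pkeep],
      subjects$ech_beta_dmpfc[pkeep], subjects$prop_HPE[pkeep],
      names = c("plasma_lac", "dmpfc_lac", "ech_beta", "prop_HPE"))
    analysis_n$path_hpe <- path_hpe$n
  }

  report <- structure(list(
    subjects = subjects,
    excluded = list(high_effort_subjects = excl_subj,
                    single_option_blocks = excl_blocks,
                    fit_failures = fit_failures),
    heatmap = heat,
    mediation_hpe = mediation_hpe,
    mediation_kep = mediation_kep,
    path_hpe = path_hpe,
    analysis_n = analysis_n,
    seed = config$seed,
    config = config,
    version = as.character(utils::packageVersion("effortpath"))
  ), class = "effort_run")

  if (!is.null(config$out_dir)) write_run(report, config$out_dir)
  report
}

#' @export
print.effort_run <- function(x, ...) {
  cat(sprintf("Synthetic study run (seed %d, package %s)\n", x$seed,
              x$version))
  cat(sprintf("  %d subjects analysed; excluded: %d (>95%% HE rule), blocks: %d, fit failures: %d\n",
              nrow(x$subjects), length(x$excluded$high_effort_subjects),
              length(x$excluded$single_option_blocks),
              length(x$excluded$fit_failures)))
  if (!is.null(x$mediation_hpe)) {
    cat(sprintf("  mediation (dmPFC lactate -> Ech beta -> HPE): p = %.4g, %s (n = %d)\n",
                x$mediation_hpe$mediation_p,
                if (x$mediation_hpe$significant) "significant" else "not significant",
                x$mediation_hpe$n))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes the analysis subject table and correlation table as CSV and the
#' numerical results as JSON.
#'
#' @param report An `effort_run` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(report$heatmap)) {
    utils::write.csv(as.data.frame(report$heatmap),
                     file.path(dir, "correlations.csv"), row.names = FALSE)
  }
  strip <- function(m) if (is.null(m)) NULL else
    m[setdiff(names(m), "variables")]
  json <- list(
    seed = report$seed,
    version = report$version,
    n_analysed = nrow(report$subjects),
    excluded = report$excluded,
    analysis_n = report$analysis_n,
    mediation_hpe = strip(unclass(report$mediation_hpe)),
    mediation_kep = strip(unclass(report$mediation_kep)),
    path_hpe = if (!is.null(report$path_hpe)) list(
      edges = report$path_hpe$edges,
      r_squared = as.list(report$path_hpe$r_squared),
      n = report$path_hpe$n)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# ---- Table IO with schema validation -------------------------------------

.SUBJECT_SCHEMA <- list(
  id = "character",
  plasma_lactate = "numeric", dmpfc_lactate = "numeric",
  ains_lactate = "numeric",
  ech_beta_dmpfc = "numeric", ech_beta_ains = "numeric",
  kR = "numeric", kP = "numeric", kEp = "numeric", kEm = "numeric",
  kFp = "numeric", kLm = "numeric", kBias = "numeric",
  prop_HE = "numeric", prop_HPE = "numeric", prop_HME = "numeric"
)

.TRIAL_SCHEMA <- list(
  block_index = "numeric", trial_index = "numeric",
  domain = "character", valence = "character",
  he_incentive = "numeric", he_effort = "numeric",
  le_incentive = "numeric", le_effort = "numeric"
)

.validate_schema <- function(df, schema, optional = character(0),
                             what = "table") {
  problems <- character(0)
  for (col in names(schema)) {
    if (!col %in% names(df)) {
      if (col %in% optional) {
        df[[col]] <- if (schema[[col]] == "numeric") NA_real_ else
          NA_character_
      } else {
        problems <- c(problems, sprintf("missing column '%s'", col))
      }
      next
    }
    x <- df[[col]]
    ok <- switch(schema[[col]],
                 numeric = is.numeric(x) || all(is.na(x)),
                 character = is.character(x) || all(is.na(x)))
    if (!ok) {
      problems <- c(problems,
                    sprintf("column '%s' should be %s, found %s",
                            col, schema[[col]], class(x)[1]))
    }
  }
  if (length(problems)) {
    stop(what, " failed validation:\n  ",
         paste(problems, collapse = "\n  "))
  }
  df
}

#' Write / read the subject-level cohort table
#'
#' CSV round-trip for the per-subject table. Missing values are encoded as
#' empty cells and never imputed. Reading validates the schema and reports
#' each violated column; the optional aIns column, if absent, is loaded as
#' all-missing.
#'
#' @param subjects A subject-level data frame (e.g. `cohort$subjects`).
#' @param path CSV file path.
#' @return `write_subject_table()` returns `path` invisibly;
#'   `read_subject_table()` returns the validated data frame.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_schema(df, .SUBJECT_SCHEMA, optional = "ains_lactate",
                   what = "subject table")
}

#' Write / read a per-trial table
#'
#' CSV round-trip for session or choice-record tables with schema
#' validation on read.
#'
#' @param trials A session or choice-record data frame.
#' @param path CSV file path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` the validated data frame.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_schema(df, .TRIAL_SCHEMA, what = "trial table")
}
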
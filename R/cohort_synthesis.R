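# Synthetic inter-individual cohort. Latent standardised variables follow the
# hypothesised causal chain plasma lactate -> dmPFC/dACC lactate -> physical
# effort sensitivity -> neural effort sensitivity; behavioural choice
# proportions are not drawn directly but emerge from simulating each
# subject's full session with their own parameters, so mediation tests on
# proportions are not circular by construction.

#' Cohort generator configuration
#'
#' Standardised path coefficients default to the correlations the study
#' design targets: plasma to dmPFC/dACC lactate 0.314, dmPFC/dACC lactate to
#' physical effort sensitivity (log kEp) 0.317, kEp to the neural effort
#' sensitivity (Ech regression estimate) 0.403. The dmPFC/dACC-lactate
#' association with high-physical-effort choices (about -0.33) is not set
#' directly: it is realised through the chain and the task simulation. The
#' anterior-insula analogue couples weakly to dmPFC/dACC lactate (0.236
#' trend) and carries no path of its own by default, matching the regional
#' specificity of the effect.
#'
#' @param n_subjects Cohort size; default 63.
#' @param r_plasma_dmpfc Standardised path plasma lactate -> dmPFC/dACC
#'   lactate. Default 0.314.
#' @param r_dmpfc_kep Standardised path dmPFC/dACC lactate -> log kEp.
#'   Default 0.317.
#' @param r_kep_echbeta Standardised path log kEp -> dmPFC/dACC Ech
#'   regression estimate. Default 0.403.
#' @param r_dmpfc_ains Standardised coupling dmPFC/dACC -> aIns lactate.
#'   Default 0.236.
#' @param r_ains_echbeta Standardised path aIns lactate -> aIns Ech estimate.
#'   Default 0 (no aIns-specific effect).
#' @param kep_meanlog,kep_sdlog Location/scale of kEp on the log scale; the
#'   latent chain shifts log kEp by `kep_sdlog` standard units.
#' @param missing_plasma,missing_dmpfc,missing_ains Per-subject missingness
#'   probabilities for the three lactate measures; defaults 1/63, 2/63 and
#'   18/63.
#' @param dt_params A [dt_model()] used when simulating sessions.
#' @param simulate_sessions Simulate each subject's full session and derive
#'   choice proportions (default). Disable for large cohorts where only the
#'   latent correlation structure is needed.
#' @param task A [task_config()] for the simulated sessions.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 63L,
                          r_plasma_dmpfc = 0.314,
                          r_dmpfc_kep = 0.317,
                          r_kep_echbeta = 0.403,
                          r_dmpfc_ains = 0.236,
                          r_ains_echbeta = 0,
                          kep_meanlog = log(0.7),
                          kep_sdlog = 0.4,
                          missing_plasma = 1 / 63,
                          missing_dmpfc = 2 / 63,
                          missing_ains = 18 / 63,
                          dt_params = dt_model(),
                          simulate_sessions = TRUE,
                          task = task_config()) {
  rs <- c(r_plasma_dmpfc = r_plasma_dmpfc, r_dmpfc_kep = r_dmpfc_kep,
          r_kep_echbeta = r_kep_echbeta, r_dmpfc_ains = r_dmpfc_ains,
          r_ains_echbeta = r_ains_echbeta)
  if (any(abs(rs) >= 1)) {
    stop("standardised path coefficients must have |r| < 1")
  }
  miss <- c(missing_plasma, missing_dmpfc, missing_ains)
  if (any(miss < 0 | miss > 1)) stop("missingness rates must lie in [0, 1]")
  stopifnot(n_subjects >= 1, kep_sdlog > 0, inherits(task, "task_config"))
  structure(list(
    n_subjects = as.integer(n_subjects),
    r_plasma_dmpfc = r_plasma_dmpfc,
    r_dmpfc_kep = r_dmpfc_kep,
    r_kep_echbeta = r_kep_echbeta,
    r_dmpfc_ains = r_dmpfc_ains,
    r_ains_echbeta = r_ains_echbeta,
    kep_meanlog = kep_meanlog,
    kep_sdlog = kep_sdlog,
    missing_plasma = missing_plasma,
    missing_dmpfc = missing_dmpfc,
    missing_ains = missing_ains,
    dt_params = dt_params,
    simulate_sessions = simulate_sessions,
    task = task
  ), class = "cohort_config")
}

# x = r * parent + sqrt(1 - r^2) * noise keeps children standardised.
.chain_child <- function(parent, r) {
  r * parent + sqrt(1 - r^2) * stats::rnorm(length(parent))
}

#' Generate a synthetic inter-individual cohort
#'
#' Draws the latent standardised chain (plasma lactate -> dmPFC/dACC lactate
#' -> log kEp -> dmPFC/dACC Ech estimate, with an aIns analogue), maps the
#' kEp latent into the behavioural parameter via the log link, samples the
#' remaining behavioural parameters independently, simulates each subject's
#' full session with [simulate_choices()], derives high-effort choice
#' proportions (overall, physical, mental), and finally injects missingness
#' into the lactate measures at the configured rates.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; the whole cohort is reproducible from
#'   it.
#' @return An object of class `effort_cohort` with elements `subjects` (one
#'   row per subject: lactate measures, Ech estimates, behavioural
#'   parameters, choice proportions), `choices` (named list of per-subject
#'   choice-record tables; empty when sessions are not simulated), `config`
#'   and `seed`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 8), seed = 1)
#' head(coh$subjects)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- config$n_subjects

  z_plasma <- stats::rnorm(n)
  z_dmpfc <- .chain_child(z_plasma, config$r_plasma_dmpfc)
  z_ains <- .chain_child(z_dmpfc, config$r_dmpfc_ains)
  z_kep <- .chain_child(z_dmpfc, config$r_dmpfc_kep)
  z_echb <- .chain_child(z_kep, config$r_kep_echbeta)
  z_echb_ains <- .chain_child(z_ains, config$r_ains_echbeta)

  pars <- default_param_sampler(n)
  pars$kEp <- exp(config$kep_meanlog + config$kep_sdlog * z_kep)

  miss <- cbind(
    plasma = stats::runif(n) < config$missing_plasma,
    dmpfc = stats::runif(n) < config$missing_dmpfc,
    ains = stats::runif(n) < config$missing_ains
  )

  subjects <- data.frame(
    id = sprintf("s%03d", seq_len(n)),
    plasma_lactate = z_plasma,
    dmpfc_lactate = z_dmpfc,
    ains_lactate = z_ains,
    ech_beta_dmpfc = z_echb,
    ech_beta_ains = z_echb_ains,
    pars,
    prop_HE = NA_real_, prop_HPE = NA_real_, prop_HME = NA_real_,
    stringsAsFactors = FALSE
  )

  choices <- list()
  if (config$simulate_sessions) {
    seeds <- matrix(sample.int(.Machine$integer.max, 2L * n), ncol = 2L)
    for (i in seq_len(n)) {
      p <- do.call(model_params, as.list(pars[i, .PARAM_NAMES]))
      first <- if (i %% 2L == 1L) "physical" else "mental"
      session <- generate_session(config$task, first_domain = first,
                                  seed = seeds[i, 1])
      rec <- simulate_choices(session, p, seed = seeds[i, 2],
                              dt_params = config$dt_params)
      choices[[subjects$id[i]]] <- rec
      ok <- !rec$missed
      subjects$prop_HE[i] <- mean(rec$chosen[ok] == "HE")
      subjects$prop_HPE[i] <- mean(rec$chosen[ok & rec$domain == "physical"] == "HE")
      subjects$prop_HME[i] <- mean(rec$chosen[ok & rec$domain == "mental"] == "HE")
    }
  }

  subjects$plasma_lactate[miss[, "plasma"]] <- NA_real_
  subjects$dmpfc_lactate[miss[, "dmpfc"]] <- NA_real_
  subjects$ains_lactate[miss[, "ains"]] <- NA_real_

  structure(list(subjects = subjects, choices = choices,
                 config = config, seed = seed),
            class = "effort_cohort")
}

#' @export
print.effort_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("Synthetic cohort of %d subjects (%s sessions)\n", nrow(s),
              if (length(x$choices)) "with simulated" else "without"))
  cat(sprintf("  missing: plasma %d, dmPFC/dACC %d, aIns %d\n",
              sum(is.na(s$plasma_lactate)), sum(is.na(s$dmpfc_lactate)),
              sum(is.na(s$ains_lactate))))
  if (length(x$choices)) {
    cat(sprintf("  mean choice rates: HE %.1f%%, HPE %.1f%%, HME %.1f%%\n",
                100 * mean(s$prop_HE), 100 * mean(s$prop_HPE),
                100 * mean(s$prop_HME)))
  }
  invisible(x)
}
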
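# Per-subject inversion of the choice model: MAP estimation in a transformed
# parameter space (log for the positive sensitivities, identity for the bias)
# with independent standard-normal priors, multistart BFGS, and a Laplace
# approximation to the model evidence. Recovery simulations and the
# validating behavioural GLM live here too.

# Pre-extracts the fitting design from a record table. Missed trials are
# excluded; fatigue/learning trajectories are reconstructed from the observed
# chosen efforts if absent (they are data, not parameters).
choice_design <- function(records) {
  if (nrow(records) > 0 &&
      (is.null(records$fatigue) || is.null(records$learning))) {
    records <- accumulate_states(records)
  }
  r <- records[!records$missed, , drop = FALSE]
  list(
    y = r$chosen == "HE",
    is_reward = r$valence == "reward",
    is_physical = r$domain == "physical",
    d_incentive = r$he_incentive - r$le_incentive,
    d_effort = r$he_effort - r$le_effort,
    F = r$fatigue,
    L = r$learning,
    n = nrow(r)
  )
}

# theta lives on the unconstrained scale: log k for sensitivities, identity
# for kBias. Fixed (non-free) parameters are pinned at 0 on the natural scale.
theta_to_params <- function(theta, free = .PARAM_NAMES) {
  p <- stats::setNames(numeric(length(.PARAM_NAMES)), .PARAM_NAMES)
  for (i in seq_along(free)) {
    nm <- free[i]
    p[nm] <- if (nm == "kBias") theta[i] else exp(theta[i])
  }
  structure(p, class = "model_params")
}

params_to_theta <- function(params, free = .PARAM_NAMES) {
  vapply(free, function(nm) {
    if (nm == "kBias") params[[nm]] else log(params[[nm]])
  }, numeric(1))
}

#' Negative log posterior of the choice model
#'
#' `-sum(log Bernoulli(chosen | p_he))` plus the negative log density of
#' independent Normal priors on the transformed parameters (log sensitivities
#' and raw bias). This is the objective minimised by [fit_map()].
#'
#' @param theta Numeric vector of transformed parameters, one entry per
#'   element of `free`.
#' @param records A choice-record data frame (missed trials are excluded).
#' @param free Character vector naming the free parameters (subset of
#'   kR, kP, kEp, kEm, kFp, kLm, kBias); the rest are fixed at 0.
#' @param prior_mean,prior_sd Prior mean and SD on each transformed
#'   coordinate (defaults 0 and 1).
#' @return The scalar negative log posterior (finite for finite `theta`).
#' @export
neg_log_posterior <- function(theta, records, free = .PARAM_NAMES,
                              prior_mean = 0, prior_sd = 1) {
  if (any(!is.finite(theta))) stop("non-finite theta")
  design <- if (is.list(records) && !is.data.frame(records) &&
                !is.null(records$is_reward)) records else choice_design(records)
  .nlp(theta, design, free, prior_mean, prior_sd)
}

.nlp <- function(theta, design, free, prior_mean = 0, prior_sd = 1) {
  params <- theta_to_params(theta, free)
  dsv <- .delta_sv(params, design$is_reward, design$is_physical,
                   design$d_incentive, design$d_effort, design$F, design$L)
  s <- ifelse(design$y, 1, -1)
  ll <- sum(stats::plogis(s * dsv, log.p = TRUE))
  lp <- sum(stats::dnorm(theta, prior_mean, prior_sd, log = TRUE))
  -(ll + lp)
}

#' Fit the choice model by MAP with Laplace evidence
#'
#' Minimises the negative log posterior by BFGS from `n_restarts` seeded
#' starting points (the prior mean plus standard-normal draws), keeps the
#' best mode (ties broken by the smaller parameter norm), and computes the
#' Laplace approximation to the log model evidence,
#' `-NLP(mode) + (d/2) log(2*pi) - log|H| / 2`, from the numerical Hessian at
#' the mode.
#'
#' @param records A choice-record data frame; missed trials are excluded and
#'   blocks failing upstream filters should be removed beforehand.
#' @param free Free parameters to estimate; the rest are fixed at 0 (useful
#'   for reduced models).
#' @param n_restarts Number of optimisation starts (>= 1; default 5).
#' @param seed Optional integer seed controlling the restart draws.
#' @param prior_mean,prior_sd Prior location/scale on the transformed scale.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @return An object of class `effort_fit`: `estimates` ([model_params()]),
#'   `theta` (transformed mode), `nlp` (objective at the mode),
#'   `hessian_logdet`, `laplace_evidence`, `evidence_reliable` (FALSE when
#'   the Hessian is not numerically positive definite), `n_trials_used`,
#'   `convergence`, and the `free` parameter set.
#' @examples
#' s <- generate_session(task_config(), seed = 1)
#' rec <- simulate_choices(s, model_params(), seed = 2)
#' fit <- fit_map(rec, seed = 3, n_restarts = 3)
#' fit$estimates
#' @export
fit_map <- function(records, free = .PARAM_NAMES, n_restarts = 5, seed = NULL,
                    prior_mean = 0, prior_sd = 1, reltol = 1e-10) {
  design <- choice_design(records)
  d <- length(free)
  stopifnot(d >= 1, n_restarts >= 1, design$n >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  starts <- rbind(rep(prior_mean, d),
                  if (n_restarts > 1) {
                    matrix(prior_mean + stats::rnorm((n_restarts - 1) * d),
                           ncol = d)
                  })
  fn <- function(th) {
    v <- tryCatch(.nlp(th, design, free, prior_mean, prior_sd),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  fits <- apply(starts, 1, function(st) {
    tryCatch(stats::optim(st, fn, method = "BFGS",
                          control = list(maxit = 500, reltol = reltol)),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("all optimisation restarts failed")
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  norms <- vapply(fits, function(f) sum(f$par^2), numeric(1))
  # best NLP first; ties broken by the smaller parameter norm
  best <- fits[[order(vals, norms)[1]]]

  H <- stats::optimHess(best$par, fn)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  reliable <- all(ev > 1e-10)
  logdet <- sum(log(pmax(ev, .Machine$double.eps)))
  evidence <- -best$value + d / 2 * log(2 * pi) - logdet / 2

  structure(list(
    estimates = theta_to_params(best$par, free),
    theta = stats::setNames(best$par, free),
    free = free,
    nlp = best$value,
    hessian_logdet = logdet,
    laplace_evidence = evidence,
    evidence_reliable = reliable,
    n_trials_used = design$n,
    convergence = best$convergence == 0,
    n_restarts = n_restarts
  ), class = "effort_fit")
}

#' @export
print.effort_fit <- function(x, ...) {
  cat(sprintf("MAP fit on %d trials (%s)\n", x$n_trials_used,
              if (x$convergence) "converged" else "NOT converged"))
  print(round(unclass(x$estimates), 4))
  cat(sprintf("  NLP %.3f | Laplace evidence %.3f%s\n", x$nlp,
              x$laplace_evidence,
              if (x$evidence_reliable) "" else " (Hessian near-singular)"))
  invisible(x)
}

#' Default sampler of true parameters for recovery simulations
#'
#' Draws cohort-like parameter vectors: log-normal sensitivities centred on
#' the package's default [model_params()] (SD 0.4 on the log scale for the
#' incentive/effort sensitivities, 0.5 for the slower fatigue/learning
#' dynamics) and a Gaussian bias. See the methods vignette for the
#' calibration of these defaults.
#'
#' @param n Number of parameter vectors to draw.
#' @return A data frame with one column per parameter and `n` rows.
#' @export
default_param_sampler <- function(n) {
  m <- unclass(model_params())
  data.frame(
    kR = stats::rlnorm(n, log(m[["kR"]]), 0.4),
    kP = stats::rlnorm(n, log(m[["kP"]]), 0.4),
    kEp = stats::rlnorm(n, log(m[["kEp"]]), 0.4),
    kEm = stats::rlnorm(n, log(m[["kEm"]]), 0.4),
    kFp = stats::rlnorm(n, log(m[["kFp"]]), 0.5),
    kLm = stats::rlnorm(n, log(m[["kLm"]]), 0.5),
    kBias = stats::rnorm(n, m[["kBias"]], 1)
  )
}

#' Parameter recovery and identifiability simulation
#'
#' Simulates `n_subjects` full sessions from parameters drawn by `sampler`,
#' refits each simulated subject with [fit_map()], and summarises recovery:
#' per-parameter true-vs-recovered correlation, bias and RMSE (all on the
#' transformed fitting scale: log for sensitivities, raw for the bias), and
#' the confusion matrix of correlations among recovered parameters.
#'
#' @param n_subjects Number of simulated subjects (>= 20 recommended for
#'   stable correlations).
#' @param sampler Function of `n` returning a data frame of true parameters;
#'   defaults to [default_param_sampler()].
#' @param config A [task_config()] describing each subject's session.
#' @param seed Integer seed governing the whole simulation.
#' @param n_restarts Restarts per fit.
#' @return An object of class `recovery_report`: `correlation`, `bias`,
#'   `rmse` (named per parameter; `NA` with a note if a parameter was sampled
#'   with zero variance), `confusion` (correlation matrix of recovered
#'   parameters), `true`, `recovered` (matrices on the transformed scale),
#'   `n_subjects`, `n_failed`, `seed`.
#' @export
parameter_recovery <- function(n_subjects = 50, sampler = default_param_sampler,
                               config = task_config(), seed = 1,
                               n_restarts = 5) {
  withr::local_seed(seed)
  true_pars <- sampler(n_subjects)
  stopifnot(all(.PARAM_NAMES %in% names(true_pars)))
  seeds <- matrix(sample.int(.Machine$integer.max, 3L * n_subjects),
                  ncol = 3L)
  theta_true <- theta_hat <- matrix(NA_real_, n_subjects, length(.PARAM_NAMES),
                                    dimnames = list(NULL, .PARAM_NAMES))
  failed <- 0L
  for (i in seq_len(n_subjects)) {
    pars <- do.call(model_params, as.list(true_pars[i, .PARAM_NAMES]))
    first <- if (i %% 2L == 1L) "physical" else "mental"
    session <- generate_session(config, first_domain = first,
                                seed = seeds[i, 1])
    rec <- simulate_choices(session, pars, seed = seeds[i, 2])
    fit <- tryCatch(fit_map(rec, seed = seeds[i, 3], n_restarts = n_restarts),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$convergence) {
      failed <- failed + 1L
      next
    }
    theta_true[i, ] <- params_to_theta(pars)
    theta_hat[i, ] <- fit$theta
  }
  ok <- stats::complete.cases(theta_hat)
  tt <- theta_true[ok, , drop = FALSE]
  th <- theta_hat[ok, , drop = FALSE]
  per_par <- function(f) {
    stats::setNames(vapply(.PARAM_NAMES, function(nm) {
      if (stats::sd(tt[, nm]) == 0) return(NA_real_)
      f(tt[, nm], th[, nm])
    }, numeric(1)), .PARAM_NAMES)
  }
  structure(list(
    correlation = per_par(function(a, b) stats::cor(a, b)),
    bias = per_par(function(a, b) mean(b - a)),
    rmse = per_par(function(a, b) sqrt(mean((b - a)^2))),
    confusion = stats::cor(th),
    true = tt,
    recovered = th,
    n_subjects = n_subjects,
    n_failed = failed,
    seed = seed
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d simulated subjects (%d failed fits)\n",
              x$n_subjects, x$n_failed))
  tab <- rbind(correlation = x$correlation, bias = x$bias, rmse = x$rmse)
  print(round(tab, 3))
  invisible(x)
}

#' Validating behavioural GLM
#'
#' The model-free check that each task variable shapes behaviour: a logistic
#' regression of high-effort choice, and a linear regression of log
#' deliberation time, on incentive level, effort level, valence and trial
#' index. Missed trials are excluded.
#'
#' @param records A choice-record data frame (optionally pre-filtered to one
#'   domain).
#' @return A data frame with columns `model` (`"choice"` / `"log_dt"`),
#'   `term`, `estimate`, `se`, `statistic`, `p`. An attribute `flagged`
#'   records non-convergence or separation warnings.
#' @export
behavioral_glm <- function(records) {
  r <- records[!records$missed, , drop = FALSE]
  r$y <- as.integer(r$chosen == "HE")
  r$valence <- factor(r$valence, levels = c("punishment", "reward"))
  flagged <- character(0)
  choice_fit <- withCallingHandlers(
    stats::glm(y ~ he_incentive + he_effort + valence + trial_index,
               family = stats::binomial(), data = r),
    warning = function(w) {
      flagged <<- c(flagged, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!choice_fit$converged || any(abs(stats::coef(choice_fit)) > 15)) {
    flagged <- c(flagged, "possible separation or non-convergence in choice GLM")
  }
  dt_fit <- stats::lm(log(DT) ~ he_incentive + he_effort + valence + trial_index,
                      data = r)
  tidy <- function(fit, model) {
    cf <- summary(fit)$coefficients
    data.frame(model = model, term = rownames(cf), estimate = cf[, 1],
               se = cf[, 2], statistic = cf[, 3], p = cf[, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- rbind(tidy(choice_fit, "choice"), tidy(dt_fit, "log_dt"))
  attr(out, "flagged") <- flagged
  out
}
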
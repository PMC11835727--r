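# Trial-level choice model: subjective value difference between the
# high-effort and low-effort options, with block-internal fatigue (physical)
# and learning/efficiency (mental) states, passed through a softmax.

.PARAM_NAMES <- c("kR", "kP", "kEp", "kEm", "kFp", "kLm", "kBias")
.SENSITIVITY_NAMES <- c("kR", "kP", "kEp", "kEm", "kFp", "kLm")

#' Behavioural model parameters
#'
#' The seven sensitivities of the choice model: reward (`kR`) and punishment
#' (`kP`) incentive sensitivities, physical (`kEp`) and mental (`kEm`) effort
#' sensitivities, physical-fatigue (`kFp`) and mental-learning (`kLm`)
#' dynamics, and a real-valued bias toward the high-effort option (`kBias`).
#' All sensitivities except `kBias` must be non-negative.
#'
#' Defaults are the cohort-level means used by the synthetic-data generator
#' (see the methods vignette for their calibration to the task's observed
#' choice rates).
#'
#' @param kR,kP Reward / punishment incentive sensitivity (>= 0).
#' @param kEp,kEm Physical / mental effort sensitivity (>= 0).
#' @param kFp Physical fatigue sensitivity (>= 0); inflates the physical
#'   effort cost as fatigue accumulates within a block.
#' @param kEm,kLm Mental learning sensitivity (>= 0); deflates the mental
#'   effort cost as task practice accumulates within a block.
#' @param kBias Additive bias toward choosing the high-effort option (any
#'   real value).
#' @return A named numeric vector of class `model_params`.
#' @examples
#' model_params(kEp = 2, kBias = -0.5)
#' @export
model_params <- function(kR = 1, kP = 1, kEp = 0.7, kEm = 0.6,
                         kFp = 0.02, kLm = 0.3, kBias = 0.3) {
  p <- c(kR = kR, kP = kP, kEp = kEp, kEm = kEm,
         kFp = kFp, kLm = kLm, kBias = kBias)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  if (!all(.PARAM_NAMES %in% names(p))) {
    stop("model parameters must be named ", paste(.PARAM_NAMES, collapse = ", "))
  }
  if (any(!is.finite(unlist(p[.PARAM_NAMES])))) {
    stop("all model parameters must be finite")
  }
  if (any(unlist(p[.SENSITIVITY_NAMES]) < 0)) {
    stop("sensitivities kR, kP, kEp, kEm, kFp, kLm must be non-negative")
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Choice-model parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Internal fatigue/learning state
#'
#' Cumulative physical fatigue `F` and mental learning `L`, both starting at
#' 0 and reset at every block boundary (maximal-performance measurements
#' bracket each block).
#'
#' @param F Cumulative physical fatigue (unitless, >= 0).
#' @param L Cumulative mental learning (unitless, >= 0).
#' @return A list with elements `F` and `L`.
#' @export
internal_state <- function(F = 0, L = 0) {
  stopifnot(F >= 0, L >= 0)
  list(F = F, L = L)
}

# Vectorised subjective-value difference used by simulation and fitting.
# is_reward / is_physical are logical vectors; F, L are state values at
# decision time.
.delta_sv <- function(params, is_reward, is_physical, d_incentive, d_effort,
                      F, L) {
  benefit <- ifelse(is_reward, params[["kR"]], params[["kP"]]) * d_incentive
  unit_cost <- ifelse(is_physical,
                      params[["kEp"]] + params[["kFp"]] * F,
                      pmax(params[["kEm"]] - params[["kLm"]] * L, 0))
  params[["kBias"]] + benefit - unit_cost * d_effort
}

#' Subjective-value difference between the two options
#'
#' Computes `SV(HE) - SV(LE)` for one trial:
#' `kBias + k_incentive * (incentive_HE - incentive_LE) - cost * (effort_HE -
#' effort_LE)`, where the incentive sensitivity is `kR` on reward trials and
#' `kP` on punishment trials (level codes count avoided loss), and the unit
#' effort cost is `kEp + kFp * F` on physical trials and
#' `max(kEm - kLm * L, 0)` on mental trials.
#'
#' @param trial A list or one-row data frame with fields `valence`
#'   (`"reward"`/`"punishment"`), `domain` (`"physical"`/`"mental"`),
#'   `he_incentive`, `he_effort`, and optionally `le_incentive`, `le_effort`
#'   (default 0).
#' @param params A [model_params()] object.
#' @param state An [internal_state()] holding fatigue/learning at decision
#'   time.
#' @return The scalar subjective-value difference.
#' @examples
#' tr <- list(valence = "reward", domain = "physical",
#'            he_incentive = 2, he_effort = 1)
#' delta_sv(tr, model_params(kR = 1, kP = 0, kEp = 0, kEm = 0,
#'                           kFp = 0, kLm = 0, kBias = 0))
#' @export
delta_sv <- function(trial, params, state = internal_state()) {
  validate_model_params(params)
  if (!trial$valence %in% c("reward", "punishment")) {
    stop("unknown valence: ", trial$valence)
  }
  if (!trial$domain %in% c("physical", "mental")) {
    stop("unknown domain: ", trial$domain)
  }
  le_inc <- if (is.null(trial$le_incentive)) 0 else trial$le_incentive
  le_eff <- if (is.null(trial$le_effort)) 0 else trial$le_effort
  .delta_sv(params,
            is_reward = trial$valence == "reward",
            is_physical = trial$domain == "physical",
            d_incentive = trial$he_incentive - le_inc,
            d_effort = trial$he_effort - le_eff,
            F = state$F, L = state$L)
}

#' Softmax probability of choosing the high-effort option
#'
#' Logistic transform of the subjective-value difference,
#' `1 / (1 + exp(-delta_sv))`, with temperature fixed to 1 (the sensitivities
#' absorb the scale).
#'
#' @param delta_sv Numeric vector of subjective-value differences.
#' @return Probabilities in (0, 1).
#' @examples
#' p_high_effort(0)    # 0.5
#' p_high_effort(2)    # 0.8808
#' @export
p_high_effort <- function(delta_sv) {
  # clamp to the open interval: extreme values saturate to the nearest
  # representable probability instead of exactly 0 or 1
  pmin(pmax(stats::plogis(delta_sv), .Machine$double.xmin),
       1 - .Machine$double.eps / 2)
}

#' Update the internal state after one trial
#'
#' Physical trials accrue fatigue from exerted effort:
#' `F <- F + Ech / he_effort_max` (choosing the low option, `Ech = 0`, leaves
#' `F` unchanged). Mental trials accrue learning per completed trial:
#' `L <- L + 1 / trials_per_block`. The other domain's state is untouched.
#'
#' @param state An [internal_state()].
#' @param domain Trial domain, `"physical"` or `"mental"`.
#' @param ech Effort level of the chosen option (0 if the low option was
#'   chosen).
#' @param he_effort_max Maximum high-effort level of the design (normalises
#'   fatigue).
#' @param trials_per_block Trials per block (normalises learning).
#' @return The updated state.
#' @export
update_state <- function(state, domain, ech, he_effort_max = 3L,
                         trials_per_block = 54L) {
  domain <- match.arg(domain, c("physical", "mental"))
  if (domain == "physical") {
    state$F <- state$F + ech / he_effort_max
  } else {
    state$L <- state$L + 1 / trials_per_block
  }
  state
}

#' Deliberation-time model
#'
#' Log-normal generative model of deliberation times:
#' `DT = exp(b0 - b1 * |delta_sv| + sigma * noise)`. Harder (closer-to-
#' indifference) choices take longer in expectation when `b1 > 0`.
#'
#' @param b0 Log median DT at indifference (seconds scale); default 0.4
#'   (median about 1.5 s).
#' @param b1 Decrease of log DT per unit |delta SV|; default 0.15.
#' @param sigma SD of the Gaussian noise on the log scale; default 0.25.
#' @return A list of class `dt_model`.
#' @export
dt_model <- function(b0 = 0.4, b1 = 0.15, sigma = 0.25) {
  stopifnot(is.finite(b0), is.finite(b1), sigma >= 0)
  structure(list(b0 = b0, b1 = b1, sigma = sigma), class = "dt_model")
}

#' Simulate deliberation times
#'
#' @param delta_sv Numeric vector of subjective-value differences.
#' @param dt_params A [dt_model()].
#' @return Positive deliberation times in seconds, one per input value.
#' @export
simulate_dt <- function(delta_sv, dt_params = dt_model()) {
  stopifnot(all(is.finite(delta_sv)))
  exp(dt_params$b0 - dt_params$b1 * abs(delta_sv) +
        dt_params$sigma * stats::rnorm(length(delta_sv)))
}

#' Simulate choices over a session
#'
#' Runs the choice model forward over a session: for each trial the
#' subjective-value difference is computed with the running fatigue/learning
#' state, the choice is drawn from the softmax probability, the chosen effort
#' and chosen-option value are recorded, a deliberation time is drawn from
#' the DT model, and the state is updated. States reset at every block
#' boundary.
#'
#' The per-trial choice uniforms are drawn up-front, so two simulations with
#' the same seed are coupled trial-by-trial: raising an effort sensitivity
#' can only flip individual choices from high- to low-effort, never the
#' reverse.
#'
#' @param session A session data frame from [generate_session()].
#' @param params A [model_params()] object.
#' @param seed Optional integer seed.
#' @param dt_params A [dt_model()] for deliberation times.
#' @return A data frame of choice records: the session columns plus
#'   `fatigue`, `learning` (state at decision time), `delta_sv`, `p_he`,
#'   `chosen` (`"HE"`/`"LE"`), `Ech`, `SVch`, `DT`, and `missed` (always
#'   `FALSE` for simulated data; observed data may flag trials with no
#'   response, which default to the low option and are excluded from
#'   analysis).
#' @examples
#' s <- generate_session(task_config(), seed = 1)
#' rec <- simulate_choices(s, model_params(), seed = 2)
#' mean(rec$chosen == "HE")
#' @export
simulate_choices <- function(session, params, seed = NULL,
                             dt_params = dt_model()) {
  validate_model_params(params)
  n <- nrow(session)
  stopifnot(n > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  u <- stats::runif(n)
  dt_noise <- stats::rnorm(n)

  he_effort_max <- max(session$he_effort)
  is_reward <- session$valence == "reward"
  is_physical <- session$domain == "physical"
  d_inc <- session$he_incentive - session$le_incentive
  d_eff <- session$he_effort - session$le_effort

  fatigue <- learning <- dsv <- numeric(n)
  chosen_he <- logical(n)
  blocks <- unique(session$block_index)
  for (b in blocks) {
    idx <- which(session$block_index == b)
    tpb <- length(idx)
    F <- 0
    L <- 0
    for (j in idx) {
      fatigue[j] <- F
      learning[j] <- L
      dsv[j] <- .delta_sv(params, is_reward[j], is_physical[j],
                          d_inc[j], d_eff[j], F, L)
      chosen_he[j] <- u[j] < stats::plogis(dsv[j])
      ech <- if (chosen_he[j]) session$he_effort[j] else 0
      if (is_physical[j]) {
        F <- F + ech / he_effort_max
      } else {
        L <- L + 1 / tpb
      }
    }
  }

  records <- session
  records$fatigue <- fatigue
  records$learning <- learning
  records$delta_sv <- dsv
  records$p_he <- stats::plogis(dsv)
  records$chosen <- ifelse(chosen_he, "HE", "LE")
  records$Ech <- ifelse(chosen_he, session$he_effort, 0)
  # SV(LE) = 0 benchmark: the low option has incentive and effort level 0,
  # so the chosen-option value is delta_sv for HE choices and 0 otherwise.
  records$SVch <- ifelse(chosen_he, dsv, 0)
  records$DT <- exp(dt_params$b0 - dt_params$b1 * abs(dsv) +
                      dt_params$sigma * dt_noise)
  records$missed <- FALSE
  attr(records, "task_config") <- attr(session, "task_config")
  records
}

#' Recompute fatigue/learning trajectories from observed choices
#'
#' Given a table of choice records (with `Ech` observed), reconstructs the
#' deterministic fatigue and learning state at each decision, matching the
#' trajectories produced during simulation. Used before fitting when the
#' state columns are absent.
#'
#' @param records A choice-record data frame with columns `block_index`,
#'   `domain`, `he_effort`, `Ech`.
#' @return `records` with `fatigue` and `learning` columns (re)computed.
#' @export
accumulate_states <- function(records) {
  he_effort_max <- max(records$he_effort)
  fatigue <- learning <- numeric(nrow(records))
  for (b in unique(records$block_index)) {
    idx <- which(records$block_index == b)
    tpb <- length(idx)
    F <- 0
    L <- 0
    for (j in idx) {
      fatigue[j] <- F
      learning[j] <- L
      if (records$domain[j] == "physical") {
        F <- F + records$Ech[j] / he_effort_max
      } else {
        L <- L + 1 / tpb
      }
    }
  }
  records$fatigue <- fatigue
  records$learning <- learning
  records
}

#' Per-block z-scored parametric modulators
#'
#' Z-scores the trial-level modulators `Ech`, `SVch` and `DT` within each
#' block (or globally), as done before entering them, non-orthogonalised,
#' as parametric modulators of the choice regressor in the neural analysis.
#' Missed trials are excluded. A modulator that is constant within a block
#' maps to all zeros with a warning.
#'
#' @param records A choice-record data frame.
#' @param by_block Z-score within each block (default) or over all trials.
#' @return A data frame with `block_index`, `trial_index` and z-scored
#'   `Ech`, `SVch`, `DT`.
#' @export
parametric_modulators <- function(records, by_block = TRUE) {
  r <- records[!records$missed, , drop = FALSE]
  if (nrow(r) == 0) stop("no usable trials")
  groups <- if (by_block) r$block_index else rep(1L, nrow(r))
  if (any(table(groups) < 2)) stop("each block needs at least 2 trials")
  zscore <- function(x, var) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("modulator '%s' constant within a block; set to 0", var))
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  out <- data.frame(block_index = r$block_index, trial_index = r$trial_index)
  for (v in c("Ech", "SVch", "DT")) {
    out[[v]] <- stats::ave(r[[v]], groups,
                           FUN = function(x) zscore(x, v))
  }
  out
}
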
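# Factorial design of the effort-based decision task: alternating physical and
# mental blocks, each crossing incentive valence x high-effort incentive level
# x high-effort effort level, against a fixed low-incentive/low-effort option.

#' Task design configuration
#'
#' Describes the factorial structure of the effort-based decision task: a
#' session of alternating physical- and mental-effort blocks, each block
#' crossing two incentive valences (reward, punishment) with the high-effort
#' option's incentive and effort levels, repeated a fixed number of times.
#' Every trial opposes this varying high-incentive/high-effort option to a
#' fixed low option (incentive level 0, effort level 0).
#'
#' The default configuration gives 2 valences x 3 incentive levels x
#' 3 effort levels x 3 repetitions = 54 trials per block and 4 blocks,
#' i.e. 216 trials per session. Counting the low option's level 0 once per
#' valence, the incentive design has 8 distinct levels (4 rewards and
#' 4 punishments) and the effort design 4 levels per domain.
#'
#' @param n_blocks Number of blocks per session (must be even so that the two
#'   effort domains can strictly alternate). Default 4.
#' @param trials_per_block Trials in each block; must equal the factorial
#'   product `2 * he_incentive_levels * he_effort_levels * n_repetitions` and
#'   be even (for left/right counterbalancing). Default 54.
#' @param he_incentive_levels Number of high-effort incentive levels per
#'   valence (level codes 1..n). Default 3.
#' @param he_effort_levels Number of high-effort effort levels (codes 1..n).
#'   Default 3.
#' @param n_repetitions Repetitions of each design cell per block. Default 3.
#' @param low_money Money magnitude of the fixed low option in currency units
#'   (metadata only; choices are modelled on level codes). Default 0.5.
#' @param physical_duration_range Range, in seconds, of the handgrip squeeze
#'   durations spanned by the physical effort levels (metadata).
#' @param physical_force_threshold Force threshold as a fraction of maximal
#'   voluntary contraction (metadata). Default 0.55.
#' @param mental_window Time window of the mental (2-back) effort in seconds
#'   (metadata). Default 10.
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' count_incentive_levels(cfg)
#' @export
task_config <- function(n_blocks = 4L,
                        trials_per_block = 54L,
                        he_incentive_levels = 3L,
                        he_effort_levels = 3L,
                        n_repetitions = 3L,
                        low_money = 0.5,
                        physical_duration_range = c(0.5, 4.5),
                        physical_force_threshold = 0.55,
                        mental_window = 10) {
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  he_incentive_levels <- as.integer(he_incentive_levels)
  he_effort_levels <- as.integer(he_effort_levels)
  n_repetitions <- as.integer(n_repetitions)

  if (n_blocks < 2L || n_blocks %% 2L != 0L) {
    stop("`n_blocks` must be a positive even number so domains can alternate.")
  }
  cells <- 2L * he_incentive_levels * he_effort_levels * n_repetitions
  if (cells != trials_per_block) {
    stop(sprintf(paste0(
      "Factorial product 2 x %d x %d x %d = %d does not equal ",
      "`trials_per_block` = %d."),
      he_incentive_levels, he_effort_levels, n_repetitions, cells,
      trials_per_block))
  }
  if (trials_per_block %% 2L != 0L) {
    stop("`trials_per_block` must be even for left/right counterbalancing.")
  }

  structure(
    list(
      n_blocks = n_blocks,
      trials_per_block = trials_per_block,
      he_incentive_levels = he_incentive_levels,
      he_effort_levels = he_effort_levels,
      n_repetitions = n_repetitions,
      low_option = list(incentive_level = 0L, effort_level = 0L,
                        money_magnitude = low_money),
      physical_duration_range = physical_duration_range,
      physical_force_threshold = physical_force_threshold,
      mental_window = mental_window
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Effort-based decision task design\n")
  cat(sprintf("  %d blocks x %d trials = %d trials per session\n",
              x$n_blocks, x$trials_per_block, x$n_blocks * x$trials_per_block))
  cat(sprintf("  HE grid: 2 valences x %d incentive x %d effort levels, %d repetitions\n",
              x$he_incentive_levels, x$he_effort_levels, x$n_repetitions))
  cat(sprintf("  incentive levels incl. low option: %d\n",
              count_incentive_levels(x)))
  invisible(x)
}

#' Number of distinct incentive levels in the design
#'
#' Counts distinct (valence, incentive-level) combinations including the low
#' option's level 0 once per valence: `2 * (he_incentive_levels + 1)`. The
#' default design has 8 levels (4 rewards, 4 punishments).
#'
#' @param config A [task_config()].
#' @return Integer count of incentive levels.
#' @export
count_incentive_levels <- function(config) {
  stopifnot(inherits(config, "task_config"))
  2L * (config$he_incentive_levels + 1L)
}

#' Generate one task block
#'
#' Builds the exact factorial set of trials for one block (each
#' valence x incentive x effort cell appearing exactly `n_repetitions` times),
#' randomises their order with a seeded generator, and assigns the high-effort
#' option's screen side so that each side appears exactly
#' `trials_per_block / 2` times.
#'
#' @param domain `"physical"` or `"mental"`.
#' @param config A [task_config()].
#' @param seed Optional integer seed; identical seeds yield identical blocks.
#' @param block_index Block position within the session (stored per trial).
#' @return A data frame of trials with columns `block_index`, `trial_index`,
#'   `domain`, `valence`, `he_incentive`, `he_effort`, `le_incentive`,
#'   `le_effort`, `side_of_he`.
#' @examples
#' b <- generate_block("physical", task_config(), seed = 1)
#' table(b$valence, b$he_incentive, b$he_effort)
#' @export
generate_block <- function(domain, config = task_config(), seed = NULL,
                           block_index = 1L) {
  domain <- match.arg(domain, c("physical", "mental"))
  stopifnot(inherits(config, "task_config"))
  grid <- expand.grid(
    valence = c("reward", "punishment"),
    he_incentive = seq_len(config$he_incentive_levels),
    he_effort = seq_len(config$he_effort_levels),
    rep = seq_len(config$n_repetitions),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  if (n != config$trials_per_block) {
    stop("Factorial cells do not match `trials_per_block`; invalid config.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  ord <- sample.int(n)
  side <- sample(rep(c("left", "right"), each = n / 2L))
  trials <- data.frame(
    block_index = as.integer(block_index),
    trial_index = seq_len(n),
    domain = domain,
    valence = grid$valence[ord],
    he_incentive = as.integer(grid$he_incentive[ord]),
    he_effort = as.integer(grid$he_effort[ord]),
    le_incentive = 0L,
    le_effort = 0L,
    side_of_he = side,
    stringsAsFactors = FALSE
  )
  attr(trials, "task_config") <- config
  attr(trials, "seed") <- seed
  trials
}

#' Generate a full session of alternating blocks
#'
#' Produces `n_blocks` blocks whose effort domains strictly alternate starting
#' from `first_domain`. Per-block randomisation seeds are drawn
#' deterministically from `seed`, so the whole session is reproducible from a
#' single integer.
#'
#' @param config A [task_config()].
#' @param first_domain Domain of the first block, `"physical"` or `"mental"`.
#' @param seed Optional integer master seed for the session.
#' @return A data frame of trials (one row per trial across all blocks), with
#'   the `task_config` attached as an attribute.
#' @examples
#' s <- generate_session(task_config(), seed = 1)
#' nrow(s)  # 216
#' @export
generate_session <- function(config = task_config(),
                             first_domain = c("physical", "mental"),
                             seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  first_domain <- match.arg(first_domain)
  other <- setdiff(c("physical", "mental"), first_domain)
  domains <- rep(c(first_domain, other), length.out = config$n_blocks)
  if (!is.null(seed)) withr::local_seed(seed)
  block_seeds <- sample.int(.Machine$integer.max, config$n_blocks)
  blocks <- Map(function(d, i, s) {
    generate_block(d, config, seed = s, block_index = i)
  }, domains, seq_len(config$n_blocks), block_seeds)
  session <- do.call(rbind, blocks)
  rownames(session) <- NULL
  attr(session, "task_config") <- config
  attr(session, "seed") <- seed
  session
}
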
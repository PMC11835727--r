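# Shared fixtures: small sessions, record tables and parameter sets built in
# code at test time.

quick_session <- function(seed = 1, config = task_config(),
                          first_domain = "physical") {
  generate_session(config, first_domain = first_domain, seed = seed)
}

# params with a single active sensitivity, everything else switched off
only_param <- function(name, value, kBias = 0) {
  args <- list(kR = 0, kP = 0, kEp = 0, kEm = 0, kFp = 0, kLm = 0,
               kBias = kBias)
  args[[name]] <- value
  do.call(model_params, args)
}

# hand-built single-block session with arbitrary trial features
manual_session <- function(valence, domain, he_incentive, he_effort,
                           block_index = 1L) {
  n <- max(length(valence), length(domain), length(he_incentive),
           length(he_effort))
  data.frame(
    block_index = rep_len(block_index, n),
    trial_index = seq_len(n),
    domain = rep_len(domain, n),
    valence = rep_len(valence, n),
    he_incentive = rep_len(he_incentive, n),
    he_effort = rep_len(he_effort, n),
    le_incentive = 0L, le_effort = 0L,
    side_of_he = rep_len(c("left", "right"), n),
    stringsAsFactors = FALSE
  )
}

# trivariate normal sample with given correlations (for Steiger calibration)
rmvnorm3 <- function(n, r12, r13, r23) {
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  L <- chol(R)
  matrix(rnorm(3 * n), n, 3) %*% L
}
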
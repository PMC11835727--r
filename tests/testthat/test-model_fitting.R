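test_that("the negative log posterior matches an independent summation", {
  # empty choice set: prior term only
  empty <- simulate_choices(quick_session(seed = 1), model_params(),
                            seed = 2)[0, ]
  th <- rep(0, 7)
  expect_equal(neg_log_posterior(th, empty),
               -sum(dnorm(th, 0, 1, log = TRUE)))

  # single trial at indifference: data term log 2 on top of the prior
  one <- manual_session("reward", "physical", 1, 1)
  one$chosen <- "HE"; one$Ech <- 1; one$missed <- FALSE
  # theta = 0 means all k = 1, kBias = 0: delta_sv = 1 - 1 = 0, p = 0.5
  expect_equal(neg_log_posterior(rep(0, 7), one),
               log(2) - sum(dnorm(rep(0, 7), log = TRUE)))

  # 10-trial fixture vs a hand-expanded sum written from the formulas
  rec <- simulate_choices(quick_session(seed = 3), model_params(),
                          seed = 4)[1:10, ]
  theta <- c(0.2, -0.1, 0.3, -0.4, -2, -1, 0.5)
  k <- exp(theta[1:6]); names(k) <- c("kR", "kP", "kEp", "kEm", "kFp", "kLm")
  ll <- 0
  for (i in 1:10) {
    ben <- if (rec$valence[i] == "reward") k[["kR"]] * rec$he_incentive[i] else
      k[["kP"]] * rec$he_incentive[i]
    cost <- if (rec$domain[i] == "physical") {
      (k[["kEp"]] + k[["kFp"]] * rec$fatigue[i]) * rec$he_effort[i]
    } else {
      max(k[["kEm"]] - k[["kLm"]] * rec$learning[i], 0) * rec$he_effort[i]
    }
    dsv <- theta[7] + ben - cost
    p <- 1 / (1 + exp(-dsv))
    ll <- ll + log(if (rec$chosen[i] == "HE") p else 1 - p)
  }
  expect_equal(neg_log_posterior(theta, rec),
               -ll - sum(dnorm(theta, log = TRUE)), tolerance = 1e-10)

  expect_error(neg_log_posterior(c(rep(0, 6), NaN), rec), "finite")
})

test_that("a pure-bias subject is refitted to reproduce nearly all choices", {
  session <- quick_session(seed = 5)
  truth <- only_param("kR", 0, kBias = 5)
  rec <- simulate_choices(session, truth, seed = 6)
  fit <- fit_map(rec, seed = 7, n_restarts = 3)
  pred <- simulate_choices(session, fit$estimates, seed = 999)
  agree <- mean((pred$p_he > 0.5) == (rec$chosen == "HE"))
  expect_gte(agree, 0.95)
  expect_true(fit$convergence)
  expect_true(is.finite(fit$laplace_evidence))
})

test_that("duplicating every trial leaves the mode near-fixed but shifts evidence", {
  rec <- simulate_choices(quick_session(seed = 8), model_params(), seed = 9)
  fit1 <- fit_map(rec, seed = 10, n_restarts = 3)
  rec2 <- rbind(rec, rec)
  fit2 <- fit_map(rec2, seed = 10, n_restarts = 3)
  # likelihood doubles, prior does not: mode moves only by the prior's pull
  expect_lt(max(abs(fit1$theta - fit2$theta)), 0.15)
  expect_gt(abs(fit2$laplace_evidence - fit1$laplace_evidence), 1)
  expect_equal(fit2$n_trials_used, 2L * fit1$n_trials_used)
})

test_that("reduced-model MAP agrees with a coarse grid search", {
  session <- quick_session(seed = 11)
  truth <- model_params(kR = 1, kP = 0, kEp = 0.7, kEm = 0, kFp = 0,
                        kLm = 0, kBias = 0)
  rec <- simulate_choices(session, truth, seed = 12)
  free <- c("kR", "kEp")
  fit <- fit_map(rec, free = free, seed = 13, n_restarts = 3)

  # independent vectorised grid evaluation of the same objective
  y <- rec$chosen == "HE"
  s <- ifelse(y, 1, -1)
  x_r <- ifelse(rec$valence == "reward", rec$he_incentive, 0)
  x_e <- ifelse(rec$domain == "physical", rec$he_effort, 0)
  th <- seq(-1, 1, by = 0.02)
  grid <- as.matrix(expand.grid(t1 = th, t2 = th))
  nlp <- apply(grid, 1, function(g) {
    dsv <- exp(g[1]) * x_r - exp(g[2]) * x_e
    -sum(plogis(s * dsv, log.p = TRUE)) - sum(dnorm(g, log = TRUE))
  })
  best <- grid[which.min(nlp), ]
  expect_lt(max(abs(exp(fit$theta) - exp(best))), 0.025)
})

test_that("missed trials are excluded from the fit", {
  rec <- simulate_choices(quick_session(seed = 14), model_params(),
                          seed = 15)
  rec2 <- rec
  rec2$missed[1:20] <- TRUE
  fit <- fit_map(rec2, seed = 16, n_restarts = 2)
  expect_equal(fit$n_trials_used, nrow(rec) - 20L)
  expect_equal(neg_log_posterior(rep(0, 7), rec2),
               neg_log_posterior(rep(0, 7), rec[-(1:20), ]))
})

test_that("an irrelevant extra parameter can only cost evidence (Occam)", {
  session <- quick_session(seed = 17)
  truth <- model_params(kR = 1, kP = 1, kEp = 0.7, kEm = 0.6, kFp = 0,
                        kLm = 0, kBias = 0.3)
  rec <- simulate_choices(session, truth, seed = 18)
  reduced <- c("kR", "kP", "kEp", "kEm", "kBias")
  fit_red <- fit_map(rec, free = reduced, seed = 19, n_restarts = 3)
  fit_full <- fit_map(rec, seed = 19, n_restarts = 3)
  expect_gt(fit_red$laplace_evidence, fit_full$laplace_evidence)
})

test_that("parameter recovery tracks the generating values", {
  rep_small <- parameter_recovery(n_subjects = 12, seed = 20,
                                  n_restarts = 3)
  expect_equal(rep_small$n_failed, 0L)
  expect_true(all(rep_small$correlation[c("kR", "kEp", "kEm")] > 0.5))
  expect_true(all(abs(rep_small$correlation) <= 1, na.rm = TRUE))
  expect_true(isSymmetric(rep_small$confusion, tol = 1e-12))
  expect_equal(unname(diag(rep_small$confusion)), rep(1, 7))

  # degenerate sampler: zero-variance parameter flagged as NA
  degen <- function(n) {
    d <- default_param_sampler(n)
    d$kR <- 1
    d
  }
  rep_deg <- parameter_recovery(n_subjects = 8, sampler = degen, seed = 21,
                                n_restarts = 2)
  expect_true(is.na(rep_deg$correlation[["kR"]]))
})

test_that("the behavioural GLM recovers the task effects", {
  session <- quick_session(seed = 22)
  p <- model_params(kR = 1, kP = 1, kEp = 1.2, kEm = 0.6, kFp = 0,
                    kLm = 0, kBias = 0)
  rec <- simulate_choices(session, p, seed = 23)
  phys <- rec[rec$domain == "physical", ]
  tab <- behavioral_glm(phys)
  eff <- tab[tab$model == "choice" & tab$term == "he_effort", ]
  inc <- tab[tab$model == "choice" & tab$term == "he_incentive", ]
  expect_lt(eff$estimate, 0)
  expect_lt(eff$p, 0.05)
  expect_gt(inc$estimate, 0)
  expect_lt(inc$p, 0.05)

  # DT decreasing in |delta SV| shows up in the log-DT regression: larger
  # effort pushes delta SV down, away from indifference on these data, so
  # the effort coefficient on log DT is negative
  dt_eff <- tab[tab$model == "log_dt" & tab$term == "he_effort", ]
  expect_lt(dt_eff$estimate, 0)
})

test_that("the behavioural GLM keeps its nominal false-positive rate", {
  withr::local_seed(24)
  session <- quick_session(seed = 25)
  null_p <- only_param("kR", 0)
  hits <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    rec <- simulate_choices(session, null_p,
                            seed = sample.int(.Machine$integer.max, 1))
    tab <- behavioral_glm(rec)
    pv <- tab[tab$model == "choice" & tab$term == "he_effort", "p"]
    hits <- hits + (pv < 0.05)
  }
  # 5% nominal; allow three binomial SDs
  expect_lte(hits / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
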
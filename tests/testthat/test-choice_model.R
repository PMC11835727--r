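test_that("delta_sv evaluates the value equation", {
  zero <- only_param("kR", 0)
  tr <- list(valence = "reward", domain = "physical",
             he_incentive = 2, he_effort = 3)
  expect_equal(delta_sv(tr, zero), 0)

  # reward benefit only: kR * (R_HE - R_LE) = 1 * 2
  expect_equal(delta_sv(tr, only_param("kR", 1),
                        internal_state()), 2 - 0 * 3)
  tr1 <- list(valence = "reward", domain = "physical",
              he_incentive = 2, he_effort = 0)
  expect_equal(delta_sv(tr1, only_param("kR", 1)), 2)

  # fatigue-inflated physical cost: (kEp + kFp * F) * dE = (1 + 0.5*2) * 2
  trp <- list(valence = "reward", domain = "physical",
              he_incentive = 0, he_effort = 2)
  p <- model_params(kR = 0, kP = 0, kEp = 1, kEm = 0, kFp = 0.5, kLm = 0,
                    kBias = 0)
  expect_equal(delta_sv(trp, p, internal_state(F = 2)), -(1 + 1) * 2)

  # mental cost clamps at zero for large learning
  trm <- list(valence = "punishment", domain = "mental",
              he_incentive = 1, he_effort = 3)
  pm <- model_params(kR = 0, kP = 2, kEp = 0, kEm = 0.5, kFp = 0, kLm = 1,
                     kBias = 0)
  expect_equal(delta_sv(trm, pm, internal_state(L = 2)), 2 * 1 - 0)

  expect_error(delta_sv(list(valence = "neutral", domain = "physical",
                             he_incentive = 1, he_effort = 1), zero),
               "valence")
  expect_error(delta_sv(list(valence = "reward", domain = "social",
                             he_incentive = 1, he_effort = 1), zero),
               "domain")
})

test_that("softmax is symmetric, bounded and strictly increasing", {
  expect_equal(p_high_effort(0), 0.5)
  expect_equal(p_high_effort(2), 0.8808, tolerance = 1e-4)
  x <- seq(-30, 30, length.out = 101)
  expect_equal(p_high_effort(x) + p_high_effort(-x), rep(1, 101))
  p <- p_high_effort(c(-750, 750, x))
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p_high_effort(x)) > 0))
})

test_that("state updates follow the fatigue/learning rules", {
  s <- internal_state()
  expect_equal(update_state(s, "physical", ech = 0)$F, 0)
  expect_equal(update_state(s, "physical", ech = 3, he_effort_max = 3)$F, 1)
  expect_equal(update_state(s, "physical", ech = 2)$L, 0)
  for (i in 1:54) s <- update_state(s, "mental", ech = 2,
                                    trials_per_block = 54)
  expect_equal(s$L, 1)
  expect_equal(s$F, 0)
})

test_that("simulated choices follow the model probabilities", {
  session <- quick_session(seed = 1)
  sat <- simulate_choices(session, only_param("kR", 0, kBias = 10), seed = 2)
  expect_gte(mean(sat$chosen == "HE"), 0.99)

  # all parameters zero: HE proportion within the binomial 99% CI of 0.5
  ind <- simulate_choices(session, only_param("kR", 0), seed = 3)
  half_width <- qnorm(0.995) * sqrt(0.25 / 216)
  expect_lt(abs(mean(ind$chosen == "HE") - 0.5), half_width)

  expect_identical(simulate_choices(session, model_params(), seed = 9),
                   simulate_choices(session, model_params(), seed = 9))
})

test_that("raising kEp cannot increase physical high-effort counts (coupled seeds)", {
  session <- quick_session(seed = 4)
  counts <- sapply(c(0.2, 0.5, 0.9, 1.5, 2.5), function(kep) {
    p <- model_params(kR = 1, kP = 1, kEp = kep, kEm = 0.5, kFp = 0,
                      kLm = 0.2, kBias = 0)
    rec <- simulate_choices(session, p, seed = 11)
    sum(rec$chosen == "HE" & rec$domain == "physical")
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("without fatigue, physical choice probabilities ignore trial order", {
  p <- model_params(kR = 1, kP = 1, kEp = 0.8, kEm = 0.5, kFp = 0,
                    kLm = 0, kBias = 0.2)
  session <- quick_session(seed = 5)
  rev_idx <- unlist(lapply(split(seq_len(nrow(session)),
                                 session$block_index), rev))
  reversed <- session[rev_idx, ]
  reversed$trial_index <- session$trial_index
  r1 <- simulate_choices(session, p, seed = 6)
  r2 <- simulate_choices(reversed, p, seed = 6)
  # with kFp = 0 a physical trial's probability depends on its features only,
  # so each trial keeps its p_he wherever it lands in the order
  phys <- reversed$domain == "physical"
  expect_equal(r2$p_he[phys], r1$p_he[rev_idx][phys], tolerance = 1e-12)
})

test_that("empirical choice frequency converges to the softmax probability", {
  # 4000 identical physical trials; no fatigue so p is constant
  session <- manual_session("reward", "physical", 2, 1)
  session <- session[rep(1, 4000), ]
  session$trial_index <- seq_len(4000)
  p <- model_params(kR = 0.6, kP = 0, kEp = 0.4, kEm = 0, kFp = 0, kLm = 0,
                    kBias = 0)
  rec <- simulate_choices(session, p, seed = 8)
  expect_equal(mean(rec$chosen == "HE"), rec$p_he[1],
               tolerance = 3 * sqrt(0.25 / 4000) / rec$p_he[1])
})

test_that("stored fatigue/learning trajectories match their recomputation", {
  rec <- simulate_choices(quick_session(seed = 10), model_params(),
                          seed = 12)
  redone <- accumulate_states(rec[, setdiff(names(rec),
                                            c("fatigue", "learning"))])
  expect_equal(redone$fatigue, rec$fatigue)
  expect_equal(redone$learning, rec$learning)
  expect_true(all(diff(rec$fatigue[rec$block_index == 1]) >= 0))
})

test_that("parametric modulators are z-scored per block", {
  rec <- simulate_choices(quick_session(seed = 13), model_params(),
                          seed = 14)
  mods <- parametric_modulators(rec)
  for (b in unique(mods$block_index)) {
    for (v in c("Ech", "SVch", "DT")) {
      x <- mods[[v]][mods$block_index == b]
      expect_lt(abs(mean(x)), 1e-12)
      expect_lt(abs(sd(x) - 1), 1e-12)
    }
  }

  # constant modulator within a block maps to zeros with a warning
  const <- rec[rec$block_index == 1, ]
  const$Ech <- 1
  expect_warning(m2 <- parametric_modulators(const), "constant")
  expect_true(all(m2$Ech == 0))
  expect_error(parametric_modulators(rec[0, ]), "no usable")
})

test_that("per-block z-scores differ from global ones when block means differ", {
  rec <- manual_session("reward", "physical", c(1, 2, 1, 3),
                        c(1, 1, 2, 2), block_index = c(1, 1, 2, 2))
  rec$Ech <- c(1, 2, 5, 9)
  rec$SVch <- c(0.1, 0.4, 2, 3)
  rec$DT <- c(1, 2, 3, 5)
  rec$missed <- FALSE
  per_block <- parametric_modulators(rec, by_block = TRUE)
  global <- parametric_modulators(rec, by_block = FALSE)
  # direct computation on the 4-trial fixture
  expect_equal(per_block$Ech[1:2], as.numeric(scale(c(1, 2))))
  expect_equal(global$Ech, as.numeric(scale(c(1, 2, 5, 9))))
  expect_false(isTRUE(all.equal(per_block$Ech, global$Ech)))
})

test_that("deliberation times follow the lognormal DT model", {
  withr::local_seed(1)
  flat <- dt_model(b0 = 0.4, b1 = 0, sigma = 0.3)
  d1 <- simulate_dt(rep(0, 4000), flat)
  d2 <- simulate_dt(rep(5, 4000), flat)
  expect_equal(median(d1), median(d2), tolerance = 0.05)

  slope <- dt_model(b0 = 0.4, b1 = 0.3, sigma = 0.3)
  d3 <- simulate_dt(rep(5, 4000), slope)
  expect_lt(median(d3), median(simulate_dt(rep(0, 4000), slope)))
  # closed-form lognormal medians
  expect_equal(median(d3), exp(0.4 - 0.3 * 5), tolerance = 0.05)

  exact <- simulate_dt(c(0, 2), dt_model(b0 = 0.4, b1 = 0.1, sigma = 0))
  expect_equal(exact, exp(c(0.4, 0.2)))
})
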
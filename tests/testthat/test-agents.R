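test_that("the leaky income update follows its convex form", {
  expect_equal(update_income(0, 1, 5), 0.2)
  expect_equal(update_income(1, 1, 7), 1)          # fixed point
  expect_equal(update_income(0.5, 0, 2), 0.25)
  expect_error(update_income(0.5, 1, 0.5), "tau")
})

test_that("combined income is the weighted sum across timescales", {
  expect_equal(combined_income(c(0.3, 0.9), c(1, 0)), 0.3)
  expect_equal(combined_income(c(0.2, 0.4), c(0.5, 0.5)), 0.3)
  expect_equal(combined_income(c(0.1, 0.5), c(0.7, 0.3)), 0.22)
  expect_error(combined_income(c(0.1, 0.5), c(1)), "length")
})

test_that("the matching rule handles its degenerate cases", {
  expect_equal(choice_probability(0.3, 0.3), 0.5)
  expect_equal(choice_probability(0.3, 0), 1)
  expect_equal(choice_probability(0, 0), 0.5)
  expect_error(choice_probability(-0.1, 0.3), "non-negative")
})

test_that("the random-bias rule extends the matching rule", {
  expect_equal(bias_model_probability(0.3, 0.2, 0, 0),
               choice_probability(0.3, 0.2))
  expect_equal(bias_model_probability(0.2, 0.2, 0.1, 0), 0.6)
  expect_gt(bias_model_probability(0.2, 0.2, 0.05, 0.01), 0.5)
  expect_equal(bias_model_probability(0, 0, 0, 0), 0.5)
})

test_that("acting follows the agent's choice probability", {
  ag_g <- integrator_agent(5, 1)
  ag_g$income_g <- 0.3; ag_g$income_r <- 0
  expect_true(all(replicate(20, act(ag_g)) == "G"))
  ag_r <- integrator_agent(5, 1)
  ag_r$income_g <- 0; ag_r$income_r <- 0.3
  expect_true(all(replicate(20, act(ag_r)) == "R"))
  set.seed(20)
  ag <- integrator_agent(5, 1)
  ag$income_g <- 0.7; ag$income_r <- 0.3
  frac <- mean(replicate(10000, act(ag)) == "G")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
})

test_that("incomes stay in [0, 1] for arbitrary reward sequences", {
  set.seed(21)
  for (k in 1:25) {
    taus <- sort(1 + rexp(3, 1 / 50))
    ag <- integrator_agent(taus, rep(1 / 3, 3),
                           initial_income = runif(1))
    for (t in 1:150) {
      ag <- agent_update(ag, sample(c("G", "R"), 1), rbinom(1, 1, 0.5))
      expect_true(all(ag$income_g >= 0 & ag$income_g <= 1))
      expect_true(all(ag$income_r >= 0 & ag$income_r <= 1))
    }
  }
})

test_that("the filter is unbiased in steady state under iid rewards", {
  set.seed(22)
  p <- 0.3
  ag <- integrator_agent(20, 1, initial_income = p)
  means <- numeric(5000)
  for (t in 1:5000) {
    ag <- agent_update(ag, "G", rbinom(1, 1, p))
    means[t] <- ag$income_g
  }
  expect_lt(abs(mean(means[1001:5000]) - p), 0.03)
})

test_that("a one-timescale agent reproduces the single-integrator model", {
  set.seed(23)
  sched <- generate_schedule(default_sched_cfg(n_blocks = 3))
  ses <- run_session(integrator_agent(9, 1, initial_income = 0.175), sched)
  # independent oracle: direct single-filter forward pass and Bernoulli LL
  a <- 1 / 9
  ig <- 0.175; ir <- 0.175
  ll <- 0
  for (t in seq_len(nrow(ses))) {
    pg <- if (ig + ir > 0) ig / (ig + ir) else 0.5
    pg <- min(max(pg, 1e-6), 1 - 1e-6)
    if (ses$free_choice[t])
      ll <- ll + log(if (ses$choice[t] == "G") pg else 1 - pg)
    rg <- ses$reward[t] * (ses$choice[t] == "G")
    rr <- ses$reward[t] * (ses$choice[t] == "R")
    ig <- (1 - a) * ig + a * rg
    ir <- (1 - a) * ir + a * rr
  }
  expect_equal(session_log_likelihood(ses, weights = 1, taus = 9,
                                      initial_incomes = 0.175), ll)
})

test_that("the first-order undermatching prediction behaves linearly", {
  expect_equal(undermatching_approximation(0, 1, 0.35, 0.35), 0)
  d1 <- undermatching_approximation(0.1, 0.9, 0.35, 0.35)
  d2 <- undermatching_approximation(0.2, 0.9, 0.35, 0.35)
  expect_equal(d2, 2 * d1)
  expect_error(undermatching_approximation(0.1, 0.9, 0.35, 0), "positive")
})

test_that("simulated slope deficit matches the first-order prediction", {
  set.seed(24)
  w <- 0.1
  cfg <- default_sched_cfg(n_blocks = 60)
  ag <- integrator_agent(c(5, 10000), c(1 - w, w), initial_income = 0.175)
  ses <- run_session(ag, generate_schedule(cfg))
  fit <- fit_matching(block_summaries(ses, last_n = 50))
  # slow incomes sit near the initial 0.175 each; fast total near the
  # schedule's payoff rate
  ag_end <- attr(ses, "agent")
  pred <- undermatching_approximation(w, 1 - w,
                                      sum(ag_end$income_g[2], ag_end$income_r[2]),
                                      0.35)
  expect_lt(abs(fit$undermatching - pred), 0.12)
  expect_gt(fit$undermatching, 0)
})

test_that("session reset keeps only the slow integrator's incomes", {
  ag <- integrator_agent(c(2, 1000), c(0.5, 0.5), initial_income = 0.175)
  ag$income_g <- c(0.9, 0.4)
  ag$income_r <- c(0.1, 0.3)
  res <- agent_session_reset(ag, carryover = TRUE)
  expect_equal(res$income_g, c(0.175, 0.4))
  expect_equal(res$income_r, c(0.175, 0.3))
  res2 <- agent_session_reset(ag, carryover = FALSE)
  expect_equal(res2$income_g, c(0.175, 0.175))
})

test_that("bias agents redraw session biases when configured", {
  set.seed(25)
  ag <- bias_agent(tau = 5, bias_sd = 0.05, bias_mean = 0.05)
  b0 <- c(ag$bias_g, ag$bias_r)
  ag2 <- agent_session_reset(ag)
  expect_false(identical(b0, c(ag2$bias_g, ag2$bias_r)))
  expect_true(ag2$bias_g >= 0 && ag2$bias_r >= 0)
})

test_that("agents can be built from configuration blocks", {
  ag <- agent_from_config(list(model = "multi_timescale",
                               taus = c(5, 1000), weights = c(0.7, 0.3)))
  expect_s3_class(ag, "integrator_agent")
  expect_equal(ag$taus, c(5, 1000))
  bg <- agent_from_config(list(model = "random_bias", tau = 5,
                               bias_g = 0.1, bias_r = 0))
  expect_s3_class(bg, "bias_agent")
  cg <- agent_from_config(list(model = "cascade", n_levels = 3))
  expect_s3_class(cg, "cascade_agent")
  expect_error(agent_from_config(list(taus = 5)), "model")
  expect_error(agent_from_config(list(model = "softmax")), "unknown model")
})
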
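test_that("block fractions are computed over free choices and all rewards", {
  choice <- c(rep("G", 40), rep("R", 10))
  reward <- c(rep(1, 8), rep(0, 32), rep(1, 2), rep(0, 8))
  ses <- make_session(choice, reward)
  bs <- block_summaries(ses)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$choice_fraction, 0.8)
  expect_equal(bs$reward_fraction, 0.8)
  expect_equal(bs$n_free_choices, 50)
  expect_equal(bs$n_rewards, 10)
})

test_that("blocks without rewards are excluded and last_n restricts trials", {
  ses <- make_session(choice = rep(c("G", "R"), 25),
                      reward = rep(0, 50))
  expect_null(block_summaries(ses))

  # 150-trial block: first 100 trials rewarded green, last 50 rewarded red
  choice <- c(rep("G", 100), rep("R", 50))
  reward <- rep(1, 150)
  ses2 <- make_session(choice, reward)
  bs <- block_summaries(ses2, last_n = 50)
  expect_equal(bs$choice_fraction, 0)   # only trials 101-150 counted
  expect_equal(bs$reward_fraction, 0)
  expect_equal(bs$n_free_choices, 50)
})

test_that("the matching fit recovers exact and noisy lines", {
  mk <- function(x, y) data.frame(block = seq_along(x), choice_fraction = y,
                                  reward_fraction = x, n_free_choices = 50,
                                  n_rewards = 20)
  on_diag <- mk(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))
  fit <- fit_matching(on_diag)
  expect_equal(fit$slope, 1)
  expect_equal(fit$undermatching, 0)
  expect_equal(fit$color_choice_bias, 0)

  flat <- mk(c(0.2, 0.5, 0.8), c(0.5, 0.5, 0.5))
  fit2 <- fit_matching(flat)
  expect_equal(fit2$slope, 0)
  expect_equal(fit2$undermatching, 1)

  set.seed(30)
  x <- runif(80, 0.1, 0.9)
  y <- 0.8 * x + 0.1 + rnorm(80, 0, 0.03)
  fit3 <- fit_matching(mk(x, y))
  expect_lt(abs(fit3$slope - 0.8), 0.05)
})

test_that("matching-fit failure modes raise informative errors", {
  mk <- function(x, y, nr = 20) data.frame(block = seq_along(x),
                                           choice_fraction = y,
                                           reward_fraction = x,
                                           n_free_choices = 50, n_rewards = nr)
  expect_error(fit_matching(mk(c(0.2, 0.5), c(0.2, 0.5))), "3 blocks")
  expect_error(fit_matching(mk(c(0.5, 0.5, 0.5), c(0.2, 0.5, 0.6))),
               "zero variance")
  # low-reward blocks are dropped before fitting
  blocks <- rbind(mk(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8)),
                  mk(1.0, 0.1, nr = 2))
  fit <- fit_matching(blocks, min_rewards = 5)
  expect_equal(fit$n_blocks, 3)
  expect_equal(fit$slope, 1)
})

test_that("color relabeling flips the bias but preserves the slope", {
  set.seed(31)
  sched <- generate_schedule(default_sched_cfg(n_blocks = 8))
  ses <- run_session(integrator_agent(c(5, 1000), c(0.7, 0.3)), sched)
  fit <- fit_matching(block_summaries(ses))
  ses_flip <- ses
  ses_flip$choice <- ifelse(ses$choice == "G", "R", "G")
  fit_flip <- fit_matching(block_summaries(ses_flip))
  expect_equal(fit_flip$slope, fit$slope, tolerance = 1e-10)
  expect_equal(fit_flip$color_choice_bias, -fit$color_choice_bias,
               tolerance = 1e-10)
})

test_that("shifting all choice fractions moves the bias, not the slope", {
  set.seed(32)
  x <- runif(30, 0.2, 0.8)
  y <- 0.7 * x + 0.12 + rnorm(30, 0, 0.02)
  mk <- function(yy) data.frame(block = seq_along(x), choice_fraction = yy,
                                reward_fraction = x, n_free_choices = 50,
                                n_rewards = 20)
  f1 <- fit_matching(mk(y))
  f2 <- fit_matching(mk(y + 0.05))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-10)
  expect_equal(f2$color_choice_bias - f1$color_choice_bias, 0.05,
               tolerance = 1e-10)
})

test_that("harvesting efficiency uses the schedule's reward ceiling", {
  ses <- make_session(rep("G", 100), c(rep(1, 21), rep(0, 79)))
  expect_equal(harvesting_efficiency(ses), 21 / 35)
  # never collects
  ses0 <- make_session(rep("G", 100), rep(0, 100))
  expect_equal(harvesting_efficiency(ses0), 0)
  expect_equal(harvesting_efficiency(ses0, total_bait_rate = 0.5), 0)
})

test_that("variance of choice is zero for constant series and matches a
           brute-force convolution for alternation", {
  const <- make_session(rep("G", 300), rep(0, 300))
  expect_equal(variance_of_choice(const)$variance, 0)

  alt <- make_session(rep(c("G", "R"), 150), rep(0, 300))
  vc <- variance_of_choice(alt)
  # brute-force causal half-Gaussian smoothing oracle
  x <- rep(c(1, 0), 150)
  smooth_oracle <- function(x, sigma, span) {
    n <- length(x)
    out <- numeric(n)
    for (t in seq_len(n)) {
      k <- 0:min(span - 1, t - 1)
      w <- exp(-k^2 / (2 * sigma^2))
      out[t] <- sum(w * x[t - k]) / sum(w)
    }
    out
  }
  fast <- smooth_oracle(x, 8, 200)
  slow <- smooth_oracle(x, 50, 200)
  expect_equal(vc$variance, mean((fast - slow)^2), tolerance = 1e-12)
  expect_lt(vc$variance, 1e-3)   # both smoothers sit near 0.5

  short <- make_session(rep("G", 150), rep(0, 150))
  expect_error(variance_of_choice(short), "free choices")
})

test_that("slow-weighted agents produce less variable choice", {
  set.seed(33)
  sched <- generate_schedule(default_sched_cfg(n_blocks = 10))
  s_fast <- run_session(integrator_agent(c(5, 10000), c(0.9, 0.1)), sched)
  set.seed(33)
  sched2 <- generate_schedule(default_sched_cfg(n_blocks = 10))
  s_slow <- run_session(integrator_agent(c(5, 10000), c(0.1, 0.9)), sched2)
  expect_lt(variance_of_choice(s_slow)$variance,
            variance_of_choice(s_fast)$variance)
})

test_that("color reward imbalance counts rewards per color over trials", {
  ses <- make_session(c(rep("G", 100), rep("R", 100)),
                      c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)))
  expect_equal(color_reward_imbalance(ses), 0.1)
  sym <- make_session(c("G", "R"), c(1, 1))
  expect_equal(color_reward_imbalance(sym), 0)
  set.seed(34)
  sched <- toy_schedule(20000, 0.175, 0.175, cod = FALSE)
  long <- run_session(fixed_agent(0.5), sched)
  expect_lt(abs(color_reward_imbalance(long)), 3 * sqrt(0.35 / 20000))
})

test_that("session summaries degrade gracefully on short sessions", {
  ses <- make_session(rep(c("G", "R"), 20), rep(0:1, 20))
  sm <- session_summary(ses)
  expect_true(is.na(sm$slope))
  expect_true(is.na(sm$variance))
  expect_false(is.na(sm$imbalance))
  expect_equal(sm$n_trials, 40)
})

test_that("drifting slow weight raises undermatching across sessions", {
  set.seed(35)
  sc <- default_sched_cfg(n_blocks = 6)
  n_ses <- 12
  w <- seq(0.05, 0.6, length.out = n_ses)
  cfg <- dataset_config(n_days = n_ses, sessions_per_day = 1,
                        weight_drift = cbind(1 - w, w), schedule = sc)
  ds <- generate_dataset(cfg, integrator_agent(c(5, 10000), c(0.95, 0.05)))
  sm <- summarize_sessions(ds)
  first_um <- mean(sm$undermatching[1:4], na.rm = TRUE)
  last_um <- mean(sm$undermatching[9:12], na.rm = TRUE)
  expect_gt(last_um, first_um)
})
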
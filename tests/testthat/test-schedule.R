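test_that("schedule_config validates its inputs", {
  expect_error(schedule_config(total_bait_rate = 0), "probability")
  expect_error(schedule_config(total_bait_rate = 1.2), "probability")
  expect_error(schedule_config(ratio_set = list(c(3, 0))), "ratio")
  expect_error(schedule_config(block_length_range = c(200, 100)), "min")
  expect_error(schedule_config(n_blocks = 0), "n_blocks")
})

test_that("block baiting rates split the total rate by the drawn ratio", {
  set.seed(1)
  sched <- generate_schedule(schedule_config(ratio_set = list(c(3, 1)),
                                             n_blocks = 6))
  per_block <- unique(sched[, c("block", "p_g", "p_r")])
  expect_equal(per_block$p_g + per_block$p_r, rep(0.35, 6))
  expect_true(all(apply(per_block[, c("p_g", "p_r")], 1, function(r)
    setequal(round(r, 6), round(c(0.35 * 3 / 4, 0.35 * 1 / 4), 6)))))

  sched11 <- generate_schedule(schedule_config(ratio_set = list(c(1, 1)),
                                               n_blocks = 3))
  expect_equal(sched11$p_g, rep(0.175, nrow(sched11)))
  expect_equal(sched11$p_r, rep(0.175, nrow(sched11)))
})

test_that("block structure respects the configured lengths and ordering", {
  set.seed(2)
  cfg <- schedule_config(block_length_range = c(100, 200), n_blocks = 20)
  sched <- generate_schedule(cfg)
  lens <- as.integer(table(sched$block))
  expect_true(all(lens >= 100 & lens <= 200))
  expect_true(all(diff(sched$block) >= 0))
  expect_equal(nrow(sched), sum(lens))
})

test_that("step_environment implements baiting and the changeover delay", {
  set.seed(3)
  # baited target chosen without a switch pays and empties
  st <- step_environment(0, 0, baited_g = TRUE, baited_r = FALSE,
                         choice = "G", prev_choice = "G")
  expect_equal(st$reward, 1L)
  expect_false(st$baited_g)
  # first choice of a switch is withheld; the bait persists
  st <- step_environment(0, 0, baited_g = TRUE, baited_r = FALSE,
                         choice = "G", prev_choice = "R")
  expect_equal(st$reward, 0L)
  expect_true(st$baited_g)
  # second consecutive choice of the new color collects it
  st <- step_environment(0, 0, baited_g = st$baited_g, baited_r = FALSE,
                         choice = "G", prev_choice = "G")
  expect_equal(st$reward, 1L)
  # nothing baited, nothing paid
  st <- step_environment(0, 0, FALSE, FALSE, "G", "G")
  expect_equal(st$reward, 0L)
  # without the COD a switch still pays
  st <- step_environment(0, 0, TRUE, FALSE, "G", "R", cod_enabled = FALSE)
  expect_equal(st$reward, 1L)
})

test_that("bait accounting is conserved over a session", {
  set.seed(4)
  sched <- generate_schedule(default_sched_cfg(n_blocks = 4))
  ses <- run_session(fixed_agent(0.5), sched)
  pending <- attr(ses, "n_baits_assigned") - sum(ses$reward)
  expect_gte(pending, 0)
  expect_lte(pending, 2)  # at most one uncollected bait per target
})

test_that("an omniscient agent without COD collects every assigned bait", {
  set.seed(5)
  sched <- generate_schedule(default_sched_cfg(n_blocks = 6,
                                               cod_enabled = FALSE))
  ses <- run_session(omniscient_agent(), sched)
  pending <- attr(ses, "n_baits_assigned") - sum(ses$reward)
  expect_lte(pending, 2)
  expect_gt(harvesting_efficiency(ses), 0.9)
})

test_that("a fixed 0.5 agent chooses green half the time on a 1:1 schedule", {
  set.seed(6)
  sched <- toy_schedule(10000, 0.175, 0.175, cod = FALSE)
  ses <- run_session(fixed_agent(0.5), sched)
  frac <- mean(ses$choice == "G")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("deterministic exclusive agents behave as expected", {
  set.seed(7)
  # always-green agent on an always-green-baited toy schedule collects all
  sched <- toy_schedule(10, 1, 0, cod = FALSE)
  ses <- run_session(fixed_agent(1), sched)
  expect_equal(sum(ses$reward), 10L)
  expect_true(all(ses$choice == "G"))
})

test_that("the changeover delay penalizes switch-heavy behavior", {
  set.seed(8)
  sched_on <- generate_schedule(default_sched_cfg(n_blocks = 6))
  set.seed(8)
  sched_off <- generate_schedule(default_sched_cfg(n_blocks = 6,
                                                   cod_enabled = FALSE))
  set.seed(99)
  r_on <- sum(run_session(fixed_agent(0.5), sched_on)$reward)
  set.seed(99)
  r_off <- sum(run_session(fixed_agent(0.5), sched_off)$reward)
  expect_lt(r_on, r_off)
})

test_that("switch pairs are collapsed into one free choice", {
  set.seed(9)
  sched <- generate_schedule(default_sched_cfg(n_blocks = 3))
  ses <- run_session(fixed_agent(0.5), sched)
  ch <- ses$choice
  n <- length(ch)
  sw <- c(FALSE, ch[-1] != ch[-n])
  # the trial after every switch repeats the new color and is not free
  after_switch <- which(sw)[which(sw) < n] + 1L
  expect_true(all(ch[after_switch] == ch[after_switch - 1L]))
  expect_true(all(!ses$free_choice[after_switch]))
  # all other trials are free
  expect_true(all(ses$free_choice[setdiff(seq_len(n), after_switch)]))
})

test_that("dataset generation follows the configured day/session structure", {
  set.seed(10)
  sc <- default_sched_cfg(n_blocks = 2, range = c(30L, 40L))
  cfg <- dataset_config(n_days = 3, sessions_per_day = 2, break_lengths = 2,
                        schedule = sc)
  ds <- generate_dataset(cfg, integrator_agent(c(5, 100), c(0.7, 0.3)))
  expect_length(ds, 6)
  expect_equal(vapply(ds, function(s) s$day[1], integer(1)),
               rep(1:3, each = 2))
  # break recorded on the first session of each day only
  brks <- vapply(ds, function(s) attr(s, "break_before"), numeric(1))
  expect_equal(brks, c(2, 0, 2, 0, 2, 0))

  expect_length(generate_dataset(dataset_config(n_days = 0, schedule = sc),
                                 integrator_agent(c(5), c(1))), 0)
})

test_that("weight drift trajectories are validated and applied", {
  sc <- default_sched_cfg(n_blocks = 2, range = c(30L, 40L))
  expect_error(dataset_config(n_days = 2, sessions_per_day = 1,
                              weight_drift = matrix(0.5, 3, 2),
                              schedule = sc), "one row per session")
  expect_error(dataset_config(n_days = 1, sessions_per_day = 2,
                              weight_drift = matrix(c(0.9, 0.9, 0.3, 0.3), 2),
                              schedule = sc), "simplex")
  set.seed(11)
  drift <- cbind(c(1, 0.5), c(0, 0.5))
  cfg <- dataset_config(n_days = 2, sessions_per_day = 1,
                        weight_drift = drift, schedule = sc)
  ds <- generate_dataset(cfg, integrator_agent(c(5, 100), c(1, 0)))
  expect_length(ds, 2)
})
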
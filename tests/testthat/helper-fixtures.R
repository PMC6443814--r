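# Shared fixtures: hand-built sessions and minimal agents for unit tests.

# build a session_data object from raw vectors
make_session <- function(choice, reward, block = rep(1L, length(choice)),
                         free = rep(TRUE, length(choice)),
                         total_bait_rate = 0.35, day = 1L, session = 1L) {
  n <- length(choice)
  out <- data.frame(day = day, session = session, trial = seq_len(n),
                    block = block, choice = choice, reward = reward,
                    free_choice = free, prob_g = NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "total_bait_rate") <- total_bait_rate
  attr(out, "n_baits_assigned") <- sum(reward)
  attr(out, "break_before") <- 0
  class(out) <- c("session_data", "data.frame")
  out
}

# agent with a fixed choice probability (never learns)
fixed_agent <- function(p) {
  structure(list(p = p), class = c("fixed_agent", "foraging_agent"))
}
registerS3method("agent_choice_prob", "fixed_agent", function(agent) agent$p,
                 envir = asNamespace("mtforage"))
registerS3method("agent_update", "fixed_agent",
                 function(agent, choice, reward) agent,
                 envir = asNamespace("mtforage"))

# single-block schedule with explicit rates, for toy environments
toy_schedule <- function(n_trials, p_g, p_r, cod = TRUE,
                         total_bait_rate = p_g + p_r) {
  out <- data.frame(trial = seq_len(n_trials), block = 1L,
                    p_g = p_g, p_r = p_r)
  attr(out, "total_bait_rate") <- total_bait_rate
  attr(out, "cod_enabled") <- cod
  class(out) <- c("foraging_schedule", "data.frame")
  out
}

default_sched_cfg <- function(n_blocks = 8L, range = c(100L, 150L), ...) {
  schedule_config(n_blocks = n_blocks, block_length_range = range, ...)
}
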
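#' Configure a concurrent variable-interval (baiting) schedule
#'
#' Describes the dynamic-foraging reward environment: two color targets (green
#' and red) are baited stochastically at rates that are constant within a block
#' of trials and change, without any signal, between blocks. A baited target
#' keeps its reward until it is chosen, so the probability of being rewarded
#' for choosing a target grows with the time since it was last chosen.
#'
#' @param total_bait_rate Sum of the two baiting probabilities, in rewards per
#'   trial. Default 0.35.
#' @param ratio_set List of length-2 numeric vectors giving the candidate
#'   baiting-rate ratios. Each block draws one ratio uniformly and assigns the
#'   richer side to green or red at random. Default `8:1, 6:1, 3:1, 1:1`.
#' @param block_length_range Integer vector `c(min, max)`; block lengths are
#'   drawn uniformly from this range. Default `c(100, 200)`.
#' @param n_blocks Number of blocks per schedule.
#' @param cod_enabled Logical; impose a changeover delay (COD)? Under the COD,
#'   a programmed reward is withheld on the first choice of a new color after a
#'   switch and delivered only on the second consecutive choice of that color.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(total_bait_rate = 0.35,
                            ratio_set = list(c(8, 1), c(6, 1), c(3, 1), c(1, 1)),
                            block_length_range = c(100L, 200L),
                            n_blocks = 10L,
                            cod_enabled = TRUE) {
  if (!is.numeric(total_bait_rate) || length(total_bait_rate) != 1 ||
      total_bait_rate <= 0 || total_bait_rate > 1)
    stop("'total_bait_rate' must be a probability in (0, 1]")
  if (!is.list(ratio_set) || length(ratio_set) == 0 ||
      !all(vapply(ratio_set, function(r) length(r) == 2 && all(r > 0), logical(1))))
    stop("'ratio_set' must be a non-empty list of positive length-2 ratios")
  block_length_range <- as.integer(round(block_length_range))
  if (length(block_length_range) != 2 || any(block_length_range < 1) ||
      block_length_range[1] > block_length_range[2])
    stop("'block_length_range' must be c(min, max) with 1 <= min <= max")
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1) stop("'n_blocks' must be >= 1")
  structure(list(total_bait_rate = total_bait_rate,
                 ratio_set = ratio_set,
                 block_length_range = block_length_range,
                 n_blocks = n_blocks,
                 cod_enabled = isTRUE(cod_enabled)),
            class = "schedule_config")
}

#' Generate a block schedule of baiting probabilities
#'
#' Draws block lengths and baiting ratios for `config$n_blocks` blocks. Within
#' each block the two per-trial baiting probabilities are constant and sum to
#' `total_bait_rate`; the richer rate is assigned to green or red with equal
#' probability. Baiting itself is evaluated lazily at run time by
#' [run_session()]: an empty target is armed on each trial with its baiting
#' probability and stays baited until chosen.
#'
#' Uses the current R random-number stream; call `set.seed()` beforehand for
#' reproducibility. Draw order: for each block, first the length, then the
#' ratio index, then the side assignment.
#'
#' @param config A [schedule_config()].
#' @return A data frame of class `foraging_schedule` with one row per trial and
#'   columns `trial`, `block`, `p_g`, `p_r`, carrying the configuration in
#'   attributes `total_bait_rate` and `cod_enabled`.
#' @export
generate_schedule <- function(config = schedule_config()) {
  stopifnot(inherits(config, "schedule_config"))
  n <- config$n_blocks
  lens <- integer(n)
  p_g <- numeric(n)
  p_r <- numeric(n)
  rng <- config$block_length_range
  for (b in seq_len(n)) {
    lens[b] <- if (rng[1] == rng[2]) rng[1] else
      sample.int(rng[2] - rng[1] + 1L, 1L) + rng[1] - 1L
    ratio <- config$ratio_set[[sample.int(length(config$ratio_set), 1L)]]
    rates <- config$total_bait_rate * ratio / sum(ratio)
    if (stats::runif(1) < 0.5) rates <- rev(rates)
    p_g[b] <- rates[1]
    p_r[b] <- rates[2]
  }
  out <- data.frame(trial = seq_len(sum(lens)),
                    block = rep.int(seq_len(n), lens),
                    p_g = rep.int(p_g, lens),
                    p_r = rep.int(p_r, lens))
  attr(out, "total_bait_rate") <- config$total_bait_rate
  attr(out, "cod_enabled") <- config$cod_enabled
  class(out) <- c("foraging_schedule", "data.frame")
  out
}

#' Advance the baiting environment by one trial
#'
#' Applies the trial-level rules of the concurrent-VI schedule: both targets
#' are (re)armed first, then the chosen target pays out unless the choice is
#' the first of a switch under the changeover delay, in which case the reward
#' is withheld (the bait persists) until the second consecutive choice of the
#' new color. A delivered reward consumes the bait.
#'
#' Exposed mainly for testing and for custom agents; [run_session()] uses the
#' same logic internally.
#'
#' @param p_g,p_r Baiting probabilities for this trial.
#' @param baited_g,baited_r Logical bait state before the trial.
#' @param choice `"G"` or `"R"`.
#' @param prev_choice Previous trial's choice (`"G"`, `"R"`, or `NA` on the
#'   first trial).
#' @param cod_enabled Logical; apply the changeover delay?
#' @return A list with `reward` (0/1), updated `baited_g`, `baited_r`, and
#'   `n_assigned` (baits armed on this trial, 0-2).
#' @export
step_environment <- function(p_g, p_r, baited_g, baited_r, choice, prev_choice,
                             cod_enabled = TRUE) {
  n_assigned <- 0L
  if (!baited_g && stats::runif(1) < p_g) { baited_g <- TRUE; n_assigned <- n_assigned + 1L }
  if (!baited_r && stats::runif(1) < p_r) { baited_r <- TRUE; n_assigned <- n_assigned + 1L }
  is_switch <- !is.na(prev_choice) && choice != prev_choice
  reward <- 0L
  if (!(cod_enabled && is_switch)) {
    if (choice == "G" && baited_g) { reward <- 1L; baited_g <- FALSE }
    if (choice == "R" && baited_r) { reward <- 1L; baited_r <- FALSE }
  }
  list(reward = reward, baited_g = baited_g, baited_r = baited_r,
       n_assigned = n_assigned)
}

#' Simulate one session of an agent foraging on a schedule
#'
#' Runs the closed loop of the task: on every trial the environment arms empty
#' targets, the agent emits a choice probability and a choice, the changeover
#' delay (if enabled) gates reward delivery, and the agent updates its internal
#' state from the delivered outcome.
#'
#' With the COD enabled, the trial after a switch is imposed: the agent
#' repeats the new color (subjects learn exactly this commitment, completing
#' switches with well over 90% probability), so every switch is a committed
#' pair whose imposed second choice is flagged `free_choice = FALSE`, and
#' analyses treat the pair as a single free choice. The sampling policy also
#' applies a lapse floor `p_floor`: without it the ratio decision rule is
#' absorbing — between rewards both targets' incomes decay at the same rate,
#' so the income ratio can only drift away from parity and a purely fast
#' agent locks into exclusive choice instead of matching. A small lapse keeps
#' the lean target sampled occasionally, as real subjects do.
#'
#' @param agent A foraging agent, e.g. [integrator_agent()], [bias_agent()],
#'   [cascade_agent()], or [omniscient_agent()].
#' @param schedule A `foraging_schedule` from [generate_schedule()].
#' @param day,session Integer metadata stored on the result.
#' @param break_before Length of the break preceding this session's day
#'   (abstract units, metadata only).
#' @param p_floor Lapse floor; choice probabilities are clipped to
#'   `[p_floor, 1 - p_floor]` before sampling (default 0.01). Policy-level
#'   only: the agent's internal incomes are untouched, and `prob_g` records
#'   the clipped probability actually sampled from.
#' @return A data frame of class `session_data` with one row per trial and
#'   columns `day`, `session`, `trial`, `block`, `choice`, `reward`,
#'   `free_choice`, `prob_g`; attributes `n_baits_assigned`,
#'   `total_bait_rate`, `break_before`, and `agent` (the updated agent, for
#'   carryover across sessions).
#' @export
run_session <- function(agent, schedule, day = 1L, session = 1L,
                        break_before = 0, p_floor = 0.01) {
  stopifnot(inherits(schedule, "foraging_schedule"))
  if (p_floor < 0 || p_floor >= 0.5) stop("'p_floor' must be in [0, 0.5)")
  n <- nrow(schedule)
  cod <- isTRUE(attr(schedule, "cod_enabled"))
  p_g <- schedule$p_g
  p_r <- schedule$p_r
  choice <- character(n)
  reward <- integer(n)
  prob_g <- numeric(n)
  free <- rep(TRUE, n)
  baited_g <- FALSE
  baited_r <- FALSE
  n_assigned <- 0L
  prev <- NA_character_
  prev_was_switch <- FALSE
  omni <- inherits(agent, "omniscient_agent")
  for (t in seq_len(n)) {
    if (!baited_g && stats::runif(1) < p_g[t]) { baited_g <- TRUE; n_assigned <- n_assigned + 1L }
    if (!baited_r && stats::runif(1) < p_r[t]) { baited_r <- TRUE; n_assigned <- n_assigned + 1L }
    if (omni) {
      ch <- if (baited_g) "G" else if (baited_r) "R" else
        if (!is.na(prev)) prev else "G"
      p <- as.numeric(ch == "G")
    } else if (cod && prev_was_switch) {
      # imposed second choice of the committed switch pair
      ch <- prev
      p <- agent_choice_prob(agent)
      p <- min(max(p, p_floor), 1 - p_floor)
      free[t] <- FALSE
    } else {
      p <- agent_choice_prob(agent)
      if (!is.finite(p) || p < 0 || p > 1)
        stop("agent returned an invalid choice probability: ", p)
      p <- min(max(p, p_floor), 1 - p_floor)
      ch <- if (stats::runif(1) < p) "G" else "R"
    }
    is_switch <- !is.na(prev) && ch != prev
    r <- 0L
    if (!(cod && is_switch)) {
      if (ch == "G" && baited_g) { r <- 1L; baited_g <- FALSE }
      if (ch == "R" && baited_r) { r <- 1L; baited_r <- FALSE }
    }
    if (!omni) agent <- agent_update(agent, ch, r)
    choice[t] <- ch
    reward[t] <- r
    prob_g[t] <- p
    prev_was_switch <- is_switch
    prev <- ch
  }
  out <- data.frame(day = as.integer(day), session = as.integer(session),
                    trial = seq_len(n), block = schedule$block,
                    choice = choice, reward = reward,
                    free_choice = free, prob_g = prob_g,
                    stringsAsFactors = FALSE)
  attr(out, "n_baits_assigned") <- n_assigned
  attr(out, "total_bait_rate") <- attr(schedule, "total_bait_rate")
  attr(out, "break_before") <- break_before
  attr(out, "agent") <- agent
  class(out) <- c("session_data", "data.frame")
  out
}

#' Configure a multi-day synthetic dataset
#'
#' Describes the session/break structure of a long experiment: days each
#' containing one or more sessions, separated by breaks of variable length,
#' with the agent's integrator weights optionally drifting from session to
#' session (emulating a slow re-weighting of fast versus slow learning across
#' the experiment).
#'
#' @param n_days Number of experimental days.
#' @param sessions_per_day Integer (recycled) or vector of length `n_days`.
#' @param break_lengths Breaks preceding each day (abstract units; first entry
#'   is the break before day 1, usually 0). Recycled to `n_days`.
#' @param weight_drift Optional matrix with one row per session giving the
#'   integrator weights for that session (rows on the simplex), or `NULL` to
#'   keep the agent's own weights throughout.
#' @param schedule A [schedule_config()] used for every session.
#' @return An object of class `dataset_config`.
#' @export
dataset_config <- function(n_days = 10L, sessions_per_day = 3L,
                           break_lengths = 1, weight_drift = NULL,
                           schedule = schedule_config()) {
  n_days <- as.integer(n_days)
  if (n_days < 0) stop("'n_days' must be >= 0")
  spd <- as.integer(rep_len(sessions_per_day, max(n_days, 1L)))
  if (n_days > 0 && any(spd < 1)) stop("'sessions_per_day' must be >= 1")
  brk <- rep_len(as.numeric(break_lengths), max(n_days, 1L))
  if (any(brk < 0)) stop("'break_lengths' must be >= 0")
  n_sessions <- if (n_days > 0) sum(spd[seq_len(n_days)]) else 0L
  if (!is.null(weight_drift)) {
    weight_drift <- as.matrix(weight_drift)
    if (nrow(weight_drift) != n_sessions)
      stop("'weight_drift' must have one row per session (", n_sessions, ")")
    if (any(weight_drift < 0) ||
        any(abs(rowSums(weight_drift) - 1) > 1e-8))
      stop("'weight_drift' rows must lie on the simplex")
  }
  structure(list(n_days = n_days, sessions_per_day = spd,
                 break_lengths = brk, weight_drift = weight_drift,
                 schedule = schedule),
            class = "dataset_config")
}

#' Generate a multi-day dataset of simulated sessions
#'
#' Sessions are generated in chronological order. The slow-integrator state is
#' carried across sessions (the fast integrators are reset at each session
#' start), mirroring how per-session model fits treat the slow income. For
#' cascade agents, [forget_step()] is applied at day boundaries in proportion
#' to the break length.
#'
#' @param config A [dataset_config()].
#' @param agent The starting agent.
#' @param carryover Logical; carry the slow integrator (or cascade synaptic
#'   state) across sessions? Default `TRUE`.
#' @return A list of `session_data` objects, class `foraging_dataset`.
#' @export
generate_dataset <- function(config, agent, carryover = TRUE) {
  stopifnot(inherits(config, "dataset_config"))
  sessions <- list()
  s_idx <- 0L
  for (d in seq_len(config$n_days)) {
    brk <- config$break_lengths[d]
    if (d > 1L && inherits(agent, "cascade_agent"))
      agent <- forget_agent(agent, brk)
    for (k in seq_len(config$sessions_per_day[d])) {
      s_idx <- s_idx + 1L
      if (!is.null(config$weight_drift) && inherits(agent, "integrator_agent"))
        agent$weights <- config$weight_drift[s_idx, ]
      agent <- agent_session_reset(agent, carryover = carryover)
      sched <- generate_schedule(config$schedule)
      ses <- run_session(agent, sched, day = d, session = s_idx,
                         break_before = if (k == 1L) brk else 0)
      agent <- attr(ses, "agent")
      attr(ses, "agent") <- NULL
      sessions[[s_idx]] <- ses
    }
  }
  structure(sessions, class = "foraging_dataset")
}
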
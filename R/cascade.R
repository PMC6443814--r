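#' Cascade synapse parameters
#'
#' Parameters of the metaplastic (cascade) synapse chain: each synapse has a
#' binary strength (depressed or potentiated) and one of `n_levels` ordered
#' plasticity levels. Strength transitions from level `i` occur with
#' probability `alpha[i]` and land in the most plastic level of the opposite
#' strength; metaplastic deepening from level `i` to `i + 1` occurs with
#' probability `q[i]` when the outcome is congruent with the current strength.
#' Rates are logarithmically spaced (`alpha_i = x^i`, `q_i = x^i`), so deeper
#' states are harder to enter and harder to leave.
#'
#' @param n_levels Number of plasticity levels `m` (default 3).
#' @param x Base of the geometric rate ladder (default 0.2).
#' @param alpha Strength-transition rates per level (default `x^(1:m)`),
#'   strictly decreasing.
#' @param q Deepening rates between consecutive levels (default
#'   `x^(1:(m-1))`), strictly decreasing.
#' @param temperature Readout temperature of the logistic choice rule
#'   (default 0.1).
#' @param forget_rate Probability per break unit that a pathway receives a
#'   random (reward-uncorrelated) plasticity event during a break
#'   (default 0.2).
#' @return An object of class `cascade_params`.
#' @export
cascade_params <- function(n_levels = 3L, x = 0.2,
                           alpha = x^seq_len(n_levels),
                           q = x^seq_len(max(n_levels - 1L, 1L)),
                           temperature = 0.1, forget_rate = 0.2) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) stop("'n_levels' must be >= 2")
  if (length(alpha) != n_levels || any(alpha <= 0) || any(alpha > 1) ||
      any(diff(alpha) >= 0))
    stop("'alpha' must be strictly decreasing rates in (0, 1], one per level")
  q <- q[seq_len(n_levels - 1L)]
  if (any(q <= 0) || any(q > 1) || (length(q) > 1 && any(diff(q) >= 0)))
    stop("'q' must be strictly decreasing rates in (0, 1]")
  if (temperature <= 0) stop("'temperature' must be positive")
  if (forget_rate < 0 || forget_rate > 1)
    stop("'forget_rate' must be in [0, 1]")
  structure(list(n_levels = n_levels, alpha = alpha, q = q,
                 temperature = temperature, forget_rate = forget_rate),
            class = "cascade_params")
}

#' Uniform synapse population
#'
#' Occupancy fractions over the `2 * n_levels` states (strength - / + by
#' level), initialized uniformly — the assumed state at the start of the
#' first experimental day, before any consolidation.
#'
#' @param n_levels Number of plasticity levels.
#' @return A `2 x n_levels` matrix with rows `minus`, `plus`, summing to 1.
#' @export
uniform_population <- function(n_levels = 3L) {
  m <- matrix(1 / (2 * n_levels), 2, n_levels,
              dimnames = list(c("minus", "plus"), NULL))
  m
}

#' Choice readout from two synapse populations
#'
#' The two action-selection pathways compete through their mean synaptic
#' strengths (fraction of potentiated synapses); the probability of choosing
#' green is a logistic function of the strength difference scaled by the
#' readout temperature.
#'
#' @param pop_g,pop_r Occupancy matrices (see [uniform_population()]).
#' @param temperature Positive readout temperature.
#' @return Probability of choosing green.
#' @export
readout_probability <- function(pop_g, pop_r, temperature) {
  if (temperature <= 0) stop("'temperature' must be positive")
  stats::plogis((sum(pop_g["plus", ]) - sum(pop_r["plus", ])) / temperature)
}

# mean-field potentiation operator: depressed(i) -> plus(1) w.p. alpha_i,
# plus(i) -> plus(i+1) w.p. q_i
cascade_potentiate <- function(pop, params, rate = 1) {
  a <- params$alpha * rate
  q <- params$q * rate
  m <- params$n_levels
  minus <- pop["minus", ]
  plus <- pop["plus", ]
  new_minus <- minus * (1 - a)
  new_plus <- plus
  if (m > 1) {
    deep <- plus[seq_len(m - 1)] * q
    new_plus[seq_len(m - 1)] <- new_plus[seq_len(m - 1)] - deep
    new_plus[2:m] <- new_plus[2:m] + deep
  }
  new_plus[1] <- new_plus[1] + sum(minus * a)
  rbind(minus = new_minus, plus = new_plus)
}

cascade_depress <- function(pop, params, rate = 1) {
  flipped <- pop[c("plus", "minus"), , drop = FALSE]
  rownames(flipped) <- c("minus", "plus")
  out <- cascade_potentiate(flipped, params, rate)
  out <- out[c("plus", "minus"), , drop = FALSE]
  rownames(out) <- c("minus", "plus")
  out
}

#' One reward-gated learning step of the cascade model
#'
#' Applies the Markov transition operator to the chosen pathway's occupancy
#' distribution (mean-field engine): a rewarded choice potentiates — each
#' depressed synapse at level `i` becomes potentiated at the most plastic
#' level with probability `alpha[i]`, and each potentiated synapse deepens
#' from level `i` to `i + 1` with probability `q[i]`; an unrewarded choice
#' applies the mirror-image depression. The unchosen pathway is unchanged.
#' With `n_synapses` set, a finite stochastic population is simulated instead
#' with binomial transition counts.
#'
#' @param state List with occupancy matrices `G` and `R`.
#' @param choice `"G"` or `"R"`.
#' @param reward 0 or 1.
#' @param params A [cascade_params()].
#' @param n_synapses If non-`NULL`, simulate this many synapses
#'   stochastically (occupancies stay fractions; counts are drawn and
#'   renormalized).
#' @return The updated state.
#' @export
learn_step <- function(state, choice, reward, params, n_synapses = NULL) {
  pop <- state[[choice]]
  op <- if (reward == 1) cascade_potentiate else cascade_depress
  if (is.null(n_synapses)) {
    state[[choice]] <- op(pop, params)
  } else {
    state[[choice]] <- stochastic_step(pop, params, reward == 1, n_synapses)
  }
  state
}

stochastic_step <- function(pop, params, potentiate, n_synapses) {
  if (!potentiate) {
    pop <- pop[c("plus", "minus"), , drop = FALSE]
    rownames(pop) <- c("minus", "plus")
  }
  m <- params$n_levels
  counts <- round(pop * n_synapses)
  move_up <- stats::rbinom(m, counts["minus", ], params$alpha)
  counts["minus", ] <- counts["minus", ] - move_up
  if (m > 1) {
    deep <- stats::rbinom(m - 1, counts["plus", seq_len(m - 1)], params$q)
    counts["plus", seq_len(m - 1)] <- counts["plus", seq_len(m - 1)] - deep
    counts["plus", 2:m] <- counts["plus", 2:m] + deep
  }
  counts["plus", 1] <- counts["plus", 1] + sum(move_up)
  out <- counts / sum(counts)
  if (!potentiate) {
    out <- out[c("plus", "minus"), , drop = FALSE]
    rownames(out) <- c("minus", "plus")
  }
  out
}

#' Inter-session forgetting of the cascade model
#'
#' During breaks, synapses experience random activity uncorrelated with the
#' reward structure of the task. Unlike reward-gated learning, these
#' spontaneous transitions are not funneled through the plasticity ladder:
#' with probability `forget_rate` per break unit, a synapse resets to the
#' most plastic level with a random (balanced) strength. Occupancies
#' therefore relax exponentially toward the naive plastic state, so longer
#' breaks both erase accumulated strength biases and raise the effective
#' learning rate of the following session.
#'
#' @param state List with occupancy matrices `G` and `R`.
#' @param break_length Non-negative number of break units.
#' @param params A [cascade_params()].
#' @return The updated state.
#' @export
forget_step <- function(state, break_length, params) {
  if (break_length < 0) stop("'break_length' must be >= 0")
  keep <- (1 - params$forget_rate)^break_length
  for (side in c("G", "R")) {
    pop <- state[[side]]
    naive <- matrix(0, nrow(pop), ncol(pop), dimnames = dimnames(pop))
    naive[, 1] <- 0.5
    state[[side]] <- keep * pop + (1 - keep) * naive
  }
  state
}

#' Cascade parameters for the multi-day consolidation experiment
#'
#' A two-tier rate ladder tuned so the model reproduces the experimental
#' phenomenology on a multi-day protocol: a plastic tier (levels 1-2, rates
#' 0.5 and 0.25) that tracks rewards within blocks like a fast integrator,
#' and a consolidated tier (levels 3-5) that is entered through a slow
#' metaplastic bottleneck (`q_2 = 5e-4`) and is nearly immune to reward-gated
#' flips. Deep occupancy therefore builds up over days — storing the long-run
#' (balanced) reward statistics and progressively compressing the readout
#' toward indifference — while nightly forgetting (`forget_rate = 0.02` per
#' break unit) slowly re-plasticizes it. With these rates matching is good in
#' early days and undermatching grows with consolidation.
#'
#' @param temperature Readout temperature (default 0.05).
#' @param forget_rate Reset probability per break unit (default 0.02).
#' @return A [cascade_params()] object with 5 levels.
#' @export
cascade_experiment_params <- function(temperature = 0.05,
                                      forget_rate = 0.02) {
  cascade_params(n_levels = 5,
                 alpha = c(0.5, 0.25, 1e-4, 5e-5, 2.5e-5),
                 q = c(0.25, 5e-4, 2.5e-4, 1.25e-4),
                 temperature = temperature, forget_rate = forget_rate)
}

#' Cascade-model foraging agent
#'
#' Wraps a cascade synapse state and parameters as a foraging agent usable
#' with [run_session()] and [generate_dataset()]: choices are read out from
#' the two pathways' mean strengths and every trial outcome drives a
#' reward-gated learning step on the chosen pathway.
#'
#' @param params A [cascade_params()].
#' @param state Initial state (default: both pathways uniform).
#' @param n_synapses Optional finite population size for the stochastic
#'   engine (`NULL` for mean-field).
#' @return An object of class `c("cascade_agent", "foraging_agent")`.
#' @export
cascade_agent <- function(params = cascade_params(), state = NULL,
                          n_synapses = NULL) {
  if (is.null(state))
    state <- list(G = uniform_population(params$n_levels),
                  R = uniform_population(params$n_levels))
  structure(list(params = params, state = state, n_synapses = n_synapses),
            class = c("cascade_agent", "foraging_agent"))
}

#' @export
agent_choice_prob.cascade_agent <- function(agent) {
  readout_probability(agent$state$G, agent$state$R,
                      agent$params$temperature)
}

#' @export
agent_update.cascade_agent <- function(agent, choice, reward) {
  agent$state <- learn_step(agent$state, choice, reward, agent$params,
                            n_synapses = agent$n_synapses)
  agent
}

forget_agent <- function(agent, break_length) {
  agent$state <- forget_step(agent$state, break_length, agent$params)
  agent
}

#' Simulate a multi-day experiment with the cascade model
#'
#' Runs the full protocol — days of sessions on freshly drawn schedules,
#' reward-gated learning within sessions, forgetting across breaks — starting
#' from uniformly distributed metaplastic states, and returns the sessions
#' together with their per-session summaries. As synapses consolidate over
#' days, the model's effective integration timescale lengthens: matching is
#' good early and undermatching grows, while the variance of choice falls.
#'
#' @param config A [dataset_config()].
#' @param params A [cascade_params()].
#' @param n_synapses Optional stochastic population size.
#' @return A list with `sessions` (a `foraging_dataset`) and `summaries`
#'   (from [summarize_sessions()]).
#' @export
run_cascade_experiment <- function(config, params = cascade_experiment_params(),
                                   n_synapses = NULL) {
  agent <- cascade_agent(params, n_synapses = n_synapses)
  sessions <- generate_dataset(config, agent)
  list(sessions = sessions, summaries = summarize_sessions(sessions))
}
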
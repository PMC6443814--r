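#' Leaky-integrator income update
#'
#' One step of the exponential reward filter
#' \deqn{I^t = (1 - 1/\tau)\, I^{t-1} + (1/\tau)\, r^{t-1},}
#' a convex combination of the previous local income and the last outcome.
#' Applied every trial to both targets, with \eqn{r = 1} only when that target
#' was chosen and rewarded.
#'
#' @param income Current local income, in rewards/trial (in `[0, 1]`).
#' @param reward 0 or 1.
#' @param tau Integration time constant in trials, `tau >= 1`.
#' @return The updated income. Vectorized over `income` (one value per
#'   timescale when `tau` is a vector of matching length).
#' @export
update_income <- function(income, reward, tau) {
  if (any(tau < 1)) stop("'tau' must be >= 1")
  (1 - 1 / tau) * income + reward / tau
}

#' Combine per-timescale incomes with simplex weights
#'
#' The decision variable of the multi-timescale model is the weighted sum of
#' the local incomes computed on each timescale,
#' \eqn{I = \sum_i w_i I_i} with \eqn{w_i \ge 0, \sum_i w_i = 1}.
#'
#' @param incomes Numeric vector of per-timescale local incomes for one target.
#' @param weights Simplex weights of the same length.
#' @return The combined income (scalar).
#' @export
combined_income <- function(incomes, weights) {
  if (length(incomes) != length(weights))
    stop("'incomes' and 'weights' must have the same length")
  sum(weights * incomes)
}

#' Local matching decision rule
#'
#' Probability of choosing the green target given the two combined local
#' incomes, \eqn{P_G = I_G / (I_G + I_R)}. When both incomes are zero the
#' rule is undefined and the indifferent value 0.5 is returned by convention.
#'
#' @param income_g,income_r Non-negative combined incomes.
#' @return Probability of choosing green.
#' @export
choice_probability <- function(income_g, income_r) {
  if (income_g < 0 || income_r < 0) stop("incomes must be non-negative")
  tot <- income_g + income_r
  if (tot == 0) 0.5 else income_g / tot
}

#' Random-bias alternative decision rule
#'
#' Choice probability of a model in which reward integration happens only on a
#' fast timescale and each session adds fixed additive color biases:
#' \eqn{P_G = (I_G + B_G) / (I_G + I_R + B_G + B_R)}. With both biases zero
#' this reduces to [choice_probability()]. Used to demonstrate that session-
#' level model fitting cannot discriminate slow reward integration from a
#' session-random bias.
#'
#' @param income_g,income_r Fast-timescale incomes (non-negative).
#' @param bias_g,bias_r Additive biases (non-negative, income units).
#' @return Probability of choosing green.
#' @export
bias_model_probability <- function(income_g, income_r, bias_g, bias_r) {
  if (any(c(income_g, income_r, bias_g, bias_r) < 0))
    stop("incomes and biases must be non-negative")
  tot <- income_g + income_r + bias_g + bias_r
  if (tot == 0) 0.5 else (income_g + bias_g) / tot
}

#' First-order prediction of the matching-slope deficit
#'
#' In the regime where the slow integrator's weight is small, expanding the
#' matching rule to first order predicts a slope deficit
#' \deqn{1 - S \approx (w_{Slow}/w_{Fast}) \cdot
#'       (I^{Slow}_{tot} / I^{Fast}_{tot}),}
#' i.e. undermatching proportional to the slow weight times the total slow
#' income. Used to validate simulations against the analytic approximation.
#'
#' @param w_slow,w_fast Integrator weights (`w_fast > 0`).
#' @param slow_total_income Sum of the two targets' slow incomes.
#' @param fast_total_income Sum of the two targets' fast incomes (must be
#'   positive).
#' @return The predicted `1 - slope`.
#' @export
undermatching_approximation <- function(w_slow, w_fast, slow_total_income,
                                        fast_total_income) {
  if (fast_total_income <= 0) stop("'fast_total_income' must be positive")
  (w_slow / w_fast) * (slow_total_income / fast_total_income)
}

#' Multi-timescale integrator agent
#'
#' The reference choice model: one leaky integrator per timescale per target,
#' combined with simplex weights and fed to the local matching rule. With a
#' single timescale it reduces to the classic single-integrator matching
#' model.
#'
#' @param taus Time constants in trials (each `>= 1`).
#' @param weights Simplex weights, same length as `taus`.
#' @param initial_income Starting income per target per timescale. Defaults to
#'   half the default schedule's total baiting rate (0.175), an unbiased start
#'   at the environment's mean payoff.
#' @return An object of class `c("integrator_agent", "foraging_agent")`.
#' @export
integrator_agent <- function(taus, weights = rep(1 / length(taus), length(taus)),
                             initial_income = 0.175) {
  taus <- as.numeric(taus)
  weights <- as.numeric(weights)
  if (any(taus < 1)) stop("'taus' must be >= 1")
  if (length(weights) != length(taus)) stop("one weight per timescale required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be non-negative and sum to 1")
  m <- length(taus)
  structure(list(taus = taus, weights = weights,
                 initial_income = initial_income,
                 income_g = rep(initial_income, m),
                 income_r = rep(initial_income, m)),
            class = c("integrator_agent", "foraging_agent"))
}

#' Random-bias agent
#'
#' Fast-integrator agent with additive per-session color biases (the
#' alternative model of the identifiability confound). Biases may be redrawn
#' each session via [agent_session_reset()] when `bias_sd > 0`.
#'
#' @param tau Fast time constant in trials.
#' @param bias_g,bias_r Additive color biases (income units, `>= 0`).
#' @param bias_sd If positive, at each session start both biases are redrawn
#'   as `abs(rnorm(1, bias_mean, bias_sd))`.
#' @param bias_mean Mean for redrawn biases.
#' @param initial_income Starting income per target.
#' @return An object of class `c("bias_agent", "foraging_agent")`.
#' @export
bias_agent <- function(tau = 5, bias_g = 0, bias_r = 0, bias_sd = 0,
                       bias_mean = 0, initial_income = 0.175) {
  if (tau < 1) stop("'tau' must be >= 1")
  if (bias_g < 0 || bias_r < 0) stop("biases must be non-negative")
  structure(list(tau = tau, bias_g = bias_g, bias_r = bias_r,
                 bias_sd = bias_sd, bias_mean = bias_mean,
                 initial_income = initial_income,
                 income_g = initial_income, income_r = initial_income),
            class = c("bias_agent", "foraging_agent"))
}

#' Omniscient benchmark agent
#'
#' Always chooses a baited target when one exists (green first if both); with
#' the COD disabled it therefore collects every assigned bait, pinning the
#' harvesting-efficiency ceiling at 1.
#'
#' @return An object of class `c("omniscient_agent", "foraging_agent")`.
#' @export
omniscient_agent <- function() {
  structure(list(), class = c("omniscient_agent", "foraging_agent"))
}

#' Choice probability of a foraging agent
#'
#' @param agent A foraging agent.
#' @return The probability of choosing the green target on the next trial.
#' @export
agent_choice_prob <- function(agent) UseMethod("agent_choice_prob")

#' @export
agent_choice_prob.integrator_agent <- function(agent) {
  choice_probability(sum(agent$weights * agent$income_g),
                     sum(agent$weights * agent$income_r))
}

#' @export
agent_choice_prob.bias_agent <- function(agent) {
  bias_model_probability(agent$income_g, agent$income_r,
                         agent$bias_g, agent$bias_r)
}

#' Update a foraging agent with a trial outcome
#'
#' @param agent A foraging agent.
#' @param choice `"G"` or `"R"`.
#' @param reward 0 or 1 (the delivered reward).
#' @return The updated agent.
#' @export
agent_update <- function(agent, choice, reward) UseMethod("agent_update")

#' @export
agent_update.integrator_agent <- function(agent, choice, reward) {
  a <- 1 / agent$taus
  agent$income_g <- (1 - a) * agent$income_g
  agent$income_r <- (1 - a) * agent$income_r
  if (reward == 1) {
    if (choice == "G") agent$income_g <- agent$income_g + a
    else agent$income_r <- agent$income_r + a
  }
  agent
}

#' @export
agent_update.bias_agent <- function(agent, choice, reward) {
  a <- 1 / agent$tau
  agent$income_g <- (1 - a) * agent$income_g
  agent$income_r <- (1 - a) * agent$income_r
  if (reward == 1) {
    if (choice == "G") agent$income_g <- agent$income_g + a
    else agent$income_r <- agent$income_r + a
  }
  agent
}

#' Draw one choice from an agent
#'
#' Bernoulli draw from the agent's current choice probability, using the
#' current R random stream.
#'
#' @param agent A foraging agent.
#' @return `"G"` or `"R"`.
#' @export
act <- function(agent) {
  p <- agent_choice_prob(agent)
  if (stats::runif(1) < p) "G" else "R"
}

#' Reset an agent at a session boundary
#'
#' Fast integrators restart at their initial income; when `carryover = TRUE`
#' the slowest integrator's incomes persist from the previous session (only
#' the slowest: all timescales shorter than the longest are treated as fast).
#' Bias agents redraw their session biases when configured to. Cascade agents
#' are returned unchanged (their persistence is synaptic).
#'
#' @param agent A foraging agent.
#' @param carryover Logical.
#' @return The reset agent.
#' @export
agent_session_reset <- function(agent, carryover = TRUE) {
  UseMethod("agent_session_reset")
}

#' @export
agent_session_reset.integrator_agent <- function(agent, carryover = TRUE) {
  m <- length(agent$taus)
  slow <- which.max(agent$taus)
  keep_g <- agent$income_g[slow]
  keep_r <- agent$income_r[slow]
  agent$income_g <- rep(agent$initial_income, m)
  agent$income_r <- rep(agent$initial_income, m)
  if (isTRUE(carryover)) {
    agent$income_g[slow] <- keep_g
    agent$income_r[slow] <- keep_r
  }
  agent
}

#' @export
agent_session_reset.bias_agent <- function(agent, carryover = TRUE) {
  agent$income_g <- agent$initial_income
  agent$income_r <- agent$initial_income
  if (agent$bias_sd > 0) {
    agent$bias_g <- abs(stats::rnorm(1, agent$bias_mean, agent$bias_sd))
    agent$bias_r <- abs(stats::rnorm(1, agent$bias_mean, agent$bias_sd))
  }
  agent
}

#' @export
agent_session_reset.default <- function(agent, carryover = TRUE) agent

#' Construct an agent from a configuration block
#'
#' Builds a foraging agent from a plain named list — typically one block of
#' a YAML configuration file read with [yaml::read_yaml()]. The `model`
#' entry selects the constructor: `"multi_timescale"` (or its one-timescale
#' special case `"single_timescale"`) for [integrator_agent()],
#' `"random_bias"` for [bias_agent()], `"cascade"` for [cascade_agent()];
#' remaining entries are passed through as constructor arguments.
#'
#' @param config Named list with a `model` string and constructor fields,
#'   e.g. `list(model = "multi_timescale", taus = c(5, 1000),
#'   weights = c(0.7, 0.3))`.
#' @return A foraging agent.
#' @export
agent_from_config <- function(config) {
  if (is.null(config$model)) stop("'config$model' is required")
  model <- config$model
  config$model <- NULL
  switch(model,
    multi_timescale = ,
    single_timescale = do.call(integrator_agent, config),
    random_bias = do.call(bias_agent, config),
    cascade = {
      pars <- do.call(cascade_params, config[setdiff(names(config),
                                                     "n_synapses")])
      cascade_agent(pars, n_synapses = config$n_synapses)
    },
    stop("unknown model '", model, "'"))
}
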
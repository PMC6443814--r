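#' Single-target estimation task
#'
#' The reduced inference problem used to analyze the bias-variance tradeoff:
#' estimate a Bernoulli reward probability that is constant within blocks of
#' `block_length` trials and steps between blocks through `p_levels`. By
#' default the levels are the block reward fractions of the default foraging
#' schedule (ratios 8:1, 6:1, 3:1, 1:1 of a total rate of 0.35, seen from the
#' richer side), cycled deterministically.
#'
#' @param block_length Trials per block.
#' @param p_levels Reward probabilities visited by the blocks.
#' @param burnin_blocks Blocks discarded before time-averaging (stationarity
#'   proxy; default 10).
#' @return An object of class `estimation_task`.
#' @export
estimation_task <- function(block_length = 100L,
                            p_levels = 0.35 * c(8 / 9, 6 / 7, 3 / 4, 1 / 2),
                            burnin_blocks = 10L) {
  block_length <- as.integer(block_length)
  if (block_length < 1) stop("'block_length' must be >= 1")
  if (any(p_levels < 0 | p_levels > 1)) stop("'p_levels' must be in [0, 1]")
  structure(list(block_length = block_length, p_levels = p_levels,
                 burnin_blocks = as.integer(burnin_blocks)),
            class = "estimation_task")
}

# deterministic p_t sequence: burn-in blocks followed by one full cycle
task_p_sequence <- function(task) {
  n_cycle <- length(task$p_levels)
  n_blocks <- task$burnin_blocks + n_cycle
  levels <- task$p_levels[((seq_len(n_blocks) - 1L) %% n_cycle) + 1L]
  list(p = rep(levels, each = task$block_length),
       eval_idx = seq.int(task$burnin_blocks * task$block_length + 1L,
                          n_blocks * task$block_length))
}

# recursive filter y_t = k y_{t-1} + x_t with y_0 = init
ar1_filter <- function(x, k, init) {
  as.numeric(stats::filter(x, k, method = "recursive", init = init))
}

#' Exact bias-variance moment recursion for the two-timescale estimator
#'
#' Propagates the exact first and second moments of the two leaky integrators
#' tracking a piecewise-constant Bernoulli rate \eqn{p_t}. With learning rate
#' \eqn{a = 1/\tau}, the mean, variance and cross-covariance obey
#' \deqn{m_t = (1-a) m_{t-1} + a\, p_{t-1},}
#' \deqn{v_t = (1-a)^2 v_{t-1} + a^2 p_{t-1}(1-p_{t-1}),}
#' \deqn{c_t = (1-a_f)(1-a_s) c_{t-1} + a_f a_s\, p_{t-1}(1-p_{t-1}),}
#' and the combined estimator
#' \eqn{\hat p_t = (1-w)\, I^{fast}_t + w\, I^{slow}_t} inherits its moments
#' by bilinearity. Squared bias \eqn{(E[\hat p_t] - p_t)^2}, variance and MSE
#' are time-averaged over one full deterministic cycle of blocks after the
#' burn-in.
#'
#' @param task An [estimation_task()].
#' @param tau_fast,tau_slow Integration time constants (trials).
#' @param w_slow Weight of the slow integrator, in `[0, 1]`.
#' @return A list with `bias2`, `variance`, `mse` (all time-averaged;
#'   `mse = bias2 + variance` exactly).
#' @export
moment_recursion <- function(task, tau_fast = 5, tau_slow = 1000, w_slow) {
  stopifnot(inherits(task, "estimation_task"))
  if (tau_fast < 1 || tau_slow < 1) stop("time constants must be >= 1")
  if (w_slow < 0 || w_slow > 1) stop("'w_slow' must be in [0, 1]")
  af <- 1 / tau_fast
  as_ <- 1 / tau_slow
  seqs <- task_p_sequence(task)
  p <- seqs$p
  n <- length(p)
  p0 <- mean(task$p_levels)
  # inputs indexed so that moment at t uses p_{t-1}
  p_in <- c(p0, p[-n])
  q_in <- p_in * (1 - p_in)
  mf <- ar1_filter(af * p_in, 1 - af, p0)
  ms <- ar1_filter(as_ * p_in, 1 - as_, p0)
  vf <- ar1_filter(af^2 * q_in, (1 - af)^2, 0)
  vs <- ar1_filter(as_^2 * q_in, (1 - as_)^2, 0)
  cc <- ar1_filter(af * as_ * q_in, (1 - af) * (1 - as_), 0)
  w <- w_slow
  m_hat <- (1 - w) * mf + w * ms
  v_hat <- (1 - w)^2 * vf + w^2 * vs + 2 * w * (1 - w) * cc
  idx <- seqs$eval_idx
  bias2 <- mean((m_hat[idx] - p[idx])^2)
  variance <- mean(v_hat[idx])
  list(bias2 = bias2, variance = variance, mse = bias2 + variance)
}

#' Sweep the slow-integrator weight of the estimation task
#'
#' Evaluates [moment_recursion()] on a grid of `w_slow` values and locates the
#' MSE-minimizing weight. The bias-variance tradeoff appears as a variance
#' that decreases, and a squared bias that increases, with `w_slow`; their sum
#' has an interior minimum whose location moves toward larger `w_slow` in more
#' stable environments (longer blocks).
#'
#' @param task An [estimation_task()].
#' @param tau_fast,tau_slow Time constants.
#' @param grid Weights to evaluate (default 51 points on `[0, 1]`).
#' @return A data frame of class `bias_variance_curve` with columns `w_slow`,
#'   `bias2`, `variance`, `mse`; the MSE-minimizing weight is stored in
#'   attribute `argmin`.
#' @export
sweep_weights <- function(task, tau_fast = 5, tau_slow = 1000,
                          grid = seq(0, 1, length.out = 51)) {
  if (length(grid) == 0) stop("'grid' must be non-empty")
  rows <- lapply(grid, function(w) {
    r <- moment_recursion(task, tau_fast, tau_slow, w)
    data.frame(w_slow = w, bias2 = r$bias2, variance = r$variance, mse = r$mse)
  })
  out <- do.call(rbind, rows)
  attr(out, "argmin") <- out$w_slow[which.min(out$mse)]
  class(out) <- c("bias_variance_curve", "data.frame")
  out
}

#' Monte Carlo check of the estimator moments
#'
#' Simulates the two-filter estimator on the task's Bernoulli reward stream
#' and returns the empirically time-averaged squared bias, variance, and MSE,
#' with standard errors over runs. Serves as the stochastic cross-check of
#' [moment_recursion()].
#'
#' @param task An [estimation_task()].
#' @param tau_fast,tau_slow,w_slow As in [moment_recursion()].
#' @param n_runs Number of independent runs.
#' @return A list with `bias2`, `variance`, `mse` and standard errors
#'   `se_bias2`, `se_variance`, `se_mse`.
#' @export
monte_carlo_moments <- function(task, tau_fast = 5, tau_slow = 1000, w_slow,
                                n_runs = 1000L) {
  seqs <- task_p_sequence(task)
  p <- seqs$p
  n <- length(p)
  idx <- seqs$eval_idx
  af <- 1 / tau_fast
  as_ <- 1 / tau_slow
  p0 <- mean(task$p_levels)
  est <- matrix(0, nrow = n_runs, ncol = length(idx))
  for (run in seq_len(n_runs)) {
    r <- as.numeric(stats::runif(n) < p)
    r_in <- c(0, r[-n])          # estimator at t sees rewards up to t-1
    If <- ar1_filter(af * r_in, 1 - af, p0)
    Is <- ar1_filter(as_ * r_in, 1 - as_, p0)
    est[run, ] <- ((1 - w_slow) * If + w_slow * Is)[idx]
  }
  m <- colMeans(est)
  v_t <- apply(est, 2, stats::var)
  b2_t <- (m - p[idx])^2
  mse_run <- rowMeans(sweep(est, 2, p[idx])^2)
  list(bias2 = mean(b2_t), variance = mean(v_t),
       mse = mean(mse_run),
       se_mse = stats::sd(mse_run) / sqrt(n_runs),
       se_variance = mean(v_t) * sqrt(2 / (n_runs - 1)),
       se_bias2 = 2 * sqrt(mean(b2_t) * mean(v_t) / n_runs))
}

#' Behavioral sweep of the slow-integrator weight on the foraging task
#'
#' Simulates the two-timescale agent on the full concurrent-VI schedule for a
#' grid of slow weights (one independently generated schedule per weight, from
#' a common seed sequence so sweeps are reproducible) and returns the
#' block-wise matching slope, the square-root variance of choice, and the
#' harvesting efficiency at each weight. Reproduces the behavioral face of the
#' bias-variance tradeoff: slope falls with `w_slow`, choice variance falls
#' with `w_slow`, and efficiency takes an inverted-U shape with an interior
#' maximum.
#'
#' @param config A [schedule_config()].
#' @param w_grid Slow-integrator weights to simulate.
#' @param tau_fast,tau_slow Time constants (trials).
#' @param last_n Trials per block entering the matching fit (default 50).
#' @return A data frame with columns `w_slow`, `slope`, `undermatching`,
#'   `sqrt_variance`, `efficiency`.
#' @export
matching_slope_vs_weight <- function(config, w_grid = seq(0, 1, by = 0.1),
                                     tau_fast = 5, tau_slow = 10000,
                                     last_n = 50L) {
  rows <- lapply(w_grid, function(w) {
    agent <- integrator_agent(taus = c(tau_fast, tau_slow),
                              weights = c(1 - w, w),
                              initial_income = config$total_bait_rate / 2)
    sched <- generate_schedule(config)
    ses <- run_session(agent, sched)
    fit <- fit_matching(block_summaries(ses, last_n = last_n))
    vc <- variance_of_choice(ses)
    data.frame(w_slow = w, slope = fit$slope,
               undermatching = fit$undermatching,
               sqrt_variance = vc$sqrt_variance,
               efficiency = as.numeric(harvesting_efficiency(ses)))
  })
  do.call(rbind, rows)
}
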
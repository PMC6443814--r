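#' Fitting configuration
#'
#' Parameters of the per-session maximum-likelihood fit of the integrator
#' weights. Time constants are fixed (by default 2, 20, and 1000 trials —
#' two timescales shorter than a typical block and one much longer); only the
#' simplex weights are estimated, via a softmax reparameterization optimized
#' by BFGS with random restarts.
#'
#' @param taus Strictly increasing time constants (trials).
#' @param restarts Number of optimizer starts (the first at the uniform
#'   weights, the rest random).
#' @param reltol Optimizer convergence tolerance.
#' @param carryover Initialize each session's slow integrator at the previous
#'   session's final slow income (fast integrators always restart)?
#' @param initial_income Starting income per target per timescale (first
#'   session, and every session for the fast integrators).
#' @param free_only Score only free choices (switch pairs collapsed)?
#' @param eps Probability clipping bound inside the likelihood.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(taus = c(2, 20, 1000), restarts = 5L, reltol = 1e-8,
                       carryover = TRUE, initial_income = 0.175,
                       free_only = TRUE, eps = 1e-6) {
  taus <- as.numeric(taus)
  if (any(diff(taus) <= 0)) stop("'taus' must be strictly increasing")
  if (any(taus < 1)) stop("'taus' must be >= 1")
  restarts <- as.integer(restarts)
  if (restarts < 1) stop("'restarts' must be >= 1")
  structure(list(taus = taus, restarts = restarts, reltol = reltol,
                 carryover = isTRUE(carryover),
                 initial_income = initial_income,
                 free_only = isTRUE(free_only), eps = eps),
            class = "fit_config")
}

# per-timescale income trajectories for both targets, one column per tau;
# row t is the income available before trial t's choice (uses r up to t-1)
income_trajectories <- function(session, taus, init_g, init_r) {
  n <- nrow(session)
  rg <- as.numeric(session$reward == 1 & session$choice == "G")
  rr <- as.numeric(session$reward == 1 & session$choice == "R")
  m <- length(taus)
  Ig <- matrix(0, n + 1L, m)
  Ir <- matrix(0, n + 1L, m)
  for (j in seq_len(m)) {
    a <- 1 / taus[j]
    Ig[, j] <- c(init_g[j], ar1_filter(a * rg, 1 - a, init_g[j]))
    Ir[, j] <- c(init_r[j], ar1_filter(a * rr, 1 - a, init_r[j]))
  }
  list(Ig = Ig, Ir = Ir)
}

#' Log-likelihood of a session under the multi-timescale model
#'
#' Forward-filters the session's delivered rewards through one leaky
#' integrator per timescale and target, combines them with the given simplex
#' weights, and scores the (by default free) choices under the local matching
#' rule with Bernoulli likelihood. Choice probabilities are clipped to
#' `[eps, 1 - eps]` to keep the log-likelihood finite.
#'
#' @param session A `session_data` object.
#' @param weights Simplex weights, one per time constant.
#' @param taus Time constants (trials).
#' @param initial_incomes List with numeric vectors `g` and `r` (one entry per
#'   timescale), or a single number used for all.
#' @param free_only Score free choices only (default `TRUE`).
#' @param eps Clipping bound.
#' @return The log-likelihood (scalar, `<= 0`).
#' @export
session_log_likelihood <- function(session, weights, taus,
                                   initial_incomes = 0.175,
                                   free_only = TRUE, eps = 1e-6) {
  stopifnot(inherits(session, "session_data"))
  if (nrow(session) == 0) stop("empty session")
  if (length(weights) != length(taus))
    stop("one weight per time constant required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must lie on the simplex")
  ii <- normalize_initial_incomes(initial_incomes, length(taus))
  tr <- income_trajectories(session, taus, ii$g, ii$r)
  ll_from_trajectories(tr, session, weights, free_only, eps)
}

normalize_initial_incomes <- function(initial_incomes, m) {
  if (is.list(initial_incomes))
    list(g = rep_len(initial_incomes$g, m), r = rep_len(initial_incomes$r, m))
  else
    list(g = rep_len(initial_incomes, m), r = rep_len(initial_incomes, m))
}

ll_from_trajectories <- function(tr, session, weights, free_only, eps) {
  n <- nrow(session)
  ig <- drop(tr$Ig[seq_len(n), , drop = FALSE] %*% weights)
  ir <- drop(tr$Ir[seq_len(n), , drop = FALSE] %*% weights)
  tot <- ig + ir
  pg <- ifelse(tot > 0, ig / tot, 0.5)
  pg <- pmin(pmax(pg, eps), 1 - eps)
  keep <- if (free_only) session$free_choice else rep(TRUE, n)
  chose_g <- session$choice == "G"
  sum(log(ifelse(chose_g, pg, 1 - pg))[keep])
}

softmax_weights <- function(theta) {
  z <- exp(c(0, theta) - max(0, theta))
  z / sum(z)
}

#' Fit the integrator weights of one session by maximum likelihood
#'
#' Maximizes the session log-likelihood over the weight simplex using a
#' softmax reparameterization (m - 1 unconstrained parameters) and BFGS with
#' multiple restarts. Degenerate sessions in which every scored choice is the
#' same color carry no information about the weights; these return a flagged
#' boundary result rather than an error, as does failure to converge at every
#' restart.
#'
#' @param session A `session_data` object.
#' @param config A [fit_config()].
#' @param carryover_income Optional list with vectors `g` and `r`: the slow
#'   integrator's initial incomes inherited from the previous session (only
#'   the last — slowest — entry is used; fast integrators restart at
#'   `config$initial_income`).
#' @return An object of class `fit_result`: weights (named `w_1..w_m`, slow
#'   weight last), `loglik`, `converged`, `flagged`, `final_slow_income`
#'   (list `g`, `r`) for chaining, and `n_scored`.
#' @export
fit_session <- function(session, config = fit_config(),
                        carryover_income = NULL) {
  stopifnot(inherits(session, "session_data"))
  m <- length(config$taus)
  init_g <- rep(config$initial_income, m)
  init_r <- rep(config$initial_income, m)
  if (config$carryover && !is.null(carryover_income)) {
    init_g[m] <- carryover_income$g
    init_r[m] <- carryover_income$r
  }
  tr <- income_trajectories(session, config$taus, init_g, init_r)
  scored <- if (config$free_only) session$free_choice else rep(TRUE, nrow(session))
  degenerate <- length(unique(session$choice[scored])) < 2
  negll <- function(theta) {
    -ll_from_trajectories(tr, session, softmax_weights(theta),
                          config$free_only, config$eps)
  }
  best <- NULL
  any_converged <- FALSE
  for (k in seq_len(config$restarts)) {
    theta0 <- if (k == 1) rep(0, m - 1) else stats::rnorm(m - 1, 0, 2)
    opt <- tryCatch(
      stats::optim(theta0, negll, method = "BFGS",
                   control = list(reltol = config$reltol, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) any_converged <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed at every restart")
  w <- softmax_weights(best$par)
  names(w) <- paste0("w_", seq_len(m))
  n <- nrow(session)
  structure(list(weights = w,
                 loglik = -best$value,
                 converged = any_converged,
                 flagged = degenerate || !any_converged,
                 final_slow_income = list(g = tr$Ig[n + 1L, m],
                                          r = tr$Ir[n + 1L, m]),
                 n_scored = sum(scored),
                 taus = config$taus),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Session fit (taus:", paste(x$taus, collapse = ", "), "trials)\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat(sprintf("  logLik: %.2f over %d choices%s\n", x$loglik, x$n_scored,
              if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}

#' Fit every session of a dataset sequentially
#'
#' Sessions are fit independently except that, with carryover enabled, the
#' slow integrator of each fit starts at the final slow income of the
#' previous session's fit. The per-session fitted slow weight is joined with
#' the session's undermatching (computed over the last `last_n` trials of
#' each block), and their correlation is tested with the conservative
#' block permutation test.
#'
#' @param dataset A `foraging_dataset` (list of `session_data`, in time
#'   order).
#' @param config A [fit_config()].
#' @param last_n Trials per block for the undermatching join (default 50).
#' @param n_perm Permutations for the correlation test.
#' @return A list of class `dataset_fit`: `fits` (data frame of per-session
#'   weights, log-likelihoods, flags, and undermatching), `correlation`
#'   (fitted slow weight vs undermatching, complete sessions), `p_value`.
#' @export
fit_dataset <- function(dataset, config = fit_config(), last_n = 50L,
                        n_perm = 1000L) {
  carry <- NULL
  m <- length(config$taus)
  rows <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    ses <- dataset[[i]]
    fit <- fit_session(ses, config, carryover_income = carry)
    carry <- fit$final_slow_income
    um <- tryCatch(fit_matching(block_summaries(ses, last_n = last_n))$undermatching,
                   error = function(e) NA_real_)
    rows[[i]] <- data.frame(session = i,
                            t(fit$weights),
                            loglik = fit$loglik,
                            flagged = fit$flagged,
                            undermatching = um)
  }
  fits <- do.call(rbind, rows)
  w_slow <- fits[[paste0("w_", m)]]
  ok <- stats::complete.cases(w_slow, fits$undermatching)
  cor_obs <- NA_real_
  p <- NA_real_
  if (sum(ok) >= 10) {
    cor_obs <- stats::cor(w_slow[ok], fits$undermatching[ok])
    p <- piecewise_permutation_test(w_slow[ok], fits$undermatching[ok],
                                    n_perm = n_perm)
  }
  structure(list(fits = fits, correlation = cor_obs, p_value = p),
            class = "dataset_fit")
}
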
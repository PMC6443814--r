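#' Block-wise choice and reward fractions
#'
#' For each block of a session, computes the fraction of free choices
#' allocated to green and the fraction of all delivered rewards collected from
#' green — the two coordinates of the block-wise matching plot. Restricting to
#' the last `last_n` trials of each block ignores the transient after an
#' unsignalled ratio change. Blocks with no rewards or no free choices in the
#' analysis window are dropped (their fractions are undefined).
#'
#' @param session A `session_data` object.
#' @param last_n Use only the last `last_n` trials of each block, or `NULL`
#'   for all trials.
#' @return A data frame with one row per retained block: `block`,
#'   `choice_fraction`, `reward_fraction`, `n_free_choices`, `n_rewards`.
#' @export
block_summaries <- function(session, last_n = NULL) {
  stopifnot(inherits(session, "session_data"))
  blocks <- unique(session$block)
  out <- lapply(blocks, function(b) {
    idx <- which(session$block == b)
    if (!is.null(last_n) && length(idx) > last_n)
      idx <- idx[(length(idx) - last_n + 1L):length(idx)]
    sub <- session[idx, ]
    free <- sub[sub$free_choice, ]
    n_free <- nrow(free)
    n_rew <- sum(sub$reward)
    if (n_free == 0 || n_rew == 0) return(NULL)
    data.frame(block = b,
               choice_fraction = mean(free$choice == "G"),
               reward_fraction = sum(sub$reward[sub$choice == "G"]) / n_rew,
               n_free_choices = n_free,
               n_rewards = n_rew)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fit the block-wise matching regression
#'
#' Ordinary least squares of block choice fraction on block reward fraction.
#' The matching law corresponds to a unit slope; the slope deficit
#' `1 - slope` quantifies undermatching, and the fitted line's value at a
#' reward fraction of 0.5, minus 0.5, is the color choice bias (a horizontal
#' offset independent of the slope).
#'
#' @param blocks A data frame from [block_summaries()], possibly pooled over
#'   sessions.
#' @param min_rewards Blocks with fewer rewards than this are excluded to
#'   limit leverage from extreme, poorly-estimated reward fractions.
#'   Default 5.
#' @return An object of class `matching_fit`: a list with `slope`,
#'   `intercept`, `undermatching`, `color_choice_bias`, `n_blocks`.
#' @export
fit_matching <- function(blocks, min_rewards = 5L) {
  if (is.null(blocks) || nrow(blocks) == 0) stop("no blocks to fit")
  blocks <- blocks[blocks$n_rewards >= min_rewards, , drop = FALSE]
  if (nrow(blocks) < 3)
    stop("need at least 3 blocks with >= ", min_rewards, " rewards")
  if (stats::var(blocks$reward_fraction) == 0)
    stop("reward fractions have zero variance; matching slope undefined")
  fit <- stats::lm(choice_fraction ~ reward_fraction, data = blocks)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(slope = slope,
                 intercept = intercept,
                 undermatching = 1 - slope,
                 color_choice_bias = intercept + 0.5 * slope - 0.5,
                 n_blocks = nrow(blocks)),
            class = "matching_fit")
}

#' @export
print.matching_fit <- function(x, ...) {
  cat("Block-wise matching fit (", x$n_blocks, " blocks)\n", sep = "")
  cat(sprintf("  slope:            %.3f\n", x$slope))
  cat(sprintf("  undermatching:    %.3f\n", x$undermatching))
  cat(sprintf("  color choice bias:% .3f\n", x$color_choice_bias))
  invisible(x)
}

#' Harvesting efficiency of a session
#'
#' Rewards actually obtained divided by the maximum number that could have
#' been collected. Because baits never expire, an ideal harvester that always
#' takes a baited target collects every bait the schedule arms, and arming is
#' only paused on the rare trials when a target is already waiting; the
#' maximum collectable over `n` trials is therefore `total_bait_rate * n` up
#' to edge effects, and that product is used as the denominator. (The count
#' of baits the schedule actually armed during the agent's own session is not
#' usable here: baiting is agent-dependent — an armed target stays armed, and
#' is not re-armed, until chosen — so assigned baits equal delivered rewards
#' plus at most one pending bait per target, for any agent.) The ratio is
#' clipped to `[0, 1]`.
#'
#' @param session A `session_data` object carrying a `total_bait_rate`
#'   attribute (written by [run_session()] and preserved by the CSV round
#'   trip).
#' @param total_bait_rate Override for the schedule's total baiting rate, for
#'   external data without the attribute.
#' @return Efficiency in `[0, 1]`.
#' @export
harvesting_efficiency <- function(session, total_bait_rate = NULL) {
  stopifnot(inherits(session, "session_data"))
  rate <- if (!is.null(total_bait_rate)) total_bait_rate else
    attr(session, "total_bait_rate")
  if (is.null(rate)) stop("session does not record the total baiting rate")
  denom <- rate * nrow(session)
  if (denom <= 0) stop("zero trials; efficiency undefined")
  min(1, sum(session$reward) / denom)
}

# causal half-Gaussian smoothing; kernel renormalized over the available past
half_gaussian_smooth <- function(x, sigma, span) {
  n <- length(x)
  k <- 0:(span - 1L)
  w <- exp(-k^2 / (2 * sigma^2))
  num <- stats::filter(x, w, sides = 1)
  den <- stats::filter(rep(1, n), w, sides = 1)
  out <- as.numeric(num / den)
  head_n <- min(span - 1L, n)
  for (t in seq_len(head_n)) {
    wt <- w[seq_len(t)]
    out[t] <- sum(wt * x[t:1]) / sum(wt)
  }
  out
}

#' Variance of choice
#'
#' The binary free-choice series (green = 1) is smoothed with two causal
#' half-Gaussian kernels, a fast one (sd `sigma_fast` trials) giving a local
#' estimate of the choice probability and a slow one (sd `sigma_slow`) giving
#' its block-scale average; both kernels span `span` past trials and are
#' normalized to unit sum. The variance of choice is the mean squared distance
#' between the two smoothed series; its square root is reported alongside for
#' display.
#'
#' @param session A `session_data` object with more free choices than `span`.
#' @param sigma_fast,sigma_slow Kernel standard deviations in trials
#'   (defaults 8 and 50).
#' @param span Kernel truncation in past trials (default 200).
#' @return A list of class `choice_variance` with `variance`,
#'   `sqrt_variance`, and the parameters.
#' @export
variance_of_choice <- function(session, sigma_fast = 8, sigma_slow = 50,
                               span = 200L) {
  stopifnot(inherits(session, "session_data"))
  x <- as.numeric(session$choice[session$free_choice] == "G")
  if (length(x) <= span)
    stop("session has ", length(x), " free choices; need more than ", span)
  fast <- half_gaussian_smooth(x, sigma_fast, span)
  slow <- half_gaussian_smooth(x, sigma_slow, span)
  v <- mean((fast - slow)^2)
  structure(list(variance = v, sqrt_variance = sqrt(v),
                 sigma_fast = sigma_fast, sigma_slow = sigma_slow,
                 span = span),
            class = "choice_variance")
}

#' Color reward imbalance
#'
#' `(R_G - R_R) / N`: the difference between the numbers of rewards collected
#' from green and from red, normalized by the number of trials. Computable for
#' one session or pooled over any window of sessions.
#'
#' @param sessions A `session_data` object or a list of them.
#' @return The imbalance (between `-rate` and `+rate`).
#' @export
color_reward_imbalance <- function(sessions) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  rg <- sum(vapply(sessions, function(s) sum(s$reward[s$choice == "G"]), numeric(1)))
  rr <- sum(vapply(sessions, function(s) sum(s$reward[s$choice == "R"]), numeric(1)))
  n <- sum(vapply(sessions, nrow, numeric(1)))
  if (n == 0) stop("no trials; imbalance undefined")
  (rg - rr) / n
}

#' Per-session summary statistics
#'
#' Computes the model-independent statistics for one session: the block-wise
#' matching fit (slope, undermatching, color choice bias), harvesting
#' efficiency, variance of choice, and color reward imbalance. Statistics that
#' cannot be computed for a given session (too few blocks, too short a series)
#' are reported as `NA`.
#'
#' @param session A `session_data` object.
#' @param last_n Trials per block used in the matching fit (default 50, which
#'   skips post-change transients); `NULL` for all.
#' @param min_rewards Passed to [fit_matching()].
#' @return A one-row data frame.
#' @export
session_summary <- function(session, last_n = 50L, min_rewards = 5L) {
  stopifnot(inherits(session, "session_data"))
  fit <- tryCatch(fit_matching(block_summaries(session, last_n = last_n),
                               min_rewards = min_rewards),
                  error = function(e) NULL)
  vc <- tryCatch(variance_of_choice(session), error = function(e) NULL)
  eff <- tryCatch(as.numeric(harvesting_efficiency(session)),
                  error = function(e) NA_real_)
  data.frame(day = session$day[1], session = session$session[1],
             n_trials = nrow(session),
             n_free_choices = sum(session$free_choice),
             slope = if (is.null(fit)) NA_real_ else fit$slope,
             undermatching = if (is.null(fit)) NA_real_ else fit$undermatching,
             color_choice_bias = if (is.null(fit)) NA_real_ else fit$color_choice_bias,
             efficiency = eff,
             variance = if (is.null(vc)) NA_real_ else vc$variance,
             sqrt_variance = if (is.null(vc)) NA_real_ else vc$sqrt_variance,
             imbalance = color_reward_imbalance(session),
             break_before = {
               b <- attr(session, "break_before")
               if (is.null(b)) NA_real_ else as.numeric(b)
             })
}

#' Summarize every session of a dataset
#'
#' @param dataset A `foraging_dataset` (list of `session_data`).
#' @param ... Passed to [session_summary()].
#' @return A data frame with one row per session, in chronological order.
#' @export
summarize_sessions <- function(dataset, ...) {
  do.call(rbind, lapply(dataset, session_summary, ...))
}
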
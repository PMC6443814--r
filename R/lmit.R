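#' LMIT configuration
#'
#' Parameters of the longest-measurable-integration-timescale analysis: a
#' sliding reference window of sessions, a set of non-positive session lags, a
#' geometric weighting of the lagged correlations in the line fit (small lags
#' are estimated from more overlapping data and are more reliable), and the
#' exclusion of the earliest sessions to discard training effects.
#'
#' @param window Reference window length in sessions (default 25).
#' @param max_lag Largest lag into the past, in sessions (default 5; lags
#'   `0..max_lag` are used).
#' @param gamma Geometric weight base for lag `i` (weight `gamma^i`,
#'   default 0.5).
#' @param exclude_first Sessions dropped from the start of the series
#'   (default 25).
#' @param smooth_windows Moving-average span, in windows, for display
#'   smoothing of the LMIT trajectory (default 10).
#' @return An object of class `lmit_config`.
#' @export
lmit_config <- function(window = 25L, max_lag = 5L, gamma = 0.5,
                        exclude_first = 25L, smooth_windows = 10L) {
  window <- as.integer(window)
  max_lag <- as.integer(max_lag)
  if (gamma <= 0 || gamma > 1) stop("'gamma' must be in (0, 1]")
  if (window <= max_lag) stop("'window' must exceed 'max_lag'")
  structure(list(window = window, max_lag = max_lag, gamma = gamma,
                 exclude_first = as.integer(exclude_first),
                 smooth_windows = as.integer(smooth_windows)),
            class = "lmit_config")
}

#' Lagged correlations between color choice bias and color reward imbalance
#'
#' For a reference window of sessions starting at `start`, computes the
#' Pearson correlation between the window's per-session color choice biases
#' and the per-session color reward imbalances shifted `i` sessions into the
#' past, for each lag `i`. A positive correlation at lag `i` means a reward
#' imbalance still influences choice bias `i` sessions later.
#'
#' @param bias_series Per-session color choice bias.
#' @param imbalance_series Per-session color reward imbalance (same length).
#' @param start First session index of the reference window.
#' @param window Window length in sessions.
#' @param lags Non-negative integer lags (sessions into the past).
#' @return Named numeric vector of correlations, one per lag (`NA` where a
#'   window has zero variance).
#' @export
lagged_correlations <- function(bias_series, imbalance_series, start,
                                window = 25L, lags = 0:5) {
  n <- length(bias_series)
  if (length(imbalance_series) != n)
    stop("series must be aligned by session index")
  if (start - max(lags) < 1 || start + window - 1 > n)
    stop("window does not fit within the series for all lags")
  idx <- start:(start + window - 1L)
  b <- bias_series[idx]
  out <- vapply(lags, function(i) {
    im <- imbalance_series[idx - i]
    ok <- stats::complete.cases(b, im)
    if (sum(ok) < 10 || stats::sd(b[ok]) == 0 || stats::sd(im[ok]) == 0)
      return(NA_real_)
    stats::cor(b[ok], im[ok])
  }, numeric(1))
  names(out) <- paste0("lag", lags)
  out
}

#' Estimate the LMIT from a set of lagged correlations
#'
#' Fits a weighted least-squares line to the correlations as a function of
#' lag, with geometric weights `gamma^i`, and takes the lag at which the
#' fitted line crosses zero correlation as the raw maximum correlation lag.
#' Multiplied by the mean session length of the reference window, this gives
#' the longest measurable integration timescale in trials — a lower bound on
#' the slowest reward-integration timescale. Conventions for degenerate
#' fits: a negative crossing is clamped to 0; a non-negative fitted slope
#' means no measurable decay within the lag range, giving 0 when the line
#' starts at or below zero correlation and the maximum lag (flagged)
#' otherwise; crossings beyond the maximum lag are capped there and flagged.
#'
#' @param correlations Named vector from [lagged_correlations()] (at least 3
#'   non-`NA` values).
#' @param mean_session_length Mean session length (trials) of the reference
#'   window.
#' @param gamma Geometric weight base.
#' @param lags Integer lags matching `correlations`.
#' @return An object of class `lmit_result`: `correlations`, `slope`,
#'   `intercept`, `raw_lag` (sessions), `lmit` (trials), `flagged`.
#' @export
estimate_lmit <- function(correlations, mean_session_length, gamma = 0.5,
                          lags = seq_along(correlations) - 1L) {
  ok <- !is.na(correlations)
  if (sum(ok) < 3) stop("need at least 3 defined lagged correlations")
  df <- data.frame(r = correlations[ok], lag = lags[ok])
  fit <- stats::lm(r ~ lag, data = df, weights = gamma^df$lag)
  b0 <- unname(stats::coef(fit)[1])
  b1 <- unname(stats::coef(fit)[2])
  flagged <- FALSE
  if (!is.finite(b1) || b1 >= 0) {
    # line never crosses downward: no measurable decay within the lag range
    if (b0 <= 0) raw <- 0
    else { raw <- max(lags); flagged <- TRUE }
  } else {
    raw <- -b0 / b1
    if (raw < 0) raw <- 0
    if (raw > max(lags)) { raw <- max(lags); flagged <- TRUE }
  }
  structure(list(correlations = correlations, slope = b1, intercept = b0,
                 raw_lag = raw, lmit = raw * mean_session_length,
                 mean_session_length = mean_session_length,
                 flagged = flagged),
            class = "lmit_result")
}

#' @export
print.lmit_result <- function(x, ...) {
  cat(sprintf("LMIT: %.0f trials (raw lag %.2f sessions x mean length %.0f)%s\n",
              x$lmit, x$raw_lag, x$mean_session_length,
              if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}

#' Sliding-window LMIT trajectory
#'
#' Slides the reference window one session at a time over the per-session
#' summary series, estimating the LMIT at each position. The first
#' `exclude_first` sessions are excluded entirely (reference and lagged
#' windows alike), so a series of `N` sessions yields
#' `N - exclude_first - window - max_lag + 1` windows.
#'
#' @param summaries Per-session summary data frame from
#'   [summarize_sessions()] (needs columns `color_choice_bias`, `imbalance`,
#'   `n_trials`).
#' @param config An [lmit_config()].
#' @return A data frame of class `lmit_series` with one row per window:
#'   `window_start` (session index of the reference window's first session),
#'   `raw_lag`, `lmit`, `mean_session_length`, `flagged`, and `lmit_smooth`
#'   (moving average over `smooth_windows` windows, for display).
#' @export
lmit_series <- function(summaries, config = lmit_config()) {
  n <- nrow(summaries)
  lags <- 0:config$max_lag
  first <- config$exclude_first + config$max_lag + 1L
  last <- n - config$window + 1L
  if (last < first)
    stop("need at least ", config$exclude_first + config$max_lag +
           config$window, " sessions; got ", n)
  rows <- lapply(first:last, function(s) {
    r <- lagged_correlations(summaries$color_choice_bias,
                             summaries$imbalance, start = s,
                             window = config$window, lags = lags)
    if (sum(!is.na(r)) < 3) return(NULL)
    msl <- mean(summaries$n_trials[s:(s + config$window - 1L)])
    est <- estimate_lmit(r, msl, gamma = config$gamma, lags = lags)
    data.frame(window_start = s, raw_lag = est$raw_lag, lmit = est$lmit,
               mean_session_length = msl, flagged = est$flagged)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no window produced a defined correlation set")
  k <- min(config$smooth_windows, nrow(out))
  out$lmit_smooth <- as.numeric(stats::filter(out$lmit, rep(1 / k, k),
                                              sides = 1))
  class(out) <- c("lmit_series", "data.frame")
  out
}

#' Conservative piece-wise block permutation test for a correlation
#'
#' Tests the Pearson correlation between two session-indexed series against a
#' null in which blocks of `block` consecutive sessions are shuffled while
#' the order within each block is preserved. Because short-range (within
#' block) dependence survives the shuffle, the test is conservative for
#' serially correlated series.
#'
#' @param x,y Equal-length numeric series.
#' @param block Sessions per block (default 5).
#' @param n_perm Number of permutations (default 1000).
#' @return Two-sided p-value, `(1 + #\{|r*| >= |r|\}) / (n_perm + 1)`.
#' @export
piecewise_permutation_test <- function(x, y, block = 5L, n_perm = 1000L) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) series; correlation undefined")
  n_blocks <- ceiling(n / block)
  if (n_blocks < 2) stop("need at least 2 blocks")
  block_id <- rep(seq_len(n_blocks), each = block)[seq_len(n)]
  idx_by_block <- split(seq_len(n), block_id)
  r_obs <- stats::cor(x, y)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    perm <- unlist(idx_by_block[sample.int(n_blocks)], use.names = FALSE)
    if (abs(stats::cor(x[perm], y)) >= abs(r_obs)) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Correlations of the LMIT trajectory with schedule covariates
#'
#' Correlates the sliding-window LMIT with two schedule covariates evaluated
#' at each window's last session: the mean experimental-day length (trials
#' completed per day) and the mean break length, both averaged over the past
#' `past_days` experimental days. Under consolidation/forgetting dynamics,
#' longer recent days should raise the LMIT (positive correlation) and longer
#' recent breaks should lower it (negative correlation).
#'
#' @param lmit_df An `lmit_series` data frame.
#' @param summaries The per-session summaries the trajectory was computed
#'   from (needs `day`, `n_trials`, `break_before`).
#' @param config The [lmit_config()] used (for the window length).
#' @param past_days Days averaged over (default 12).
#' @param n_perm Permutations for the significance tests.
#' @return A data frame with rows `day_length` and `break_length`:
#'   `correlation`, `p_value`, `n_windows` (`NA` correlation where a
#'   covariate has zero variance).
#' @export
covariate_correlations <- function(lmit_df, summaries,
                                   config = lmit_config(), past_days = 12L,
                                   n_perm = 1000L) {
  if (!all(c("day", "n_trials", "break_before") %in% names(summaries)))
    stop("summaries must carry 'day', 'n_trials', and 'break_before' metadata")
  day_trials <- tapply(summaries$n_trials, summaries$day, sum)
  day_break <- tapply(summaries$break_before, summaries$day,
                      function(b) max(b, na.rm = TRUE))
  days <- as.integer(names(day_trials))
  recent_mean <- function(series, d) {
    keep <- days <= d & days > d - past_days
    if (!any(keep)) NA_real_ else mean(series[keep])
  }
  end_session <- lmit_df$window_start + config$window - 1L
  end_day <- summaries$day[end_session]
  mean_len <- vapply(end_day, function(d) recent_mean(day_trials, d), numeric(1))
  mean_brk <- vapply(end_day, function(d) recent_mean(day_break, d), numeric(1))
  one <- function(cov, label) {
    ok <- stats::complete.cases(lmit_df$lmit, cov)
    if (sum(ok) < 10 || stats::sd(cov[ok]) == 0 ||
        stats::sd(lmit_df$lmit[ok]) == 0)
      return(data.frame(covariate = label, correlation = NA_real_,
                        p_value = NA_real_, n_windows = sum(ok)))
    data.frame(covariate = label,
               correlation = stats::cor(lmit_df$lmit[ok], cov[ok]),
               p_value = piecewise_permutation_test(lmit_df$lmit[ok], cov[ok],
                                                    n_perm = n_perm),
               n_windows = sum(ok))
  }
  rbind(one(mean_len, "day_length"), one(mean_brk, "break_length"))
}

#' Window-averaged LMIT of one dataset
#'
#' Averages the lagged correlations over every admissible window position of
#' a per-session summary series and estimates a single LMIT from the mean
#' correlation profile. Averaging before the line fit suppresses the
#' considerable sampling noise of single 25-session windows, which otherwise
#' dominates the zero-crossing.
#'
#' @param summaries Per-session summary data frame (see [lmit_series()]).
#' @param config An [lmit_config()].
#' @return An `lmit_result` for the averaged profile.
#' @export
dataset_lmit <- function(summaries, config = lmit_config()) {
  n <- nrow(summaries)
  lags <- 0:config$max_lag
  first <- config$exclude_first + config$max_lag + 1L
  last <- n - config$window + 1L
  if (last < first)
    stop("need at least ", config$exclude_first + config$max_lag +
           config$window, " sessions; got ", n)
  acc <- vapply(first:last, function(s)
    lagged_correlations(summaries$color_choice_bias, summaries$imbalance,
                        start = s, window = config$window, lags = lags),
    numeric(length(lags)))
  rbar <- rowMeans(acc, na.rm = TRUE)
  msl <- mean(summaries$n_trials[first:n])
  estimate_lmit(rbar, msl, gamma = config$gamma, lags = lags)
}

#' LMIT as a function of the generating slow weight
#'
#' Simulates replicate multi-session datasets for each value of the slow
#' integrator's weight, estimates each dataset's window-averaged LMIT, and
#' reports the median across replicates per weight. The measurable
#' integration timescale grows with the slow weight: weakly weighted slow
#' integration leaves lagged correlations below the sampling noise, while a
#' strongly weighted one sustains them over several sessions.
#'
#' @param w_grid Slow-integrator weights to simulate.
#' @param n_replicates Datasets per weight.
#' @param n_sessions Sessions per dataset.
#' @param schedule A [schedule_config()] for each session.
#' @param taus Fast and slow time constants.
#' @param config An [lmit_config()].
#' @return A data frame with one row per weight: `w_slow`, `median_lmit`
#'   (trials), `median_raw_lag` (sessions).
#' @export
lmit_weight_sweep <- function(w_grid = c(0.1, 0.3, 0.5, 0.7),
                              n_replicates = 20L, n_sessions = 85L,
                              schedule = schedule_config(
                                n_blocks = 5L,
                                block_length_range = c(180L, 200L)),
                              taus = c(5, 1000),
                              config = lmit_config()) {
  rows <- lapply(w_grid, function(w) {
    res <- vapply(seq_len(n_replicates), function(k) {
      dc <- dataset_config(n_days = n_sessions, sessions_per_day = 1L,
                           break_lengths = 1, schedule = schedule)
      ag <- integrator_agent(taus = taus, weights = c(1 - w, w),
                            initial_income = schedule$total_bait_rate / 2)
      est <- dataset_lmit(summarize_sessions(generate_dataset(dc, ag)),
                          config)
      c(est$lmit, est$raw_lag)
    }, numeric(2))
    data.frame(w_slow = w, median_lmit = stats::median(res[1, ]),
               median_raw_lag = stats::median(res[2, ]))
  })
  do.call(rbind, rows)
}
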
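#' Write a dataset to tidy CSV with a JSON metadata sidecar
#'
#' The trial records of all sessions go to one tidy CSV (one row per trial:
#' `day, session, trial, block, choice, reward, free_choice`) and the
#' per-session metadata (bait counts, baiting rate, preceding break) to a
#' JSON sidecar next to it, so a dataset round-trips losslessly.
#'
#' @param dataset A `foraging_dataset`.
#' @param path Path of the CSV file to write; the sidecar gets the same path
#'   with extension `.meta.json`.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(dataset, path) {
  rows <- lapply(dataset, function(s)
    s[, c("day", "session", "trial", "block", "choice", "reward",
          "free_choice")])
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- lapply(dataset, function(s) list(
    session = s$session[1], day = s$day[1], n_trials = nrow(s),
    n_baits_assigned = attr(s, "n_baits_assigned"),
    total_bait_rate = attr(s, "total_bait_rate"),
    break_before = attr(s, "break_before")))
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path),
                                    ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_sessions()]
#'
#' Also accepts externally produced files in the same tabular format; when
#' the sidecar is absent, sessions are reconstructed without bait counts and
#' [harvesting_efficiency()] falls back to its rate-based denominator.
#'
#' @param path Path of the CSV file.
#' @return A `foraging_dataset`.
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "session", "trial", "block", "choice", "reward",
            "free_choice")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  meta_path <- paste0(tools::file_path_sans_ext(path), ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = FALSE) else NULL
  meta_by_session <- list()
  for (m in meta) meta_by_session[[as.character(m$session)]] <- m
  sessions <- lapply(split(df, df$session), function(s) {
    s <- s[order(s$trial), ]
    s$free_choice <- as.logical(s$free_choice)
    rownames(s) <- NULL
    m <- meta_by_session[[as.character(s$session[1])]]
    if (!is.null(m)) {
      attr(s, "n_baits_assigned") <- m$n_baits_assigned
      attr(s, "total_bait_rate") <- m$total_bait_rate
      attr(s, "break_before") <- m$break_before
    }
    class(s) <- c("session_data", "data.frame")
    s
  })
  sessions <- sessions[order(as.integer(names(sessions)))]
  structure(unname(sessions), class = "foraging_dataset")
}

default_pipeline_config <- function() {
  list(seed = 1L,
       schedule = list(total_bait_rate = 0.35, block_length_min = 100,
                       block_length_max = 200, n_blocks = 4, cod = TRUE),
       dataset = list(n_days = 20, sessions_per_day = 3, break_length = 1,
                      w_slow_start = 0.05, w_slow_end = 0.45),
       agent = list(tau_fast = 5, tau_slow = 1000),
       fit = list(taus = c(2, 20, 1000), restarts = 5),
       lmit = list(window = 25, max_lag = 5, gamma = 0.5, exclude_first = 25),
       n_perm = 500)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> metrics -> fit -> lmit deterministically for a given
#' seed: generates a multi-day dataset from a drifting-weight integrator
#' agent, writes the tidy session CSV, the per-session summary CSV, the
#' per-session fit CSV, the LMIT trajectory CSV (when the dataset is long
#' enough), and a manifest JSON listing every artifact with its MD5 content
#' hash. Rerunning with the same config and seed reproduces the manifest
#' bit-for-bit.
#'
#' @param config A nested list, or the path of a YAML file with the same
#'   structure; missing entries fall back to the package defaults (see
#'   source of `default_pipeline_config`).
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow writing into a non-empty directory?
#' @return The manifest, invisibly (named list of file MD5 hashes).
#' @export
run_pipeline <- function(config = list(), out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("'", out_dir, "' is not empty; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  sc <- config$schedule
  sched_cfg <- schedule_config(
    total_bait_rate = sc$total_bait_rate,
    block_length_range = c(sc$block_length_min, sc$block_length_max),
    n_blocks = sc$n_blocks, cod_enabled = isTRUE(sc$cod))
  dc <- config$dataset
  n_sessions <- dc$n_days * dc$sessions_per_day
  w_slow <- seq(dc$w_slow_start, dc$w_slow_end, length.out = n_sessions)
  drift <- cbind(1 - w_slow, w_slow)
  ds_cfg <- dataset_config(n_days = dc$n_days,
                           sessions_per_day = dc$sessions_per_day,
                           break_lengths = dc$break_length,
                           weight_drift = drift, schedule = sched_cfg)
  agent <- integrator_agent(taus = c(config$agent$tau_fast,
                                     config$agent$tau_slow),
                            weights = drift[1, ],
                            initial_income = sc$total_bait_rate / 2)
  dataset <- generate_dataset(ds_cfg, agent)
  sessions_csv <- file.path(out_dir, "sessions.csv")
  write_sessions(dataset, sessions_csv)

  summaries <- summarize_sessions(dataset)
  summary_csv <- file.path(out_dir, "session_summaries.csv")
  utils::write.csv(summaries, summary_csv, row.names = FALSE)

  fit <- fit_dataset(dataset, fit_config(taus = config$fit$taus,
                                         restarts = config$fit$restarts),
                     n_perm = config$n_perm)
  fits_csv <- file.path(out_dir, "session_fits.csv")
  utils::write.csv(fit$fits, fits_csv, row.names = FALSE)

  files <- c(sessions_csv,
             paste0(tools::file_path_sans_ext(sessions_csv), ".meta.json"),
             summary_csv, fits_csv)
  lc <- config$lmit
  lcfg <- lmit_config(window = lc$window, max_lag = lc$max_lag,
                      gamma = lc$gamma, exclude_first = lc$exclude_first)
  lmit_ok <- n_sessions >= lc$exclude_first + lc$max_lag + lc$window
  if (lmit_ok) {
    traj <- lmit_series(summaries, lcfg)
    lmit_csv <- file.path(out_dir, "lmit_trajectory.csv")
    utils::write.csv(traj, lmit_csv, row.names = FALSE)
    files <- c(files, lmit_csv)
  }

  scalars <- list(seed = config$seed, n_sessions = n_sessions,
                  fit_correlation_w_slow_undermatching = fit$correlation,
                  fit_correlation_p_value = fit$p_value)
  scalars_json <- file.path(out_dir, "scalars.json")
  jsonlite::write_json(scalars, scalars_json, auto_unbox = TRUE, digits = NA)
  files <- c(files, scalars_json)

  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
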
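#' TAC trial configuration
#'
#' Rules of one Target Achievement Control trial: the subject has `timeout`
#' seconds to match the target and must hold it for `dwell` consecutive
#' seconds, every activation remaining within `tolerance` of its target
#' level. The tolerance is absolute on the normalized `[0, 1]` activation
#' scale (0.2 by default; 0.25 is the relaxed variant used with an
#' amputee), the boundary is closed (an error exactly equal to the
#' tolerance still counts as in target), and the dwell is measured in whole
#' samples: `ceiling(dwell * fs)` consecutive in-target samples.
#'
#' @param timeout trial time limit in seconds (default 15).
#' @param dwell required consecutive time in target in seconds (default 1.5).
#' @param tolerance per-activation absolute band (default 0.2).
#' @param fs control-loop rate in Hz (default 100).
#' @param include_rest also require the decoder's rest channel to stay
#'   within tolerance of zero (default `FALSE`: targets are defined over
#'   the motor activations).
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(timeout = 15, dwell = 1.5, tolerance = 0.2,
                         fs = 100, include_rest = FALSE) {
  if (!(dwell > 0 && dwell <= timeout))
    stop_validation("dwell must satisfy 0 < dwell <= timeout")
  if (!(tolerance > 0 && tolerance < 1))
    stop_validation("tolerance must lie in (0, 1)")
  structure(list(timeout = timeout, dwell = dwell, tolerance = tolerance,
                 fs = fs, include_rest = include_rest),
            class = "trial_config")
}

#' Is a prediction inside the target band?
#'
#' True iff every activation named by the target -- including those
#' required to be zero -- is within `tolerance` of its target level
#' (closed boundary).
#'
#' @param pred named predicted activation vector (may include `rest`).
#' @param target a [target_spec()].
#' @param tolerance absolute per-activation band.
#' @param include_rest also compare a `rest` channel against zero.
#' @return Logical scalar.
#' @export
in_target <- function(pred, target, tolerance = 0.2, include_rest = FALSE) {
  need <- names(target$levels)
  if (include_rest && "rest" %in% names(pred)) need <- c(need, "rest")
  miss <- setdiff(need, names(pred))
  if (length(miss))
    stop_validation("prediction lacks activation(s): ",
                    paste(miss, collapse = ", "))
  ref <- c(target$levels, rest = 0)[need]
  # closed boundary, with an epsilon so that an error numerically equal to
  # the tolerance (e.g. 0.8 - 0.6 vs 0.2) still counts as in target
  all(abs(as.numeric(pred[need]) - as.numeric(ref)) <= tolerance + 1e-12)
}

# required consecutive in-target samples; the epsilon guards against
# ceiling() overshooting on dwell*fs values that are integers up to
# floating-point error (e.g. 0.07 * 100)
dwell_samples <- function(config) as.integer(ceiling(config$dwell * config$fs - 1e-9))

#' Trial metrics from an in-target trace
#'
#' Pure scoring function behind [run_trial()]: given the boolean in-target
#' flag per control sample, finds the first completion of
#' `ceiling(dwell * fs)` consecutive in-target samples. Samples after the
#' success instant never change the result. TCT is the elapsed time from
#' stimulus onset to the completing sample; TIT counts all in-target
#' samples up to the success instant (or the whole trace on failure);
#' reachability records whether the band was entered at all.
#'
#' @param flags logical vector, one entry per control sample.
#' @param config a [trial_config()].
#' @return A list with `success`, `tct` (NA on failure), `tit`,
#'   `reachable`, `n_dwell`, `end_sample`.
#' @export
trial_metrics <- function(flags, config = trial_config()) {
  n_dwell <- dwell_samples(config)
  n_max <- round(config$timeout * config$fs)
  flags <- as.logical(flags)[seq_len(min(length(flags), n_max))]
  success_at <- NA_integer_
  if (length(flags)) {
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= n_dwell)
    if (length(hit)) {
      k <- hit[1]
      success_at <- ends[k] - r$lengths[k] + n_dwell  # completing sample
    }
  }
  success <- !is.na(success_at)
  upto <- if (success) seq_len(success_at) else seq_along(flags)
  list(success = success,
       tct = if (success) success_at / config$fs else NA_real_,
       tit = sum(flags[upto]) / config$fs,
       reachable = any(flags),
       n_dwell = n_dwell,
       end_sample = if (success) success_at else length(flags))
}

#' Run one closed-loop TAC trial
#'
#' Simulates the full loop at the control rate: subject step (driven by the
#' decoder feedback), frame rendering, causal low-pass filtering, feature
#' extraction, ridge prediction, target check. The trial succeeds at the
#' first completion of the dwell and is truncated there (or at the
#' timeout). Deterministic given `seed` and the sensor seed.
#'
#' @param model a [fit_ridge()] decoder.
#' @param subject a [subject_model()].
#' @param target a [target_spec()].
#' @param templates an [action_templates()].
#' @param sensor a [sensor_model()].
#' @param config a [trial_config()].
#' @param seed integer seed for the subject's motor noise.
#' @param t0 session-clock time of the first sample (drift continuity).
#' @param cutoff_hz,order low-pass filter parameters.
#' @param roi_lambda ROI plane-fit penalty when the model uses `"roig"`
#'   features.
#' @return An object of class `trial_result`: `success`, `tct`, `tit`,
#'   `reachable`, `trajectory` (per-sample predicted activations), `flags`,
#'   `target`, `method`, `duration`.
#' @export
run_trial <- function(model, subject, target, templates, sensor,
                      config = trial_config(), seed = 1, t0 = 0,
                      cutoff_hz = 1, order = 1, roi_lambda = 1) {
  fs <- config$fs
  n_max <- round(config$timeout * fs)
  n_dwell <- dwell_samples(config)
  lp <- lowpass_coefs(cutoff_hz, fs, order)
  M <- if (model$method == "roig") roig_transform(lambda = roi_lambda)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  st <- subject_state(subject, target)
  feedback <- setNames(numeric(model$d), model$activations)
  preds <- matrix(NA_real_, nrow = n_max, ncol = model$d,
                  dimnames = list(NULL, model$activations))
  flags <- logical(n_max)
  fstate <- NULL
  consec <- 0L
  k_end <- n_max
  for (k in seq_len(n_max)) {
    step <- simulate_subject_step(subject, st, target, feedback)
    st <- step$state
    t <- t0 + (k - 1) / fs
    frame <- render_frame(templates, step$activation, sensor, t)
    fstate <- if (is.null(fstate)) filter_state(lp, x0 = as.numeric(frame))
              else filter_step(fstate, as.numeric(frame))
    x <- clamp01(fstate$y)
    feats <- if (is.null(M)) x else as.numeric(M %*% x)
    pred <- predict(model, feats)
    preds[k, ] <- pred
    feedback <- pred
    flags[k] <- in_target(pred, target, config$tolerance,
                          config$include_rest)
    consec <- if (flags[k]) consec + 1L else 0L
    if (consec >= n_dwell) { k_end <- k; break }
  }
  m <- trial_metrics(flags[seq_len(k_end)], config)
  structure(list(success = m$success, tct = m$tct, tit = m$tit,
                 reachable = m$reachable,
                 trajectory = preds[seq_len(k_end), , drop = FALSE],
                 flags = flags[seq_len(k_end)],
                 target = target, method = model$method,
                 duration = k_end / fs),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s [%s, %s]: %s; tct = %s s, tit = %.2f s%s\n",
              x$target$name, x$target$group, x$method,
              if (x$success) "success" else "failure",
              if (x$success) sprintf("%.2f", x$tct) else "-", x$tit,
              if (!x$success && x$reachable) " (reached)" else ""))
  invisible(x)
}

#' Run a full simulated TAC session
#'
#' Reproduces the session protocol: an initial training recording, then
#' repeated task-reaching phases with retraining in between to counter
#' drift. Each phase presents every task once per feature method, in a
#' seeded random order that alternates between the methods. The session
#' clock advances through recordings and trials so that sensor drift
#' accumulates realistically.
#'
#' @param templates an [action_templates()].
#' @param sensor a [sensor_model()].
#' @param subject a [subject_model()].
#' @param limits an [activation_limits()].
#' @param task_config task list, as from [default_task_config()].
#' @param methods feature methods alternated within each phase.
#' @param config a [trial_config()].
#' @param n_phases number of task-reaching phases (default 3).
#' @param lambda ridge regularization for the decoders.
#' @param train_protocol protocol of the initial training recording
#'   (3 repetitions by default); retraining recordings use 2 repetitions.
#' @param retrain_reps repetitions per retraining recording.
#' @param seed master seed; task orders and per-trial seeds derive from it.
#' @return An object of class `session_report` with `trials` (one row per
#'   trial) and `summary` (per method x task group aggregates); see
#'   [aggregate_trials()].
#' @export
run_session <- function(templates, sensor, subject,
                        limits = activation_limits(),
                        task_config = default_task_config(limits),
                        methods = c("raw", "roig"),
                        config = trial_config(), n_phases = 3, lambda = 1,
                        train_protocol = training_protocol(),
                        retrain_reps = 2, seed = 1) {
  seed <- as.integer(seed) %% 1000000L
  t_clock <- train_protocol$t0
  models <- list()
  record_and_train <- function(n_reps) {
    proto <- train_protocol
    proto$n_reps <- n_reps
    proto$t0 <- t_clock
    sess <- generate_training_session(templates, sensor, proto)
    t_clock <<- sess$stream$time[length(sess$stream$time)] + 1 / proto$fs
    for (m in methods)
      models[[m]] <<- train_decoder(sess, method = m, lambda = lambda)
  }
  record_and_train(train_protocol$n_reps)
  rows <- list()
  trial_no <- 0L
  for (phase in seq_len(n_phases)) {
    if (phase > 1) record_and_train(retrain_reps)
    plan <- build_task_set(limits, task_config, methods = methods,
                           seed = seed + phase)
    for (entry in plan) {
      trial_no <- trial_no + 1L
      tr <- run_trial(models[[entry$method]], subject, entry$target,
                      templates, sensor, config,
                      seed = seed * 1000L + trial_no, t0 = t_clock)
      t_clock <- t_clock + tr$duration + 1  # short gap between tasks
      rows[[trial_no]] <- data.frame(
        phase = phase, trial = trial_no, method = entry$method,
        task = entry$target$name, group = entry$target$group,
        success = tr$success, tct = tr$tct, tit = tr$tit,
        reachable = tr$reachable, duration = tr$duration)
    }
  }
  trials <- do.call(rbind, rows)
  structure(list(trials = trials, summary = aggregate_trials(trials),
                 config = config, n_phases = n_phases, seed = seed),
            class = "session_report")
}

#' Aggregate trial results into the session summary
#'
#' Pure function of the trial table: per feature method and task group
#' (plus an `all` row per method) it reports the number of trials, the
#' success rate in percent, mean and sd of TCT over successful trials only
#' (TCT is undefined for failures), mean and sd of TIT split by success and
#' failure, and the reachability percentage.
#'
#' @param trials data frame with columns `method`, `group`, `success`,
#'   `tct`, `tit`, `reachable` (as produced by [run_session()]).
#' @return A data frame, one row per method x group.
#' @export
aggregate_trials <- function(trials) {
  groups <- c(unique(trials$group), "all")
  out <- list()
  for (m in unique(trials$method)) {
    for (g in groups) {
      sub <- trials[trials$method == m &
                      (g == "all" | trials$group == g), , drop = FALSE]
      if (nrow(sub) == 0L) next
      succ <- sub[sub$success, , drop = FALSE]
      fail <- sub[!sub$success, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        method = m, group = g, n = nrow(sub),
        sr = 100 * mean(sub$success),
        tct_mean = if (nrow(succ)) mean(succ$tct) else NA_real_,
        tct_sd = if (nrow(succ) > 1) sd(succ$tct) else NA_real_,
        tit_success_mean = if (nrow(succ)) mean(succ$tit) else NA_real_,
        tit_success_sd = if (nrow(succ) > 1) sd(succ$tit) else NA_real_,
        tit_failure_mean = if (nrow(fail)) mean(fail$tit) else NA_real_,
        tit_failure_sd = if (nrow(fail) > 1) sd(fail$tit) else NA_real_,
        reachability = 100 * mean(sub$reachable))
    }
  }
  do.call(rbind, out)
}

#' @export
print.session_report <- function(x, ...) {
  cat("<session_report>", nrow(x$trials), "trials over", x$n_phases,
      "phases\n\n")
  s <- x$summary
  cat(sprintf("%-6s %-22s %3s %6s %8s %8s %7s\n",
              "method", "group", "n", "SR%", "TCT(s)", "TIT(s)", "reach%"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%-6s %-22s %3d %6.1f %8s %8s %7.1f\n",
                s$method[i], s$group[i], s$n[i], s$sr[i],
                ifelse(is.na(s$tct_mean[i]), "-",
                       sprintf("%.2f", s$tct_mean[i])),
                ifelse(is.na(s$tit_success_mean[i]), "-",
                       sprintf("%.2f", s$tit_success_mean[i])),
                s$reachability[i]))
  }
  invisible(x)
}

#' Write a session report to disk
#'
#' @param report a `session_report`.
#' @param path output path for the JSON report; the trial table is written
#'   alongside with suffix `_trials.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(summary = report$summary,
                            n_phases = report$n_phases,
                            seed = report$seed),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(report$trials,
            sub("\\.json$", "_trials.csv", path), row.names = FALSE)
  invisible(path)
}

#' Open-loop prediction error on combined-action targets
#'
#' Trains a decoder on a single-action session rendered through the given
#' sensor, then renders one steady frame per target at the combined
#' activation and measures the mean absolute error between the decoded and
#' the true motor activation levels. Used to study how the compressive /
#' saturating sensor response degrades combined actions -- most strongly
#' those including the power grasp, whose broad pattern drives many taxels
#' toward saturation.
#'
#' @param templates an [action_templates()].
#' @param sensor a [sensor_model()].
#' @param targets list of [target_spec()]s.
#' @param lambda ridge regularization.
#' @param method feature method.
#' @param protocol training protocol.
#' @param t_eval session time at which evaluation frames are rendered.
#' @return A data frame with one row per target: `task`, `group`, `mae`.
#' @export
combined_action_error <- function(templates, sensor, targets, lambda = 1,
                                  method = "raw",
                                  protocol = training_protocol(),
                                  t_eval = NULL) {
  sess <- generate_training_session(templates, sensor, protocol)
  model <- train_decoder(sess, method = method, lambda = lambda)
  if (is.null(t_eval))
    t_eval <- sess$stream$time[length(sess$stream$time)] + 1
  M <- if (method == "roig") roig_transform(lambda = 1)
  rows <- lapply(targets, function(tg) {
    frame <- render_frame(templates, tg$levels, sensor, t = t_eval)
    x <- as.numeric(frame)
    feats <- if (is.null(M)) x else as.numeric(M %*% x)
    pred <- predict(model, feats)
    data.frame(task = tg$name, group = tg$group,
               mae = mean(abs(pred[MOTOR_ACTIONS] - tg$levels)))
  })
  do.call(rbind, rows)
}
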
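#' Per-action muscle-bulge templates
#'
#' Each trained action has a repeatable spatial pattern of forearm pressure
#' produced by the bulging of the muscles that drive it. Templates are
#' smooth two-dimensional bumps (truncated Gaussians) on the unrolled
#' 8 x 36 taxel sheet (8 rows per board along the arm, 9 boards x 4 columns
#' around the circumference, with wrap-around), unit peak, centered at an
#' action-specific circumferential position. The power-grasp template is
#' deliberately broad and overlaps the flexion support, emulating the
#' interference between grasping and wrist flexion that share extrinsic
#' forearm muscles. The total rendered pressure is the activation-weighted
#' linear superposition of these patterns -- the working hypothesis that
#' lets a decoder trained on single actions predict combined ones.
#'
#' @param gains named per-action gains scaling each unit-peak pattern.
#'   Defaults keep the combined pressure of every feasible task below the
#'   sensor ceiling when the response is linear.
#' @param centers named circumferential centers (column index on the
#'   36-wide unrolled sheet).
#' @param width,row_width Gaussian standard deviations along the
#'   circumference and the row axis, per action.
#' @return An object of class `action_templates`: a list with `patterns`
#'   (5 x 288 matrix, rows = motor actions, unit peak) and `gains`.
#' @export
action_templates <- function(gains = c(power = 0.8, flexion = 0.5,
                                       extension = 0.5, pronation = 0.5,
                                       supination = 0.5),
                             centers = c(power = 8, flexion = 6,
                                         extension = 24, pronation = 15,
                                         supination = 33),
                             width = c(power = 7, flexion = 3,
                                       extension = 3, pronation = 3,
                                       supination = 3),
                             row_width = c(power = 4, flexion = 2.5,
                                           extension = 2.5, pronation = 2.5,
                                           supination = 2.5)) {
  acts <- MOTOR_ACTIONS
  stopifnot(all(acts %in% names(gains)), all(acts %in% names(centers)))
  n_circ <- N_BOARDS * N_COLS  # 36 positions around the arm
  # flattened taxel coordinates: circumferential position and row
  circ <- integer(N_TAXELS); rowpos <- integer(N_TAXELS)
  for (b in 0:(N_BOARDS - 1)) for (r in 0:(N_ROWS - 1)) for (cc in 0:(N_COLS - 1)) {
    i <- taxel_index(b, r, cc)
    circ[i] <- b * N_COLS + cc
    rowpos[i] <- r
  }
  P <- matrix(0, nrow = length(acts), ncol = N_TAXELS,
              dimnames = list(acts, taxel_names()))
  for (a in acts) {
    dc <- abs(circ - centers[[a]])
    dc <- pmin(dc, n_circ - dc)  # wrap around the bracelet
    dr <- rowpos - (N_ROWS - 1) / 2
    pat <- exp(-(dc^2 / (2 * width[[a]]^2) + dr^2 / (2 * row_width[[a]]^2)))
    pat[pat < 1e-4] <- 0  # truncate far tails
    P[a, ] <- pat / max(pat)
  }
  structure(list(patterns = P, gains = gains[acts]),
            class = "action_templates")
}

#' @export
print.action_templates <- function(x, ...) {
  cat("<action_templates>", nrow(x$patterns), "actions x", ncol(x$patterns),
      "taxels; gains:",
      paste(sprintf("%s=%.2f", names(x$gains), x$gains), collapse = ", "), "\n")
  invisible(x)
}

#' Sensor model
#'
#' Captures the non-ideal behaviour of the taxels: a monotone response from
#' pressure to normalized reading (linear, or compressive with saturation
#' toward 1, qualitatively matching the foam characteristic), additive
#' Gaussian noise, a slow per-taxel linear drift (foam memory / skin
#' elasticity), and optional loading/unloading hysteresis. Per-taxel drift
#' slopes are drawn once from the model seed.
#'
#' @param noise_sd per-taxel Gaussian noise standard deviation.
#' @param baseline rest contact pressure reading in `[0, 1)`.
#' @param response `"linear"` (reading = baseline + pressure, clamped) or
#'   `"saturating"` (compressive: `baseline + (1 - baseline) *
#'   (1 - exp(-g p)) / (1 - exp(-g))`, clamped).
#' @param sat_gain compression strength `g` of the saturating response.
#' @param drift_rate standard deviation of the per-taxel drift slope, in
#'   reading units per second.
#' @param hysteresis add a small positive offset while a taxel is unloading
#'   (stream rendering only); default off.
#' @param hysteresis_mag offset magnitude when `hysteresis` is on.
#' @param seed integer seed for the sensor's random draws (drift slopes,
#'   per-frame noise).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(noise_sd = 0.005, baseline = 0.05,
                         response = c("linear", "saturating"), sat_gain = 3,
                         drift_rate = 0, hysteresis = FALSE,
                         hysteresis_mag = 0.01, seed = 1) {
  response <- match.arg(response)
  if (noise_sd < 0 || drift_rate < 0 || baseline < 0 || baseline >= 1)
    stop_validation("invalid sensor parameters")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed) %% .Machine$integer.max)
  slopes <- rnorm(N_TAXELS, 0, 1) * drift_rate
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(noise_sd = noise_sd, baseline = baseline,
                 response = response, sat_gain = sat_gain,
                 drift_rate = drift_rate, drift_slopes = slopes,
                 hysteresis = hysteresis, hysteresis_mag = hysteresis_mag,
                 seed = as.integer(seed)),
            class = "sensor_model")
}

apply_response <- function(sensor, pressure) {
  if (sensor$response == "linear") {
    sensor$baseline + pressure
  } else {
    g <- sensor$sat_gain
    sensor$baseline + (1 - sensor$baseline) *
      (1 - exp(-g * pressure)) / (1 - exp(-g))
  }
}

frame_noise <- function(sensor, t) {
  if (sensor$noise_sd == 0) return(0)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed((sensor$seed + round(t * 1000)) %% .Machine$integer.max)
  eps <- rnorm(N_TAXELS, 0, sensor$noise_sd)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  eps
}

activation_pressure <- function(templates, activation) {
  a <- setNames(numeric(length(MOTOR_ACTIONS)), MOTOR_ACTIONS)
  known <- intersect(names(activation), c(MOTOR_ACTIONS, "rest"))
  if (length(known) != length(activation))
    stop_validation("unknown action name(s): ",
                    paste(setdiff(names(activation), c(MOTOR_ACTIONS, "rest")),
                          collapse = ", "))
  motor <- intersect(names(activation), MOTOR_ACTIONS)
  a[motor] <- as.numeric(activation[motor])
  as.numeric((a * templates$gains) %*% templates$patterns)
}

#' Render one tactile frame from an activation state
#'
#' Pressure is the linear superposition `sum_k a_k g_k pattern_k` of the
#' active templates; the sensor response, drift ramp and per-frame noise
#' are then applied and the reading clamped to `[0, 1]`. Deterministic
#' given the sensor seed and `t` (noise is seeded per frame from both).
#' The `rest` channel of an activation vector contributes no pressure; the
#' baseline contact pressure is part of the sensor response.
#'
#' @param templates an [action_templates()].
#' @param activation named activation levels in `[0, 1]` (motor actions;
#'   a `rest` entry is ignored for rendering).
#' @param sensor a [sensor_model()].
#' @param t frame time in seconds (drives drift and the noise seed).
#' @return A [tactile_frame()].
#' @export
render_frame <- function(templates, activation, sensor, t = 0) {
  p <- activation_pressure(templates, activation)
  reading <- apply_response(sensor, p) + sensor$drift_slopes * t +
    frame_noise(sensor, t)
  tactile_frame(clamp01(reading), t = t)
}

#' Render a whole activation trajectory as a stream
#'
#' Vectorized equivalent of calling [render_frame()] at each timestamp
#' (bit-identical when hysteresis is off). With hysteresis on, taxels whose
#' pressure is decreasing get a positive unloading offset.
#'
#' @param templates an [action_templates()].
#' @param activations n x k matrix of named activation columns.
#' @param times length-n vector of timestamps.
#' @param sensor a [sensor_model()].
#' @param fs sampling rate stored in the stream.
#' @return A [tactile_stream()].
#' @export
render_stream <- function(templates, activations, times, sensor, fs = 100) {
  activations <- as.matrix(activations)
  motor <- intersect(colnames(activations), MOTOR_ACTIONS)
  A <- activations[, motor, drop = FALSE]
  A <- sweep(A, 2, templates$gains[motor], "*")
  P <- A %*% templates$patterns[motor, , drop = FALSE]
  R <- apply_response(sensor, P)
  if (sensor$hysteresis && nrow(P) > 1) {
    unloading <- rbind(FALSE, diff(P) < 0)
    R <- R + sensor$hysteresis_mag * unloading
  }
  R <- R + outer(times, sensor$drift_slopes)
  if (sensor$noise_sd > 0) {
    for (i in seq_along(times))
      R[i, ] <- R[i, ] + frame_noise(sensor, times[i])
  }
  tactile_stream(times, clamp01(R), fs = fs)
}

#' Training protocol description
#'
#' One bout per listed action per repetition: a rest gap, a ramp up to the
#' stimulated level, a plateau, and a ramp down (trapezoidal stimulus). The
#' defaults (6 actions including rest, 3 repetitions, 7 s per bout) give a
#' recording of about two minutes.
#'
#' @param actions actions stimulated, in bout order; `"rest"` bouts keep
#'   all motor activations at zero.
#' @param n_reps repetitions of the full action list.
#' @param rest_s,ramp_s,plateau_s bout phase durations in seconds.
#' @param level plateau stimulus level (1 for training).
#' @param fs sampling rate in Hz.
#' @param t0 session-clock time of the first sample (lets drift accumulate
#'   across successive recordings).
#' @return A list of class `training_protocol`.
#' @export
training_protocol <- function(actions = ALL_ACTIONS, n_reps = 3, rest_s = 2,
                              ramp_s = 1, plateau_s = 3, level = 1,
                              fs = 100, t0 = 0) {
  if (length(actions) == 0L) stop_validation("empty action list")
  bad <- setdiff(actions, ALL_ACTIONS)
  if (length(bad))
    stop_validation("unknown action(s): ", paste(bad, collapse = ", "))
  if (level <= 0 || level > 1) stop_validation("level must be in (0, 1]")
  structure(list(actions = actions, n_reps = n_reps, rest_s = rest_s,
                 ramp_s = ramp_s, plateau_s = plateau_s, level = level,
                 fs = fs, t0 = t0),
            class = "training_protocol")
}

#' Generate a stimulated single-action training session
#'
#' Produces the paired tactile stream and label stream used to train the
#' decoder: one trapezoidal bout per action per repetition with rest in
#' between. The label of the stimulated action follows the stimulus
#' profile; the `rest` channel carries the complement `1 - level`, so it is
#' fully active during rest periods and fades out as an action is engaged.
#'
#' @param templates an [action_templates()].
#' @param sensor a [sensor_model()].
#' @param protocol a [training_protocol()].
#' @return A list of class `training_session` with `stream`
#'   (a [tactile_stream()]), `labels` (n x 6 matrix, columns
#'   `rest, power, flexion, extension, pronation, supination`), `bouts`
#'   (data frame: action, rep, start/end sample), and `protocol`.
#' @export
generate_training_session <- function(templates, sensor,
                                      protocol = training_protocol()) {
  fs <- protocol$fs
  nb <- function(s) round(s * fs)
  n_rest <- nb(protocol$rest_s); n_ramp <- nb(protocol$ramp_s)
  n_plat <- nb(protocol$plateau_s)
  bout_len <- n_rest + 2 * n_ramp + n_plat
  bout_profile <- c(numeric(n_rest),
                    seq(0, 1, length.out = n_ramp + 1)[-1],
                    rep(1, n_plat),
                    seq(1, 0, length.out = n_ramp + 1)[-1]) * protocol$level
  n_total <- bout_len * length(protocol$actions) * protocol$n_reps + n_rest
  labels <- matrix(0, nrow = n_total, ncol = length(ALL_ACTIONS),
                   dimnames = list(NULL, ALL_ACTIONS))
  bouts <- list()
  pos <- 0L
  for (rep_i in seq_len(protocol$n_reps)) {
    for (a in protocol$actions) {
      idx <- pos + seq_len(bout_len)
      if (a != "rest") labels[idx, a] <- bout_profile
      bouts[[length(bouts) + 1L]] <-
        data.frame(action = a, rep = rep_i, start = pos + 1L,
                   end = pos + bout_len)
      pos <- pos + bout_len
    }
  }
  labels[, "rest"] <- 1 - apply(labels[, MOTOR_ACTIONS, drop = FALSE], 1, max)
  times <- protocol$t0 + (seq_len(n_total) - 1) / fs
  stream <- render_stream(templates, labels, times, sensor, fs = fs)
  structure(list(stream = stream, labels = labels,
                 bouts = do.call(rbind, bouts), protocol = protocol),
            class = "training_session")
}

#' @export
print.training_session <- function(x, ...) {
  cat("<training_session>", nrow(x$bouts), "bouts,",
      length(x$stream$time), "samples @", x$stream$fs, "Hz\n")
  invisible(x)
}

#' Train a decoder from a training session
#'
#' The standard pipeline: causal low-pass filtering, feature extraction
#' (`"raw"` 288-dim or `"roig"` 54-dim), then closed-form ridge regression
#' onto the 6 activation channels (rest included by default).
#'
#' @param session a [generate_training_session()] result.
#' @param method `"raw"` or `"roig"`.
#' @param lambda ridge regularization (default 1).
#' @param cutoff_hz,order low-pass filter parameters.
#' @param roi_lambda ridge penalty of the ROI plane fit (default 1).
#' @param rest keep the rest channel as a 6th output (default); `FALSE`
#'   drops it (rest-as-all-zeros encoding, d = 5).
#' @return A [fit_ridge()] model.
#' @export
train_decoder <- function(session, method = c("raw", "roig"), lambda = 1,
                          cutoff_hz = 1, order = 1, roi_lambda = 1,
                          rest = TRUE) {
  method <- match.arg(method)
  filtered <- lowpass_filter(session$stream, cutoff_hz = cutoff_hz,
                             order = order)
  X <- feature_matrix(filtered, method = method, lambda = roi_lambda)
  Y <- session$labels
  if (!rest) Y <- Y[, MOTOR_ACTIONS, drop = FALSE]
  fit_ridge(X, Y, lambda = lambda, method = method)
}

#' Simulated closed-loop subject
#'
#' A stand-in for the human in the loop: at each control step the intended
#' activation moves toward the target proportionally to the per-activation
#' error between the target and the decoder feedback
#' (`intended <- intended + gain * (target - feedback) + noise`), with an
#' optional reaction delay (feedback from `delay` samples ago) and motor
#' noise. The `"sequential"` strategy ramps the involved actions one at a
#' time -- the advised tactic of executing one action of a combination
#' first, then adding the other -- holding later actions at zero until each
#' earlier one is within `seq_tolerance` of its target.
#'
#' @param gain proportional correction per control step (> 0). The default
#'   0.05 per 10 ms step (5 per second) settles in about a second against a
#'   1 Hz-filtered plant without oscillating.
#' @param motor_noise_sd per-step Gaussian motor noise.
#' @param delay reaction delay in samples (>= 0).
#' @param strategy `"simultaneous"` or `"sequential"`.
#' @param seq_tolerance per-activation band within which a sequential
#'   action counts as achieved.
#' @param seed seed tag stored with the model (trial-level seeding is done
#'   by the TAC engine).
#' @return An object of class `subject_model`.
#' @export
subject_model <- function(gain = 0.05, motor_noise_sd = 0, delay = 0,
                          strategy = c("simultaneous", "sequential"),
                          seq_tolerance = 0.1, seed = 1) {
  strategy <- match.arg(strategy)
  if (gain <= 0) stop_validation("gain must be > 0")
  if (delay < 0 || motor_noise_sd < 0)
    stop_validation("delay and motor noise must be >= 0")
  structure(list(gain = gain, motor_noise_sd = motor_noise_sd,
                 delay = as.integer(delay), strategy = strategy,
                 seq_tolerance = seq_tolerance, seed = as.integer(seed)),
            class = "subject_model")
}

#' @rdname subject_model
#' @param subject a `subject_model`.
#' @param target a [target_spec()].
#' @return `subject_state()` returns the initial mutable state (intended
#'   activation at rest, empty feedback buffer, sequential action order by
#'   decreasing target level).
#' @export
subject_state <- function(subject, target) {
  list(intended = setNames(numeric(length(MOTOR_ACTIONS)), MOTOR_ACTIONS),
       fb_queue = vector("list", 0),
       seq_order = names(sort(target$levels[target$levels > 0],
                              decreasing = TRUE)))
}

#' One control step of the simulated subject
#'
#' @param subject a [subject_model()].
#' @param state state from [subject_state()] or a previous step.
#' @param target a [target_spec()].
#' @param feedback named decoder prediction (motor activations) currently
#'   shown to the subject.
#' @return A list with `activation` (the new intended motor activation,
#'   clamped to `[0, 1]`) and `state`. Motor noise, when enabled, is drawn
#'   from the current RNG stream.
#' @export
simulate_subject_step <- function(subject, state, target, feedback) {
  fb <- setNames(numeric(length(MOTOR_ACTIONS)), MOTOR_ACTIONS)
  fb[intersect(names(feedback), MOTOR_ACTIONS)] <-
    feedback[intersect(names(feedback), MOTOR_ACTIONS)]
  # reaction delay: act on feedback from `delay` samples ago
  if (subject$delay > 0) {
    state$fb_queue <- c(state$fb_queue, list(fb))
    if (length(state$fb_queue) > subject$delay) {
      fb <- state$fb_queue[[1]]
      state$fb_queue <- state$fb_queue[-1]
    } else {
      fb <- setNames(numeric(length(MOTOR_ACTIONS)), MOTOR_ACTIONS)
    }
  }
  err <- target$levels - fb
  active <- rep(TRUE, length(MOTOR_ACTIONS))
  names(active) <- MOTOR_ACTIONS
  if (subject$strategy == "sequential" && length(state$seq_order) > 1) {
    achieved <- abs(err[state$seq_order]) <= subject$seq_tolerance
    first_open <- which(!achieved)[1]
    if (!is.na(first_open) && first_open < length(state$seq_order)) {
      later <- state$seq_order[(first_open + 1):length(state$seq_order)]
      active[later] <- FALSE
      state$intended[later] <- 0
    }
  }
  noise <- if (subject$motor_noise_sd > 0)
    rnorm(length(MOTOR_ACTIONS), 0, subject$motor_noise_sd) else 0
  upd <- state$intended + subject$gain * err + noise
  state$intended[active] <- clamp01(upd)[active]
  list(activation = state$intended, state = state)
}
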
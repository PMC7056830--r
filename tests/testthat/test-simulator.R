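test_that("templates are non-negative unit-peak patterns with distinct supports", {
  tpl <- action_templates()
  expect_equal(rownames(tpl$patterns),
               c("power", "flexion", "extension", "pronation", "supination"))
  expect_true(all(tpl$patterns >= 0))
  expect_equal(unname(apply(tpl$patterns, 1, max)), rep(1, 5))
  # supports are distinct: no two actions peak at the same taxel
  peaks <- apply(tpl$patterns, 1, which.max)
  expect_equal(anyDuplicated(peaks), 0)
  # power overlaps the flexion support (shared extrinsic muscles)
  overlap <- tpl$patterns["power", ] * tpl$patterns["flexion", ]
  expect_gt(max(overlap), 0.5)
})

test_that("rendering superposes action patterns linearly before the response", {
  tpl <- action_templates()
  sen <- ideal_sensor()
  base <- as.numeric(render_frame(tpl, c(power = 0), sen, t = 0))
  expect_equal(base, rep(sen$baseline, 288))
  # single action at level 1: baseline + gain * pattern (clamped)
  fr <- as.numeric(render_frame(tpl, c(flexion = 1), sen, t = 0))
  expect_equal(fr, unname(clamp01(sen$baseline +
                             tpl$gains[["flexion"]] * tpl$patterns["flexion", ])))
  # additivity of effects above baseline for an in-range combination
  a1 <- c(flexion = 0.4); a2 <- c(pronation = 0.5)
  f1 <- as.numeric(render_frame(tpl, a1, sen, 0)) - base
  f2 <- as.numeric(render_frame(tpl, a2, sen, 0)) - base
  f12 <- as.numeric(render_frame(tpl, c(a1, a2), sen, 0)) - base
  expect_equal(f12, f1 + f2, tolerance = 1e-12)
  expect_error(render_frame(tpl, c(wiggle = 1), sen, 0), "unknown")
})

test_that("the saturating response is monotone, compressive, and bounded", {
  sen <- sensor_model(noise_sd = 0, response = "saturating", baseline = 0.05)
  p <- seq(0, 3, by = 0.01)
  r <- tactomyo:::apply_response(sen, p)
  expect_equal(r[1], 0.05)                 # response(0) = baseline
  expect_true(all(diff(r) > 0))            # monotone
  expect_true(all(diff(diff(r)) < 1e-12))  # concave (compressive)
  expect_lt(abs(max(clamp01(r)) - 1), 1e-6)
})

test_that("streams render deterministically and match per-frame rendering", {
  tpl <- action_templates()
  sen <- sensor_model(noise_sd = 0.01, drift_rate = 1e-3, seed = 9)
  A <- matrix(runif(20 * 2, 0, 0.5), 20, 2,
              dimnames = list(NULL, c("flexion", "power")))
  tt <- (0:19) / 100
  s1 <- render_stream(tpl, A, tt, sen)
  s2 <- render_stream(tpl, A, tt, sensor_model(noise_sd = 0.01,
                                               drift_rate = 1e-3, seed = 9))
  expect_identical(s1$values, s2$values)  # bit-identical under matched seeds
  s3 <- render_stream(tpl, A, tt, sensor_model(noise_sd = 0.01,
                                               drift_rate = 1e-3, seed = 10))
  expect_false(identical(s1$values, s3$values))
  # stream rendering equals frame-by-frame rendering (hysteresis off)
  for (i in c(1, 10, 20)) {
    fr <- render_frame(tpl, A[i, ], sen, t = tt[i])
    expect_equal(unname(s1$values[i, ]), as.numeric(fr), tolerance = 1e-12)
  }
})

test_that("training sessions produce one trapezoidal bout per action per rep", {
  tpl <- action_templates()
  sen <- ideal_sensor()
  sess <- generate_training_session(tpl, sen, quick_protocol())
  expect_equal(nrow(sess$bouts), 18)  # 6 actions x 3 reps
  expect_true(all(sess$labels >= 0 & sess$labels <= 1))
  # rest channel is the complement of the stimulated level
  expect_equal(sess$labels[, "rest"],
               1 - apply(sess$labels[, -1], 1, max))
  # with zero noise and linear response, rest samples sit at baseline
  rest_rows <- which(sess$labels[, "rest"] == 1)
  expect_true(all(abs(sess$stream$values[rest_rows, ] - sen$baseline) < 1e-12))
  # plateau reaches the stimulated level
  flex_bout <- sess$bouts[sess$bouts$action == "flexion", ][1, ]
  expect_equal(max(sess$labels[flex_bout$start:flex_bout$end, "flexion"]), 1)
  expect_error(generate_training_session(tpl, sen,
                                         training_protocol(actions = character(0))),
               "empty")
})

test_that("the simulated subject settles on reachable targets", {
  sub <- subject_model(gain = 1, delay = 0)
  tg <- target_spec("mix", c(flexion = 0.6, pronation = 0.4),
                    "combined-no-power")
  st <- subject_state(sub, tg)
  # feedback equal to the target produces no movement from the fixed point
  st$intended[] <- tg$levels
  step <- simulate_subject_step(sub, st, tg, tg$levels)
  expect_equal(step$activation, tg$levels)
  # perfect decoder (feedback = intended): fixed-point iteration converges
  st <- subject_state(sub, tg)
  act <- st$intended
  for (k in 1:50) {
    step <- simulate_subject_step(sub, st, tg, act)
    st <- step$state; act <- step$activation
  }
  expect_lt(max(abs(act - tg$levels)), 1e-6)
})

test_that("the sequential strategy ramps one action at a time", {
  sub <- subject_model(gain = 0.2, strategy = "sequential",
                       seq_tolerance = 0.05)
  tg <- target_spec("combo", c(flexion = 0.8, pronation = 0.6),
                    "combined-no-power")
  st <- subject_state(sub, tg)
  act <- st$intended
  trace <- matrix(0, 60, 2, dimnames = list(NULL, c("flexion", "pronation")))
  for (k in 1:60) {
    step <- simulate_subject_step(sub, st, tg, act)
    st <- step$state; act <- step$activation
    trace[k, ] <- act[c("flexion", "pronation")]
  }
  first_ok <- which(abs(trace[, "flexion"] - 0.8) <= 0.05)[1]
  expect_gt(first_ok, 1)
  expect_true(all(trace[seq_len(first_ok - 1), "pronation"] == 0))
  expect_gt(trace[60, "pronation"], 0)
})

test_that("reaction delay defers the subject's response", {
  sub <- subject_model(gain = 1, delay = 3)
  tg <- target_spec("single", c(flexion = 0.5), "single")
  st <- subject_state(sub, tg)
  act <- st$intended
  lv <- numeric(6)
  for (k in 1:6) {
    step <- simulate_subject_step(sub, st, tg, c(flexion = 1))
    st <- step$state; act <- step$activation
    lv[k] <- act[["flexion"]]
  }
  # until the delayed feedback arrives the subject sees zeros and keeps
  # integrating toward the target; once the (too high) feedback of the
  # first steps arrives, it pushes the intent back down
  expect_equal(lv, c(0.5, 1, 1, 0.5, 0, 0))
})

test_that("drift degrades held-out predictions and retraining recovers", {
  tpl <- action_templates()
  sen <- sensor_model(noise_sd = 0, drift_rate = 2e-3, seed = 21)
  proto <- quick_protocol()
  sess <- generate_training_session(tpl, sen, proto)
  mod <- train_decoder(sess, "raw", lambda = 1)
  tg <- target_spec("flexion", c(flexion = 0.8), "single")
  err_at <- function(model, t) {
    fr <- render_frame(tpl, tg$levels, sen, t = t)
    mean(abs(predict(model, as.numeric(fr))[names(tg$levels)] - tg$levels))
  }
  t_end <- sess$stream$time[length(sess$stream$time)]
  errs <- vapply(t_end + c(10, 60, 120, 240), function(t) err_at(mod, t), 0)
  expect_true(all(diff(errs) > 0))  # drift: error grows over session time
  # retrain(replace) on fresh data recorded now reduces the error
  proto2 <- quick_protocol(t0 = t_end + 230)
  sess2 <- generate_training_session(tpl, sen, proto2)
  filt <- lowpass_filter(sess2$stream)
  mod2 <- retrain(mod, feature_matrix(filt, "raw"), sess2$labels,
                  mode = "replace")
  expect_lt(err_at(mod2, t_end + 240), errs[4])
})
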
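test_that("frame and stream validation enforce the data model", {
  expect_s3_class(zero_frame(), "tactile_frame")
  expect_length(taxel_names(), 288)
  expect_equal(taxel_index(0, 0, 0), 1L)
  expect_equal(taxel_index(8, 7, 3), 288L)
  # flattening is board-major, then row, then column
  expect_equal(taxel_index(0, 0, 3) + 1L, taxel_index(0, 1, 0))
  expect_equal(taxel_index(0, 7, 3) + 1L, taxel_index(1, 0, 0))

  expect_error(tactile_frame(numeric(287)), "288")
  expect_error(tactile_frame(rep(1.5, 288)), "\\[0, 1\\]")
  expect_error(tactile_frame(c(NA, numeric(287))), "finite")

  expect_error(tactile_stream(numeric(0), matrix(0, 0, 288)),
               "at least one frame")
  expect_error(tactile_stream(c(0, 0.01, 0.01), matrix(0, 3, 288)),
               "strictly increasing")
  expect_error(tactile_stream(c(0, 0.5), matrix(0, 2, 288)),
               "jitter")
})

test_that("frame grid view round-trips with the flattening order", {
  fr <- random_frame(42)
  g <- frame_grid(fr)
  expect_equal(dim(g), c(9, 8, 4))
  expect_equal(g[3, 5, 2], as.numeric(fr)[taxel_index(2, 4, 1)])
  expect_equal(as.numeric(tactile_frame(g)), as.numeric(fr))
})

test_that("stream CSV read/write round-trips losslessly", {
  path <- withr::local_tempfile(fileext = ".csv")
  st <- random_stream(7, n = 15)
  write_stream(st, path)
  back <- read_stream(path)
  expect_equal(back$fs, st$fs)
  expect_equal(back$values, st$values, tolerance = 1e-8)
  # re-writing the re-read stream is bit-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_stream(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("read_stream rejects malformed files with clear errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  st <- constant_stream(0, n = 3)
  write_stream(st, path)
  expect_equal(n_distinct <- nrow(read_stream(path)$values), 3)
  expect_true(all(read_stream(path)$values == 0))

  # broken header
  lines <- readLines(path)
  writeLines(c(sub("b0_r0_c0", "bogus", lines[1:3]), lines[-(1:3)]), path)
  expect_error(read_stream(path), "header")

  # repeated timestamp
  write_stream(st, path)
  lines <- readLines(path)
  lines[5] <- lines[4]
  writeLines(lines, path)
  expect_error(read_stream(path), "strictly increasing")

  # out-of-range value names the offending row
  write_stream(st, path)
  lines <- readLines(path)
  lines[5] <- sub("0.00000000,0.00000000$", "0.00000000,2.00000000", lines[5])
  writeLines(lines, path)
  expect_error(read_stream(path), "row")

  expect_error(write_stream(list(), path), "tactile_stream")
})

test_that("ADC counts are normalized by the declared full scale", {
  path <- withr::local_tempfile(fileext = ".csv")
  st <- constant_stream(0.25, n = 3)
  write_stream(st, path, meta = list(full_scale = 1))
  lines <- readLines(path)
  lines <- gsub("0.25000000", "256.00000000", lines)
  lines[2] <- "# full_scale: 1024"
  writeLines(lines, path)
  expect_equal(unname(read_stream(path)$values[1, 1]), 0.25)
})

test_that("low-pass filter has unit DC gain and converges to a constant", {
  st <- constant_stream(0.7, n = 500)
  out <- lowpass_filter(st, cutoff_hz = 1, order = 1)
  expect_equal(out$time, st$time)
  expect_lt(max(abs(out$values[500, ] - 0.7)), 1e-6)
  # state priming: no start-up transient for a constant stream
  expect_lt(max(abs(out$values - 0.7)), 1e-9)
  expect_error(lowpass_filter(st, cutoff_hz = 60), "Nyquist|fs/2")
})

test_that("step response matches a dense ODE oracle of the analog filter", {
  skip_if_not_installed("deSolve")
  fs <- 100
  n <- 100
  x <- c(0, rep(1, n - 1))  # step at the second sample
  st <- tactile_stream((seq_len(n) - 1) / fs,
                       matrix(x, nrow = n, ncol = 288), fs = fs)
  out <- lowpass_filter(st, cutoff_hz = 1, order = 1)
  y <- out$values[, 1]
  # analog first-order low-pass: tau * y' = u - y, u = step at t = 1/fs
  tau <- 1 / (2 * pi * 1)
  ode <- deSolve::ode(y = c(y = 0), times = seq(0, 0.99, by = 1e-4),
                      func = function(t, s, p)
                        list((as.numeric(t >= 1 / fs) - s) / tau))
  t_eval <- 1 / fs + tau  # one analog time constant after step onset
  y_d <- stats::approx(st$time, y, xout = t_eval)$y
  y_a <- stats::approx(ode[, "time"], ode[, "y"], xout = t_eval)$y
  expect_equal(y_a, 1 - exp(-1), tolerance = 1e-3)  # oracle sanity
  expect_lt(abs(y_d - y_a) / y_a, 0.02)
})

test_that("frequencies above cutoff are attenuated", {
  fs <- 100; n <- 400
  tt <- (seq_len(n) - 1) / fs
  x <- 0.5 + 0.4 * sin(2 * pi * 10 * tt)
  st <- tactile_stream(tt, matrix(x, nrow = n, ncol = 288), fs = fs)
  out <- lowpass_filter(st, cutoff_hz = 1, order = 1)
  y <- out$values[tt > 2, 1]  # after settling
  expect_lt(max(y) - min(y), 0.2 * 0.8)  # strong attenuation at 10 Hz
})

test_that("the filter recursion is linear and causal", {
  lp <- lowpass_coefs(1, 100, order = 2)
  set.seed(9)
  xa <- runif(50); xb <- runif(50)
  run <- function(x) {
    st <- filter_state(lp, x0 = 0, n_channels = 1)
    vapply(x, function(xi) {
      st <<- filter_step(st, xi)
      st$y
    }, numeric(1))
  }
  ya <- run(xa); yb <- run(xb)
  yab <- run(2 * xa + 3 * xb)
  expect_lt(max(abs(yab - (2 * ya + 3 * yb))), 1e-9)
  # causality: perturbing future samples leaves earlier outputs untouched
  xc <- xa; xc[31:50] <- 1
  expect_identical(run(xc)[1:30], ya[1:30])
})

test_that("package recursion matches signal::filter", {
  lp <- lowpass_coefs(2, 100, order = 3)
  set.seed(4)
  x <- runif(200)
  st <- filter_state(lp, x0 = 0, n_channels = 1)
  mine <- vapply(x, function(xi) { st <<- filter_step(st, xi); st$y },
                 numeric(1))
  ref <- as.numeric(signal::filter(signal::Arma(b = lp$b, a = lp$a), x))
  expect_equal(mine, ref, tolerance = 1e-12)
})
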
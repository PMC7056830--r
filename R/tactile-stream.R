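#' Taxel naming and flattening order
#'
#' Taxels are indexed by `(board, row, col)` with `board` in 0..8, `row` in
#' 0..7 and `col` in 0..3, and flattened board-major, then row, then column.
#' This fixed ordering is normative: ridge regression is permutation
#' invariant, but the ROI partition of [partition_rois()] depends on it.
#'
#' @param board,row,col 0-based taxel coordinates (vectorised).
#' @return `taxel_index()` returns the 1-based position of the taxel in a
#'   flattened 288-vector; `taxel_names()` the full 288-long name vector
#'   `b0_r0_c0 ... b8_r7_c3` in flattening order.
#' @examples
#' taxel_index(0, 0, 0)  # 1
#' taxel_index(8, 7, 3)  # 288
#' @export
taxel_index <- function(board, row, col) {
  stopifnot(all(board >= 0 & board < N_BOARDS),
            all(row >= 0 & row < N_ROWS),
            all(col >= 0 & col < N_COLS))
  as.integer(board) * (N_ROWS * N_COLS) + as.integer(row) * N_COLS +
    as.integer(col) + 1L
}

#' @rdname taxel_index
#' @export
taxel_names <- function() {
  idx <- expand.grid(col = 0:(N_COLS - 1), row = 0:(N_ROWS - 1),
                     board = 0:(N_BOARDS - 1))
  sprintf("b%d_r%d_c%d", idx$board, idx$row, idx$col)
}

#' Single tactile frame
#'
#' One timestamped reading of the full 9x8x4 taxel grid, values normalized
#' to `[0, 1]`.
#'
#' @param values numeric vector of length 288 in flattening order, or a
#'   9x8x4 array indexed `[board, row, col]` (1-based).
#' @param t time stamp in seconds (non-negative).
#' @return An object of class `tactile_frame`: a named 288-vector with a
#'   `t` attribute.
#' @seealso [frame_grid()] to recover the 9x8x4 array view.
#' @export
tactile_frame <- function(values, t = 0) {
  if (is.array(values) && length(dim(values)) == 3) {
    if (!all(dim(values) == c(N_BOARDS, N_ROWS, N_COLS)))
      stop_validation("frame array must be 9x8x4, got ",
                      paste(dim(values), collapse = "x"))
    values <- as.numeric(aperm(values, c(3, 2, 1)))
  }
  values <- as.numeric(values)
  if (length(values) != N_TAXELS)
    stop_validation("a tactile frame has exactly ", N_TAXELS,
                    " values, got ", length(values))
  if (!all(is.finite(values)))
    stop_validation("frame contains non-finite values")
  if (any(values < 0 | values > 1))
    stop_validation("frame values must lie in [0, 1] after normalization")
  if (!is.finite(t) || t < 0)
    stop_validation("frame time must be a non-negative number")
  structure(setNames(values, taxel_names()), t = as.numeric(t),
            class = "tactile_frame")
}

#' @rdname tactile_frame
#' @param frame a `tactile_frame`.
#' @export
frame_grid <- function(frame) {
  aperm(array(as.numeric(frame), dim = c(N_COLS, N_ROWS, N_BOARDS)),
        c(3, 2, 1))
}

#' @export
print.tactile_frame <- function(x, ...) {
  cat("<tactile_frame> t =", attr(x, "t"), "s; 288 taxels in [",
      format(min(x), digits = 3), ",", format(max(x), digits = 3), "]\n")
  invisible(x)
}

#' Tactile stream
#'
#' A uniformly sampled sequence of tactile frames, stored as an n x 288
#' matrix plus a time vector. Timestamps must be strictly increasing and
#' spaced `1/fs` within a jitter tolerance.
#'
#' @param time numeric vector of timestamps in seconds.
#' @param values n x 288 numeric matrix, one row per frame, columns in
#'   flattening order.
#' @param fs sampling rate in Hz (default 100).
#' @param jitter_tol allowed relative deviation of the inter-frame spacing
#'   from `1/fs` (default 0.05).
#' @return An object of class `tactile_stream` with elements `time`,
#'   `values`, `fs`.
#' @export
tactile_stream <- function(time, values, fs = 100, jitter_tol = 0.05) {
  values <- as.matrix(values)
  time <- as.numeric(time)
  if (length(time) == 0L)
    stop_validation("a tactile stream must contain at least one frame")
  if (nrow(values) != length(time))
    stop_validation("time vector and value matrix disagree: ",
                    length(time), " vs ", nrow(values), " frames")
  if (ncol(values) != N_TAXELS)
    stop_validation("streams carry ", N_TAXELS, " taxel columns, got ",
                    ncol(values))
  if (!all(is.finite(time)) || any(time < 0))
    stop_validation("timestamps must be finite and non-negative")
  if (length(time) > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) {
      k <- which(dt <= 0)[1]
      stop_validation("timestamps must be strictly increasing (violated at row ",
                      k + 1L, ", t = ", time[k + 1L], ")")
    }
    if (any(abs(dt - 1 / fs) > jitter_tol / fs))
      stop_validation("inter-frame spacing deviates from 1/fs = ", 1 / fs,
                      " s by more than the jitter tolerance")
  }
  bad <- which(!is.finite(values) | values < 0 | values > 1)
  if (length(bad)) {
    row <- (bad[1] - 1L) %% nrow(values) + 1L
    stop_validation("taxel values must be finite and in [0, 1]; first offending data row: ",
                    row)
  }
  colnames(values) <- taxel_names()
  structure(list(time = time, values = values, fs = fs),
            class = "tactile_stream")
}

#' @export
print.tactile_stream <- function(x, ...) {
  cat("<tactile_stream>", length(x$time), "frames @", x$fs, "Hz,",
      sprintf("t in [%.3f, %.3f] s\n", x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' @rdname tactile_stream
#' @param stream a `tactile_stream`.
#' @param i frame number (1-based).
#' @export
stream_frame <- function(stream, i) {
  tactile_frame(stream$values[i, ], t = stream$time[i])
}

n_frames <- function(stream) length(stream$time)

#' Read and write tactile stream CSV files
#'
#' The stream format is plain CSV with a header `time_s,b0_r0_c0,...,b8_r7_c3`
#' (289 columns in flattening order) and one row per sample. Comment lines
#' starting with `#` may carry `key: value` metadata; `fs` and `full_scale`
#' are honoured. Raw integer ADC counts are normalized by dividing by
#' `full_scale` so that stored readings land in `[0, 1]`.
#'
#' @param path file path.
#' @param fs sampling rate used when the file carries no `# fs:` line.
#' @param full_scale ADC full-scale value; values in the file are divided by
#'   it. Overrides any `# full_scale:` line when given.
#' @return `read_stream()` returns a validated [tactile_stream()];
#'   `write_stream()` returns `path` invisibly.
#' @export
read_stream <- function(path, fs = 100, full_scale = NULL) {
  if (!file.exists(path)) stop_format("stream file not found: ", path)
  meta <- read_stream_meta(path)
  if (!is.null(meta$fs)) fs <- as.numeric(meta$fs)
  if (is.null(full_scale))
    full_scale <- if (!is.null(meta$full_scale)) as.numeric(meta$full_scale) else 1
  header <- strsplit(first_noncomment_line(path), ",", fixed = TRUE)[[1]]
  expected <- c("time_s", taxel_names())
  if (length(header) != length(expected) || !all(header == expected))
    stop_format("malformed stream header: expected 'time_s' followed by the 288 ",
                "taxel columns in flattening order")
  dat <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (nrow(dat) == 0L) stop_format("stream file contains no data rows")
  values <- as.matrix(dat[, -1, drop = FALSE]) / full_scale
  tactile_stream(dat[[1]], values, fs = fs)
}

read_stream_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

first_noncomment_line <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop_format("stream file has no header line")
    if (!startsWith(ln, "#")) return(ln)
  }
}

#' @rdname read_stream
#' @param stream a [tactile_stream()].
#' @param digits number of decimal places written (fixed notation); the
#'   round trip `read_stream(write_stream(x))` is lossless at this precision.
#' @param meta named list of extra `# key: value` metadata lines.
#' @export
write_stream <- function(stream, path, digits = 8, meta = list()) {
  if (!inherits(stream, "tactile_stream"))
    stop_validation("write_stream() expects a tactile_stream")
  meta <- modifyList(list(fs = stream$fs, full_scale = 1), meta)
  hdr <- c(sprintf("# %s: %s", names(meta), vapply(meta, format, "")),
           paste(c("time_s", taxel_names()), collapse = ","))
  fmt <- paste0("%.", digits, "f")
  rows <- vapply(seq_along(stream$time), function(i) {
    paste(c(sprintf(fmt, stream$time[i]), sprintf(fmt, stream$values[i, ])),
          collapse = ",")
  }, "")
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_format("cannot write stream to: ", path)
  invisible(path)
}

#' Causal low-pass Butterworth filtering of tactile streams
#'
#' Designs a digital Butterworth low-pass filter (bilinear transform, via
#' [signal::butter()]) and applies it causally, per taxel, in a single pass
#' (no zero-phase filtering: the pipeline runs online). The filter state is
#' primed with the first sample of each channel, i.e. the filter starts at
#' steady state for that value, so a stream that begins at rest shows no
#' start-up transient. The default 1 Hz first-order filter attenuates sensor
#' noise while keeping the control loop responsive.
#'
#' `lowpass_filter()` clamps its output to `[0, 1]` at the stream boundary;
#' the internal recursion is unclamped and exactly linear, and is exposed
#' through `filter_state()` / `filter_step()` for online sample-by-sample
#' use over all 288 channels at once.
#'
#' @param stream a [tactile_stream()].
#' @param cutoff_hz cut-off frequency in Hz; must be below the Nyquist
#'   frequency `fs/2`.
#' @param order filter order (>= 1; default 1).
#' @return A filtered [tactile_stream()] with identical timestamps.
#' @export
lowpass_filter <- function(stream, cutoff_hz = 1, order = 1) {
  coefs <- lowpass_coefs(cutoff_hz, stream$fs, order)
  st <- filter_state(coefs, x0 = stream$values[1, ])
  out <- matrix(0, nrow = n_frames(stream), ncol = N_TAXELS)
  for (i in seq_len(n_frames(stream))) {
    st <- filter_step(st, stream$values[i, ])
    out[i, ] <- st$y
  }
  tactile_stream(stream$time, clamp01(out), fs = stream$fs,
                 jitter_tol = Inf)
}

#' @rdname lowpass_filter
#' @param fs sampling rate in Hz.
#' @export
lowpass_coefs <- function(cutoff_hz = 1, fs = 100, order = 1) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop_validation("cutoff must satisfy 0 < cutoff < fs/2 = ", fs / 2, " Hz")
  if (order < 1) stop_validation("filter order must be >= 1")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a), fs = fs,
       cutoff_hz = cutoff_hz, order = as.integer(order))
}

#' @rdname lowpass_filter
#' @param coefs coefficients from `lowpass_coefs()`.
#' @param x0 numeric vector of initial channel values used to prime the
#'   state at steady state (recycled to the number of channels).
#' @param n_channels number of parallel channels.
#' @export
filter_state <- function(coefs, x0 = 0, n_channels = N_TAXELS) {
  x0 <- rep_len(as.numeric(x0), n_channels)
  n <- length(coefs$a) - 1L
  # steady-state direct-form-II-transposed registers for constant input x0:
  # z_i = x0 * sum_{j > i} (b_j - a_j); exact because DC gain is 1.
  z <- matrix(0, nrow = n, ncol = n_channels)
  for (i in seq_len(n)) {
    j <- (i + 1L):(n + 1L)
    z[i, ] <- x0 * sum(coefs$b[j] - coefs$a[j])
  }
  list(coefs = coefs, z = z, y = x0)
}

#' @rdname lowpass_filter
#' @param state a filter state from `filter_state()` or a previous
#'   `filter_step()`.
#' @param x numeric vector: one new sample per channel.
#' @return `filter_step()` returns the updated state; element `y` holds the
#'   (unclamped) filtered sample.
#' @export
filter_step <- function(state, x) {
  b <- state$coefs$b; a <- state$coefs$a
  n <- length(a) - 1L
  z <- state$z
  y <- b[1] * x + z[1, ]
  if (n > 1L) {
    for (i in seq_len(n - 1L))
      z[i, ] <- b[i + 1L] * x + z[i + 1L, ] - a[i + 1L] * y
  }
  z[n, ] <- b[n + 1L] * x - a[n + 1L] * y
  state$z <- z
  state$y <- y
  state
}
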
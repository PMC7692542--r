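#' Regularly sampled multichannel series
#'
#' The working container produced by preprocessing: a frames-by-channels
#' value matrix sampled at `rate_hz`, with an implied time axis
#' `start + (0:(n-1))/rate_hz` and a per-frame logical validity mask.
#'
#' @param values numeric matrix (frames x channels) with column names, or a
#'   numeric vector for a single channel.
#' @param rate_hz sampling rate in Hz.
#' @param start time of the first frame in seconds from session start.
#' @param valid logical vector, one flag per frame; defaults to all `TRUE`.
#' @return an object of class `uniform_series`.
#' @export
uniform_series <- function(values, rate_hz, start = 0, valid = NULL) {
  if (is.vector(values)) {
    values <- matrix(values, ncol = 1, dimnames = list(NULL, "value"))
  }
  stopifnot(is.matrix(values), is.numeric(values), rate_hz > 0)
  if (is.null(valid)) valid <- rep(TRUE, nrow(values))
  stopifnot(length(valid) == nrow(values), is.logical(valid))
  structure(
    list(values = values, rate_hz = rate_hz, start = start, valid = valid),
    class = "uniform_series"
  )
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d frames x %d channels @ %g Hz, %.1f%% valid\n",
              nrow(x$values), ncol(x$values), x$rate_hz,
              100 * mean(x$valid)))
  invisible(x)
}

#' @rdname uniform_series
#' @param x object to test or use.
#' @export
is_uniform_series <- function(x) inherits(x, "uniform_series")

#' @rdname uniform_series
#' @export
series_times <- function(x) {
  stopifnot(is_uniform_series(x))
  x$start + (seq_len(nrow(x$values)) - 1) / x$rate_hz
}

#' @rdname uniform_series
#' @export
series_duration <- function(x) nrow(x$values) / x$rate_hz

#' Interpolate a non-uniformly sampled stream to a uniform rate
#'
#' Linear interpolation between valid neighboring frames onto the grid
#' `0, 1/rate, 2/rate, ...` up to the last observed timestamp.  Grid frames
#' are marked invalid when (a) they fall outside the span of valid input
#' frames (no extrapolation), or (b) the two valid input frames bracketing
#' them are more than `max_gap_s` apart -- long tracking dropouts are not
#' bridged, they surface as invalid frames that feed the window-validity
#' rule downstream.
#'
#' @param timestamps numeric vector, strictly increasing, seconds from
#'   session start.
#' @param values numeric matrix (frames x channels) or vector.
#' @param rate_hz target rate (default 30).
#' @param valid logical per input frame; invalid frames are ignored.
#' @param max_gap_s largest inter-frame gap bridged by interpolation
#'   (default 0.2 s, i.e. six nominal frames at 30 Hz).
#' @param duration_s optional session duration; the grid then spans
#'   `0 .. duration_s` regardless of when tracking started/ended.
#' @return a [uniform_series].
#' @export
interpolate_uniform <- function(timestamps, values, rate_hz = 30,
                                valid = NULL, max_gap_s = 0.2,
                                duration_s = NULL) {
  if (is.vector(values)) {
    values <- matrix(values, ncol = 1, dimnames = list(NULL, "value"))
  }
  stopifnot(length(timestamps) == nrow(values))
  if (is.null(valid)) valid <- rep(TRUE, length(timestamps))
  valid <- valid & rowSums(is.na(values)) == 0
  bad <- which(diff(timestamps) <= 0)
  if (length(bad) > 0) {
    stop("timestamps not strictly increasing at row ", bad[1] + 1)
  }
  ts <- timestamps[valid]
  vs <- values[valid, , drop = FALSE]
  if (length(ts) < 2) stop("need at least 2 valid frames to interpolate")

  t_end <- if (is.null(duration_s)) timestamps[length(timestamps)] else duration_s
  n_out <- floor(t_end * rate_hz + 1e-9) + 1
  grid <- (seq_len(n_out) - 1) / rate_hz

  # bracketing interval for each grid point among the valid input frames
  lo <- findInterval(grid, ts)                 # 0 if before first valid frame
  inside <- lo >= 1 & grid <= ts[length(ts)]
  lo_c <- pmin(pmax(lo, 1), length(ts) - 1)
  hi_c <- lo_c + 1
  # exact hits on the last valid frame
  w <- (grid - ts[lo_c]) / (ts[hi_c] - ts[lo_c])
  w <- pmin(pmax(w, 0), 1)
  out <- vs[lo_c, , drop = FALSE] * (1 - w) + vs[hi_c, , drop = FALSE] * w
  gap_ok <- (ts[hi_c] - ts[lo_c]) <= max_gap_s | abs(grid - ts[lo_c]) < 1e-12 |
    abs(grid - ts[hi_c]) < 1e-12
  ok <- inside & gap_ok
  out[!ok, ] <- NA_real_
  uniform_series(out, rate_hz, start = 0, valid = ok)
}

# ---- zero-phase Butterworth -------------------------------------------------

# causal IIR pass y = filter(b, a, x) on a plain matrix, column-wise (C)
iir_pass <- function(b, a, m) iir_filter_mat(b, a, m)

# forward-backward IIR filtering of a matrix, column-wise, with odd
# reflection padding at both ends so the filter state has settled before the
# real samples begin.
filtfilt_mat <- function(b, a, x, padlen = NULL) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (is.null(padlen)) padlen <- min(n - 1, 10 * max(length(a), length(b)))
  one_pass <- function(m) iir_pass(b, a, m)
  # odd reflection: 2*x[1] - x[k+1] at the head, analog at the tail
  head_pad <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(padlen + 1, 2), , drop = FALSE]
  tail_pad <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
    x[seq(n - 1, n - padlen), , drop = FALSE]
  xp <- rbind(head_pad, x, tail_pad)
  y <- one_pass(xp)
  y <- one_pass(y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y[padlen + seq_len(n), , drop = FALSE]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-order Butterworth low-pass filter forward and backward
#' (squaring its magnitude response and cancelling its phase), per
#' contiguous run of valid frames.  At the cutoff frequency the two-pass
#' amplitude ratio is 0.5 (the square of the single-pass -3 dB point).
#' Runs shorter than three filter startup lengths are passed through
#' unfiltered and recorded in the `unfiltered_runs` attribute.  Invalid
#' frames are untouched.
#'
#' @param series a [uniform_series].
#' @param cutoff_hz cutoff frequency in Hz (default 6); must be below the
#'   Nyquist frequency.
#' @param order filter order (default 2).
#' @return a [uniform_series] of identical shape and validity mask.
#' @export
butterworth_zero_phase <- function(series, cutoff_hz = 6, order = 2) {
  stopifnot(is_uniform_series(series))
  if (cutoff_hz >= series$rate_hz / 2) {
    stop("cutoff_hz (", cutoff_hz, ") must be below the Nyquist frequency (",
         series$rate_hz / 2, ")")
  }
  bf <- signal::butter(order, 2 * cutoff_hz / series$rate_hz, type = "low")
  startup <- 3 * (order + 1)
  min_len <- 3 * startup
  out <- series$values
  runs <- valid_runs(series$valid)
  skipped <- integer(0)
  for (i in seq_len(nrow(runs))) {
    idx <- runs[i, 1]:runs[i, 2]
    if (length(idx) < min_len) {
      skipped <- c(skipped, unname(runs[i, 1]))
      next
    }
    out[idx, ] <- filtfilt_mat(bf$b, bf$a, series$values[idx, , drop = FALSE])
  }
  res <- uniform_series(out, series$rate_hz, series$start, series$valid)
  attr(res, "unfiltered_runs") <- skipped
  res
}

# start/end indices of maximal runs of TRUE
valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Downsample a uniform series by linear interpolation
#'
#' Each output frame at time `t` takes the linearly interpolated value of
#' the bracketing source frames; the frame is invalid if either bracketing
#' source frame is invalid.  When the target rate divides the source rate
#' the output is an exact subsample.
#'
#' @param series a [uniform_series].
#' @param target_rate_hz output rate (default 10); must not exceed the
#'   source rate.
#' @return a [uniform_series] at `target_rate_hz`.
#' @export
downsample_series <- function(series, target_rate_hz = 10) {
  stopifnot(is_uniform_series(series))
  if (target_rate_hz > series$rate_hz) {
    stop("target rate (", target_rate_hz,
         ") exceeds source rate (", series$rate_hz, ")")
  }
  n <- nrow(series$values)
  t_src_last <- (n - 1) / series$rate_hz
  grid <- seq(0, t_src_last + 1e-12, by = 1 / target_rate_hz)
  pos <- grid * series$rate_hz + 1      # fractional source index
  lo <- pmin(floor(pos + 1e-9), n)
  hi <- pmin(lo + 1, n)
  w <- pos - lo
  w[w < 1e-9] <- 0
  vals <- series$values[lo, , drop = FALSE] * (1 - w)
  frac <- w > 0   # only true interpolation touches the right neighbor
  if (any(frac)) {
    vals[frac, ] <- vals[frac, , drop = FALSE] +
      series$values[hi[frac], , drop = FALSE] * w[frac]
  }
  ok <- series$valid[lo] & ifelse(frac, series$valid[hi], TRUE)
  vals[!ok, ] <- NA_real_
  uniform_series(vals, target_rate_hz, series$start, ok)
}

#' Plan validity-screened analysis windows
#'
#' Tiles the session with consecutive, non-overlapping windows of
#' `window_s` seconds anchored at the session start (a trailing partial
#' window is dropped), and keeps a window only if at least
#' `min_valid_fraction` of its frames are valid -- intervals where less
#' than 90% of the data were tracked are discarded under the defaults.
#'
#' @param series a [uniform_series] (or a logical validity vector via
#'   `valid` + `rate_hz`).
#' @param window_s window length in seconds (default 100).
#' @param min_valid_fraction smallest valid-frame fraction for a window to
#'   be kept (default 0.9).
#' @return a `window_plan`: data frame with columns `window`, `start_frame`,
#'   `end_frame`, `valid_fraction`, `keep`, plus attributes `window_s` and
#'   `rate_hz`.
#' @export
plan_windows <- function(series, window_s = 100, min_valid_fraction = 0.9) {
  stopifnot(is_uniform_series(series))
  n <- nrow(series$values)
  wlen <- round(window_s * series$rate_hz)
  k <- floor(n / wlen)
  if (k == 0) {
    warning("series shorter than one window (", window_s, " s); zero windows")
  }
  starts <- (seq_len(k) - 1) * wlen + 1
  ends <- starts + wlen - 1
  vf <- vapply(seq_len(k),
               function(i) mean(series$valid[starts[i]:ends[i]]),
               numeric(1))
  plan <- data.frame(window = seq_len(k), start_frame = starts,
                     end_frame = ends, valid_fraction = vf,
                     keep = vf >= min_valid_fraction)
  attr(plan, "window_s") <- window_s
  attr(plan, "rate_hz") <- series$rate_hz
  class(plan) <- c("window_plan", "data.frame")
  plan
}

#' Combine two partners' window plans
#'
#' A dyad-level window is kept only if it is kept for both partners.
#'
#' @param plan_a,plan_b `window_plan` objects over the same grid.
#' @return a `window_plan` with the conjunction of the keep flags.
#' @export
combine_window_plans <- function(plan_a, plan_b) {
  stopifnot(inherits(plan_a, "window_plan"), inherits(plan_b, "window_plan"))
  k <- min(nrow(plan_a), nrow(plan_b))
  out <- plan_a[seq_len(k), , drop = FALSE]
  out$valid_fraction <- pmin(plan_a$valid_fraction[seq_len(k)],
                             plan_b$valid_fraction[seq_len(k)])
  out$keep <- plan_a$keep[seq_len(k)] & plan_b$keep[seq_len(k)]
  out
}
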
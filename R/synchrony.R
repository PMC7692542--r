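#' Windowed lagged cross-correlation of two uniform series
#'
#' For every kept analysis window and every lag on the grid
#' `-max_lag_s, ..., -0.1, 0, 0.1, ..., max_lag_s`, the Pearson correlation
#' between `x(t)` and `y(t + tau)` over the samples where both series are
#' valid and both time points fall inside the window (the shift stays
#' inside the window, so the overlap shrinks as `|tau|` grows).  Positive
#' lags mean the second series trails the first.  Cells whose overlap holds
#' fewer than `n_min` jointly valid samples, or where either segment is
#' constant, are missing (`NA`) -- never imputed.
#'
#' @param x,y single-channel [uniform_series] at the same rate (10 Hz in
#'   the standard pipeline) with aligned starts.
#' @param plan a `window_plan` (already combined across partners for dyad
#'   data, see [combine_window_plans()]).
#' @param max_lag_s largest lag magnitude in seconds (5 for body, 1 for
#'   face).
#' @param lag_step_s lag grid step (default 0.1 s); `lag_step_s` times the
#'   sampling rate must be a whole number of samples.
#' @param n_min smallest overlap for a cell to count (default 50 samples,
#'   i.e. 5 s at 10 Hz).
#' @return an object of class `windowed_crosscorr`: list with `r` (kept
#'   windows x lags matrix), `n_overlap` (same shape), `lags` (seconds),
#'   `windows` (kept window ids), `rate_hz`, and `sign_convention`.
#' @export
windowed_crosscorr <- function(x, y, plan, max_lag_s = 5, lag_step_s = 0.1,
                               n_min = 50) {
  stopifnot(is_uniform_series(x), is_uniform_series(y))
  if (x$rate_hz != y$rate_hz) {
    stop("rate mismatch: ", x$rate_hz, " vs ", y$rate_hz, " Hz")
  }
  if (ncol(x$values) != 1 || ncol(y$values) != 1) {
    stop("windowed_crosscorr expects single-channel series; ",
         "see the feature table for per-channel variants")
  }
  res <- wcc_engine(x$values, y$values, x$valid, y$valid, plan,
                    x$rate_hz, max_lag_s, lag_step_s, n_min)
  rmat <- res$r[, , 1, drop = FALSE]
  nmat <- res$n[, , 1, drop = FALSE]
  dim(rmat) <- dim(rmat)[1:2]
  dim(nmat) <- dim(nmat)[1:2]
  structure(
    list(r = rmat,
         n_overlap = nmat,
         lags = res$lags, windows = res$windows, rate_hz = x$rate_hz,
         sign_convention = "positive lag: second series trails the first"),
    class = "windowed_crosscorr"
  )
}

# Multichannel core: Xa, Xb are frames x channels matrices with shared
# per-frame validity masks; returns r and n arrays [window, lag, channel].
# Per window, the masked cross-products Sxy(s), Sx(s), Sy(s), Sxx(s),
# Syy(s) and overlap counts n(s) for every integer shift s are computed in
# one go via FFT cross-correlation (zero-filled invalid frames plus mask
# cross-correlations), column-wise across channels; Pearson correlations
# then follow from the sums.  Pairwise-invalid samples are excluded
# exactly, as in a direct double loop.
wcc_engine <- function(Xa, Xb, va, vb, plan, rate_hz, max_lag_s, lag_step_s,
                       n_min) {
  step <- lag_step_s * rate_hz
  if (abs(step - round(step)) > 1e-9) {
    stop("lag_step_s (", lag_step_s, ") is not a whole number of samples at ",
         rate_hz, " Hz")
  }
  step <- round(step)
  nlag_side <- round(max_lag_s / lag_step_s)
  shifts <- seq(-nlag_side, nlag_side) * step
  lags <- shifts / rate_hz
  kept <- which(plan$keep)
  if (length(kept) == 0) {
    warning("no kept windows; empty cross-correlation result")
  }
  nch <- ncol(Xa)
  r <- array(NA_real_, c(length(kept), length(shifts), nch))
  nn <- array(0L, c(length(kept), length(shifts), nch))
  va <- va & rowSums(is.na(Xa)) == 0
  vb <- vb & rowSums(is.na(Xb)) == 0
  Xa0 <- Xa; Xa0[!va, ] <- 0; Xa0[is.na(Xa0)] <- 0
  Xb0 <- Xb; Xb0[!vb, ] <- 0; Xb0[is.na(Xb0)] <- 0
  n_frames <- min(nrow(Xa), nrow(Xb))
  smax <- max(abs(shifts))
  for (wi in seq_along(kept)) {
    w0 <- plan$start_frame[kept[wi]]
    w1 <- min(plan$end_frame[kept[wi]], n_frames)
    L <- w1 - w0 + 1
    m <- stats::nextn(L + smax, 2)
    pad <- function(M) rbind(M, matrix(0, m - nrow(M), ncol(M)))
    A <- Xa0[w0:w1, , drop = FALSE]
    B <- Xb0[w0:w1, , drop = FALSE]
    ma <- as.numeric(va[w0:w1])
    mb <- as.numeric(vb[w0:w1])
    fA <- Conj(stats::mvfft(pad(A)))
    fA2 <- Conj(stats::mvfft(pad(A * A)))
    fma <- Conj(stats::fft(c(ma, numeric(m - L))))
    fB <- stats::mvfft(pad(B))
    fB2 <- stats::mvfft(pad(B * B))
    fmb <- stats::fft(c(mb, numeric(m - L)))
    xcs <- function(F1, F2) {
      # Sum_t u[t] v[t+s]: index s+1 for s >= 0, m+s+1 for s < 0
      Re(stats::mvfft(F1 * F2, inverse = TRUE)) / m
    }
    idx <- ifelse(shifts >= 0, shifts + 1, m + shifts + 1)
    Sxy <- xcs(fA, fB)[idx, , drop = FALSE]
    Sx  <- xcs(fA, matrix(fmb, m, nch))[idx, , drop = FALSE]
    Sxx <- xcs(fA2, matrix(fmb, m, nch))[idx, , drop = FALSE]
    Sy  <- xcs(matrix(fma, m, nch), fB)[idx, , drop = FALSE]
    Syy <- xcs(matrix(fma, m, nch), fB2)[idx, , drop = FALSE]
    n_ok <- round(Re(stats::fft(fma * fmb, inverse = TRUE)) / m)[idx]
    # clip shifts whose in-window overlap is impossible
    n_ok[abs(shifts) >= L] <- 0
    vx <- n_ok * Sxx - Sx^2
    vy <- n_ok * Syy - Sy^2
    # variances at roundoff scale (relative to the sum of squares) are
    # treated as zero: constant segments have no defined correlation
    degen <- (vx < 1e-8 * pmax(n_ok, 1) * abs(Sxx)) |
      (vy < 1e-8 * pmax(n_ok, 1) * abs(Syy))
    denom <- sqrt(pmax(vx, 0) * pmax(vy, 0))
    rr <- (n_ok * Sxy - Sx * Sy) / denom
    rr[degen | !is.finite(rr)] <- NA_real_
    rr[n_ok < n_min, ] <- NA_real_
    r[wi, , ] <- pmin(pmax(rr, -1), 1)
    nn[wi, , ] <- matrix(as.integer(n_ok), length(shifts), nch)
  }
  list(r = r, n = nn, lags = lags, windows = kept)
}

#' @export
as.data.frame.windowed_crosscorr <- function(x, ...) {
  out <- as.data.frame(x$r)
  names(out) <- sprintf("lag_%+.1f", x$lags)
  cbind(data.frame(window = x$windows), out)
}

#' @export
print.windowed_crosscorr <- function(x, ...) {
  cat(sprintf("<windowed_crosscorr> %d window(s) x %d lags (step %.1f s), %s\n",
              NROW(x$r), length(x$lags), diff(x$lags[1:2]),
              x$sign_convention))
  invisible(x)
}

#' Summary scores of a windowed cross-correlation
#'
#' The five synchrony summaries aggregated jointly over all non-missing
#' (window, lag) cells: `mean_r`; `abs_mean_r` (mean of `|r|`);
#' `nonneg_mean_r` (mean over the nonnegative cells; missing if none);
#' `max_r`; and `abs_max_r`, the signed value of the cell with the largest
#' magnitude.  The per-lag `profile` (mean over windows at each lag) is
#' retained for the lag-decay diagnostic.
#'
#' @param wcc a [windowed_crosscorr].
#' @return an object of class `synchrony_summary` (list of the five scalars
#'   plus `profile`, `lags`, `n_windows`), or scalars `NA` when no window
#'   was kept.
#' @export
summarize_synchrony <- function(wcc) {
  stopifnot(inherits(wcc, "windowed_crosscorr"))
  r <- wcc$r
  if (length(r) == 0 || all(is.na(r))) {
    return(structure(list(mean_r = NA_real_, abs_mean_r = NA_real_,
                          nonneg_mean_r = NA_real_, max_r = NA_real_,
                          abs_max_r = NA_real_,
                          profile = rep(NA_real_, length(wcc$lags)),
                          lags = wcc$lags, n_windows = 0L),
                     class = "synchrony_summary"))
  }
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  cells <- r[!is.na(r)]
  nonneg <- cells[cells >= 0]
  structure(
    list(mean_r = mean(cells),
         abs_mean_r = mean(abs(cells)),
         nonneg_mean_r = if (length(nonneg)) mean(nonneg) else NA_real_,
         max_r = max(cells),
         abs_max_r = cells[which.max(abs(cells))],
         profile = colMeans(r, na.rm = TRUE),
         lags = wcc$lags,
         n_windows = nrow(r)),
    class = "synchrony_summary"
  )
}

#' @export
print.synchrony_summary <- function(x, ...) {
  cat(sprintf(paste0("<synchrony_summary> mean %.3f | abs mean %.3f | ",
                     "nonneg mean %.3f | max %.3f | abs max %.3f ",
                     "(%d window(s))\n"),
              x$mean_r, x$abs_mean_r, x$nonneg_mean_r, x$max_r, x$abs_max_r,
              x$n_windows))
  invisible(x)
}

#' Per-lag synchrony profile
#'
#' Mean cross-correlation over windows at each lag.  For genuinely coupled
#' partners the profile decays toward zero as the lag moves away from the
#' true coupling lag; a flat profile indicates absence of synchrony.
#'
#' @param wcc a [windowed_crosscorr] or [summarize_synchrony()] result.
#' @return data frame with columns `lag_s` and `mean_r`.
#' @export
synchrony_lag_profile <- function(wcc) {
  if (inherits(wcc, "windowed_crosscorr")) wcc <- summarize_synchrony(wcc)
  stopifnot(inherits(wcc, "synchrony_summary"))
  data.frame(lag_s = wcc$lags, mean_r = wcc$profile)
}

# shared dyad preprocessing: both partners' composite extent series at the
# synchrony rate, plus the combined window plan
dyad_extent_series <- function(session, cfg) {
  ext10 <- lapply(session$participants, function(p) {
    u <- interpolate_uniform(p$skeleton$timestamps, p$skeleton$values,
                             cfg$resample_rate_hz, p$skeleton$valid,
                             cfg$max_gap_s)
    f <- butterworth_zero_phase(u, cfg$filter_cutoff_hz, cfg$filter_order)
    ext <- frame_displacement(f)
    comp <- uniform_series(ext$values[, "composite", drop = FALSE],
                           ext$rate_hz, ext$start, ext$valid)
    downsample_series(comp, cfg$synchrony_rate_hz)
  })
  align_pair(ext10)
}

# composite facial-movement series per partner at the synchrony rate
dyad_face_series <- function(session, cfg) {
  f10 <- lapply(session$participants, function(p) {
    u <- interpolate_uniform(p$blendshapes$timestamps, p$blendshapes$values,
                             cfg$resample_rate_hz, p$blendshapes$valid,
                             cfg$max_gap_s)
    if (isTRUE(cfg$filter_faces)) {
      u <- butterworth_zero_phase(u, cfg$filter_cutoff_hz, cfg$filter_order)
    }
    merged <- merge_blend_pairs(u)
    vars <- apply(merged$values[merged$valid, , drop = FALSE], 2, stats::var)
    keep <- which(vars >= cfg$low_variance_threshold)
    comp <- if (length(keep)) {
      rowMeans(merged$values[, keep, drop = FALSE])
    } else rowMeans(merged$values)
    downsample_series(uniform_series(comp, u$rate_hz, u$start, u$valid),
                      cfg$synchrony_rate_hz)
  })
  align_pair(f10)
}

# truncate two uniform series to their common length
align_pair <- function(pair) {
  n <- min(nrow(pair[[1]]$values), nrow(pair[[2]]$values))
  lapply(pair, function(s) {
    uniform_series(s$values[seq_len(n), , drop = FALSE], s$rate_hz, s$start,
                   s$valid[seq_len(n)])
  })
}

#' Bodily and facial synchrony of a dyad session
#'
#' `body_synchrony()` runs the full body pipeline (30 Hz interpolation,
#' 6 Hz zero-phase Butterworth filter, composite extent of movement,
#' 10 Hz downsampling, 100 s validity-screened windows) and
#' cross-correlates the two partners' composite extent series over lags up
#' to +/-5 s.  `face_synchrony()` does the analog for the composite
#' facial-movement series with lags up to +/-1 s (faces are interpolated
#' and downsampled but not low-pass filtered unless `cfg$filter_faces`).
#'
#' @param session a [dyad_session].
#' @param cfg a [pipeline_config()].
#' @return list with `summary` (a `synchrony_summary`), `wcc` (the
#'   [windowed_crosscorr]), and `plan` (the combined window plan).
#' @export
body_synchrony <- function(session, cfg = pipeline_config()) {
  pair <- dyad_extent_series(session, cfg)
  pair_synchrony(pair, cfg, cfg$body_max_lag_s)
}

#' @rdname body_synchrony
#' @export
face_synchrony <- function(session, cfg = pipeline_config()) {
  pair <- dyad_face_series(session, cfg)
  pair_synchrony(pair, cfg, cfg$face_max_lag_s)
}

pair_synchrony <- function(pair, cfg, max_lag_s) {
  plans <- lapply(pair, plan_windows, window_s = cfg$window_s,
                  min_valid_fraction = cfg$min_window_valid_fraction)
  plan <- combine_window_plans(plans[[1]], plans[[2]])
  if (!any(plan$keep)) {
    warning("no kept windows for this dyad; synchrony summary is missing")
  }
  wcc <- suppressWarnings(
    windowed_crosscorr(pair[[1]], pair[[2]], plan, max_lag_s,
                       cfg$lag_step_s, cfg$n_min_overlap))
  list(summary = summarize_synchrony(wcc), wcc = wcc, plan = plan)
}
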
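# Shared fixtures and independent oracles for the test suite.

# short-session generator config for fast unit tests
quick_synth <- function(...) {
  synth_config(duration_s = 30, dropout_fraction = 0.02, seed = 123, ...)
}

# pipeline config with short windows matching the quick sessions
quick_pipeline <- function(...) {
  pipeline_config(window_s = 10, n_min_overlap = 20, ...)
}

# Independent brute-force oracle for the windowed lagged cross-correlation:
# explicit double loop over lags and samples, Pearson by the textbook
# formula.  Deliberately shares no code with wcc_engine().
brute_wcc <- function(x, y, vx, vy, plan, rate_hz, max_lag_s, lag_step_s,
                      n_min) {
  shifts <- seq(-round(max_lag_s / lag_step_s),
                round(max_lag_s / lag_step_s)) * round(lag_step_s * rate_hz)
  kept <- which(plan$keep)
  r <- matrix(NA_real_, length(kept), length(shifts))
  for (wi in seq_along(kept)) {
    w0 <- plan$start_frame[kept[wi]]
    w1 <- min(plan$end_frame[kept[wi]], length(x), length(y))
    for (li in seq_along(shifts)) {
      s <- shifts[li]
      xs <- c(); ys <- c()
      for (k in w0:w1) {
        if (k + s >= w0 && k + s <= w1 && vx[k] && vy[k + s]) {
          xs <- c(xs, x[k]); ys <- c(ys, y[k + s])
        }
      }
      n <- length(xs)
      if (n < n_min) next
      mx <- sum(xs) / n; my <- sum(ys) / n
      sxx <- sum((xs - mx)^2); syy <- sum((ys - my)^2)
      if (sxx == 0 || syy == 0) next
      r[wi, li] <- sum((xs - mx) * (ys - my)) / sqrt(sxx * syy)
    }
  }
  r
}

# rigid transform: rotate all joints by a fixed 3-D rotation and translate
rigid_transform_skeleton <- function(values, angle = 0.7,
                                     axis = c(1, 2, 2) / 3,
                                     shift = c(0.5, -0.2, 0.3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  out <- values
  for (j in seq_len(ncol(values) / 3)) {
    cols <- (j - 1) * 3 + 1:3
    out[, cols] <- t(R %*% t(values[, cols, drop = FALSE]) + shift)
  }
  out
}

# a deterministic synthetic session pair for reuse across tests
make_test_session <- function(duration_s = 30, alpha = 0.8, lag_s = 0.3,
                              seed = 42, ...) {
  scfg <- synth_config(duration_s = duration_s, coupling_alpha = alpha,
                       coupling_lag_s = lag_s, seed = seed, ...)
  tr <- cohort_truth(1, scfg, seed)
  generate_dyad_session(tr$dyads[1, , drop = FALSE], scfg)
}
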
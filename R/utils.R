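# Internal helpers shared across modules.

# Evaluate code under a temporary RNG state so package functions are
# deterministic given `seed` without clobbering the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed k of a parent seed, kept inside 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

# Band-limited standardized Gaussian noise: white noise through a
# second-order Butterworth low-pass at `bandwidth_hz` (single pass -- phase
# is irrelevant for noise), with a warmup run-in discarded so the filter
# state is stationary, then rescaled to unit sample variance per column.
# When the bandwidth sits far below Nyquist the process is synthesized at
# a coarser rate (`coarse` frames per output frame) and upsampled.
smooth_noise <- function(n, rate_hz, bandwidth_hz, ncol = 1, coarse = 1,
                         upsample = c("linear", "step")) {
  upsample <- match.arg(upsample)
  if (coarse > 1) {
    stopifnot(bandwidth_hz < 0.4 * rate_hz / coarse)
    n2 <- ceiling(n / coarse) + 1
    y2 <- smooth_noise(n2, rate_hz / coarse, bandwidth_hz, ncol)
    if (upsample == "step") {
      y <- y2[rep(seq_len(n2), each = coarse)[seq_len(n)], , drop = FALSE]
    } else {
      pos <- (seq_len(n) - 1) / coarse + 1
      lo <- floor(pos)
      w <- pos - lo
      y <- y2[lo, , drop = FALSE] * (1 - w) +
        y2[pmin(lo + 1, n2), , drop = FALSE] * w
    }
    return(y)
  }
  bf <- signal::butter(2, 2 * bandwidth_hz / rate_hz, type = "low")
  warm <- ceiling(5 * rate_hz / bandwidth_hz)
  z <- matrix(stats::rnorm((n + warm) * ncol), n + warm, ncol)
  y <- iir_pass(bf$b, bf$a, z)[warm + seq_len(n), , drop = FALSE]
  sweep(y, 2, apply(y, 2, stats::sd), "/")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Likert discretization: round with clamping at the scale ends.
likert <- function(x, lo = 1, hi = 7) as.integer(clamp(round(x), lo, hi))

# maximum run length of TRUE in a logical vector (0 if none)
max_run <- function(flag) {
  r <- rle(flag)
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}
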
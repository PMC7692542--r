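#' Configuration of the synthetic dyad generator
#'
#' Parameters of the generative model used to emulate dyadic motion-tracking
#' sessions with known ground truth.  Partner coupling is injected into a
#' shared scalar "movement drive" process and propagated to joint
#' displacement magnitudes, so the extent-of-movement series (the input of
#' body synchrony) inherits an analytically controlled lagged correlation.
#'
#' @param duration_s session length in seconds (default 300).
#' @param rate_hz nominal sampling rate (default 30).
#' @param jitter_sd_s SD of timestamp jitter, truncated below half the
#'   nominal step so time stays strictly increasing (default 0.004 s).
#' @param dropout_fraction expected fraction of nominal frames lost to
#'   tracking dropouts (default 0.05).
#' @param dropout_mean_run mean dropout run length in frames (default 6).
#' @param coupling_alpha coupling strength `a` in \[0, 1\]: the weight of the
#'   shared drive in partner B's drive (default 0.5).
#' @param coupling_lag_s lag `tau` of partner B behind partner A in seconds
#'   (default 0.2; magnitude must stay within the 5 s body lag grid).
#' @param bandwidth_hz bandwidth of the drive and noise processes; must lie
#'   below the 6 Hz preprocessing cutoff (default 1).
#' @param drive_baseline constant floor `c` of the drive (default 0.5).
#' @param drive_sd SD of the shared band-limited process (default 0.3).
#' @param drive_noise_scale multiplier on the independent drive noises
#'   `e_A`, `e_B` (default 1; 0 makes fully coupled partners identical).
#' @param movement_gain meters of joint displacement per frame per unit
#'   drive (default 0.0025, i.e. 0.075 m/s at drive 1 and 30 Hz).
#' @param posture_radius radius (m) of the per-joint posture orbit around
#'   the template position (default 0.15).
#' @param blend_event_rate facial activation events per minute per active
#'   merged channel (default 6).
#' @param blend_amplitude typical peak blendshape activation (default 0.6).
#' @param blend_noise_sd SD of the smooth tracking noise added to every
#'   blendshape channel (default 0.005).
#' @param attraction_effect_size standardized shift of the coupled movement
#'   features between high- and low-attraction dyads (default 0).
#' @param alpha_slope,gain_slope how one SD of latent attraction moves the
#'   dyad's coupling strength / movement gain when
#'   `attraction_effect_size = 1`.
#' @param item_noise_sd SD of per-item noise on attraction items (default 0.7).
#' @param attraction_item_scale latent-attraction loading of the items
#'   (default 0.8).
#' @param observer_noise_sd SD of observer error on partner BFI ratings; 0
#'   makes impression accuracy exactly 1 (default 1.0).
#' @param observer_na_prob probability an observer item is "Cannot make
#'   judgment" (default 0.03).
#' @param seed base seed of the cohort seed hierarchy (default 1).
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(duration_s = 300, rate_hz = 30,
                         jitter_sd_s = 0.004,
                         dropout_fraction = 0.05, dropout_mean_run = 6,
                         coupling_alpha = 0.5, coupling_lag_s = 0.2,
                         bandwidth_hz = 1,
                         drive_baseline = 0.5, drive_sd = 0.3,
                         drive_noise_scale = 1,
                         movement_gain = 0.0025, posture_radius = 0.15,
                         blend_event_rate = 6, blend_amplitude = 0.6,
                         blend_noise_sd = 0.005,
                         attraction_effect_size = 0,
                         alpha_slope = 0.15, gain_slope = 0.3,
                         item_noise_sd = 0.7, attraction_item_scale = 0.8,
                         observer_noise_sd = 1.0, observer_na_prob = 0.03,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$duration_s > 0, cfg$rate_hz > 0,
            cfg$dropout_fraction >= 0, cfg$dropout_fraction < 1,
            cfg$jitter_sd_s >= 0)
  if (cfg$coupling_alpha < 0 || cfg$coupling_alpha > 1) {
    stop("coupling_alpha must lie in [0, 1]")
  }
  if (abs(cfg$coupling_lag_s) > 5) {
    stop("coupling_lag_s exceeds the 5 s body lag grid")
  }
  if (cfg$bandwidth_hz >= 6) {
    stop("bandwidth_hz must lie below the 6 Hz preprocessing cutoff")
  }
  if (cfg$jitter_sd_s >= 0.5 / cfg$rate_hz) {
    stop("jitter_sd_s must stay below half the nominal frame step")
  }
  structure(cfg, class = "synth_config")
}

#' Generate one coupled pair of movement-drive series
#'
#' The drive pair is built from a shared smooth band-limited nonnegative
#' process `g(t)`:
#' `drive_A(t) = c + g(t) + e_A(t)` and
#' `drive_B(t) = c + a * g(t - tau) + sqrt(1 - a^2) * e_B(t)`,
#' where `e_A`, `e_B` are independent smooth noises matched in variance to
#' `g`, `a` is the coupling strength and `tau` the coupling lag.  The lagged
#' correlation between the two drives therefore peaks at lag `tau`, and both
#' series are clamped to be nonnegative.
#'
#' @param cfg a [synth_config].
#' @param seed integer seed.
#' @param alpha,lag_s optional per-dyad overrides of `cfg$coupling_alpha` /
#'   `cfg$coupling_lag_s`.
#' @return list with numeric vectors `drive_a`, `drive_b` sampled on the
#'   nominal grid, and the realized `alpha` and `lag_s`.
#' @export
generate_drive_pair <- function(cfg, seed = cfg$seed,
                                alpha = cfg$coupling_alpha,
                                lag_s = cfg$coupling_lag_s) {
  stopifnot(inherits(cfg, "synth_config"))
  if (abs(lag_s) > 5) stop("coupling lag exceeds the configured 5 s maximum")
  with_seed(seed, {
    n <- floor(cfg$duration_s * cfg$rate_hz) + 1
    shift <- round(lag_s * cfg$rate_hz)
    pad <- abs(shift)
    mu_g <- 2.5 * cfg$drive_sd
    z <- smooth_noise(n + pad, cfg$rate_hz, cfg$bandwidth_hz, ncol = 3)
    g_ext <- pmax(0, mu_g + cfg$drive_sd * z[, 1])
    # B at time index k reads g at k - shift (B trails A by lag_s when > 0)
    idx_a <- seq_len(n) + max(0, shift)
    idx_b <- idx_a - shift
    sd_e <- cfg$drive_noise_scale * stats::sd(g_ext)
    e_a <- sd_e * z[seq_len(n), 2]
    e_b <- sd_e * z[seq_len(n), 3]
    list(drive_a = pmax(0, cfg$drive_baseline + g_ext[idx_a] + e_a),
         drive_b = pmax(0, cfg$drive_baseline + alpha * g_ext[idx_b] +
                          sqrt(1 - alpha^2) * e_b),
         alpha = alpha, lag_s = lag_s)
  })
}

# jittered nominal timestamps + dropout runs; returns kept frame indices and
# their timestamps
sample_timebase <- function(n, cfg) {
  grid <- (seq_len(n) - 1) / cfg$rate_hz
  bound <- 0.49 / cfg$rate_hz
  jit <- clamp(stats::rnorm(n, 0, cfg$jitter_sd_s), -bound, bound)
  jit[1] <- abs(jit[1])       # session starts at t >= 0
  ts <- grid + jit
  drop <- rep(FALSE, n)
  target <- round(cfg$dropout_fraction * n)
  guard <- 0
  while (sum(drop) < target && guard < 10 * n) {
    len <- 1 + stats::rgeom(1, 1 / cfg$dropout_mean_run)
    at <- sample.int(n, 1)
    drop[at:min(n, at + len - 1)] <- TRUE
    guard <- guard + 1
  }
  keep <- which(!drop)
  list(idx = keep, timestamps = ts[keep])
}

# one participant's skeleton values from a drive vector: each joint orbits
# its template position on a randomly oriented circle of radius
# `posture_radius`; the angular speed is drive * movement_gain / radius, so
# the per-frame displacement magnitude is proportional to the drive.  The
# orbit direction flips smoothly (a filtered-noise telegraph process).
skeleton_from_drive <- function(drive, cfg, gain = cfg$movement_gain) {
  n <- length(drive)
  joints <- upper_body_joints()
  tmpl <- default_skeleton_template()
  R <- cfg$posture_radius
  vals <- matrix(NA_real_, n, length(joints) * 3)
  colnames(vals) <- skeleton_colnames()
  sgn <- sign(smooth_noise(n, cfg$rate_hz, 0.15, ncol = length(joints),
                           coarse = 10, upsample = "step"))
  sgn[sgn == 0] <- 1
  step <- gain * drive / cfg$rate_hz / R      # |d phi| per frame
  for (j in seq_along(joints)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    phi <- cumsum(sgn[, j] * step) - sgn[1, j] * step[1]
    offs <- R * (outer(cos(phi) - 1, u) + outer(sin(phi), v))
    cols <- (j - 1) * 3 + 1:3
    vals[, cols] <- sweep(offs, 2, tmpl[j, ], "+")
  }
  vals
}

#' Generate a coupled pair of skeleton streams
#'
#' Drives the two partners' joint displacement magnitudes with
#' [generate_drive_pair()]; per frame, each joint advances along a smooth
#' orbit around its template position by an arc length proportional to the
#' participant's drive value.  Timestamps are the nominal grid plus
#' truncated jitter, with dropout runs deleted.
#'
#' @inheritParams generate_drive_pair
#' @param gain_a,gain_b per-participant movement gains (default
#'   `cfg$movement_gain`).
#' @return list of two streams (`timestamps`, `values`, `valid`) plus the
#'   drive pair used.
#' @export
generate_skeleton_pair <- function(cfg, seed = cfg$seed,
                                   alpha = cfg$coupling_alpha,
                                   lag_s = cfg$coupling_lag_s,
                                   gain_a = cfg$movement_gain,
                                   gain_b = cfg$movement_gain) {
  stopifnot(inherits(cfg, "synth_config"))
  drives <- generate_drive_pair(cfg, child_seed(seed, 1), alpha, lag_s)
  with_seed(child_seed(seed, 2), {
    streams <- list()
    gains <- c(gain_a, gain_b)
    for (p in 1:2) {
      drive <- if (p == 1) drives$drive_a else drives$drive_b
      vals <- skeleton_from_drive(drive, cfg, gains[p])
      tb <- sample_timebase(length(drive), cfg)
      streams[[p]] <- list(timestamps = tb$timestamps,
                           values = vals[tb$idx, , drop = FALSE],
                           valid = rep(TRUE, length(tb$idx)))
    }
    c(streams, list(drives = drives))
  })
}

# merged blendshape items that carry real activation events
active_blend_items <- function() {
  c("mouthSmile", "browInnerUp", "eyeBlink", "jawOpen", "browDown",
    "mouthPress", "mouthFrown", "eyeSquint", "mouthDimple", "cheekSquint",
    "noseSneer", "mouthStretch", "eyeWide", "mouthShrugUpper",
    "mouthPucker", "browOuterUp")
}

# attack-sustain-decay pulse kernel at the nominal rate
pulse_kernel <- function(rate_hz, attack_s = 0.3, sustain_s = 0.4,
                         decay_s = 0.5) {
  na <- max(1, round(attack_s * rate_hz))
  ns <- max(1, round(sustain_s * rate_hz))
  nd <- max(1, round(decay_s * rate_hz))
  c(seq(0, 1, length.out = na + 1)[-1], rep(1, ns),
    seq(1, 0, length.out = nd + 1)[-1])
}

# place events (times in frames, amplitudes) into a signal vector
events_to_signal <- function(n, at, amp, kernel) {
  x <- numeric(n + length(kernel))
  for (i in seq_along(at)) {
    idx <- at[i] + seq_along(kernel) - 1
    x[idx] <- x[idx] + amp[i] * kernel
  }
  x[seq_len(n)]
}

#' Generate a coupled pair of blendshape streams
#'
#' Sparse attack--sustain--decay activation pulses on a subset of merged
#' facial channels.  Partner B mimics each of partner A's events with
#' probability `alpha` at delay `lag_s`, and produces independent events at
#' the complementary rate, so the event rate is alpha-invariant.
#' Left/right channel pairs share a common latent activation plus small
#' asymmetry noise; all values are clipped to \[0, 1\].
#'
#' @inheritParams generate_drive_pair
#' @param rate_mult_a,rate_mult_b per-participant multipliers on the event
#'   rate.
#' @return list of two streams (`timestamps`, `values`, `valid`).
#' @export
generate_blendshape_pair <- function(cfg, seed = cfg$seed,
                                     alpha = cfg$coupling_alpha,
                                     lag_s = cfg$coupling_lag_s,
                                     rate_mult_a = 1, rate_mult_b = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(seed, {
    n <- floor(cfg$duration_s * cfg$rate_hz) + 1
    kern <- pulse_kernel(cfg$rate_hz)
    items <- active_blend_items()
    pairs <- blendshape_pairs()
    lag_f <- round(lag_s * cfg$rate_hz)
    chans <- blendshape_channels()
    sig <- list(matrix(0, n, length(chans), dimnames = list(NULL, chans)),
                matrix(0, n, length(chans), dimnames = list(NULL, chans)))
    rate_pm <- cfg$blend_event_rate * c(rate_mult_a, rate_mult_b)
    for (item in items) {
      lam_a <- rate_pm[1] * cfg$duration_s / 60
      k_a <- stats::rpois(1, lam_a)
      at_a <- sort(sample.int(max(1, n - length(kern)), k_a, replace = TRUE))
      amp_a <- cfg$blend_amplitude * stats::runif(k_a, 0.5, 1.25)
      # B: mimicry of A's events with probability alpha, plus own events
      mim <- stats::runif(k_a) < alpha
      at_b_m <- at_a[mim] + lag_f
      amp_b_m <- amp_a[mim] * stats::runif(sum(mim), 0.85, 1.15)
      ok <- at_b_m >= 1 & at_b_m <= n - length(kern)
      k_b <- stats::rpois(1, (1 - alpha) * rate_pm[2] * cfg$duration_s / 60)
      at_b_o <- sort(sample.int(max(1, n - length(kern)), k_b, replace = TRUE))
      amp_b_o <- cfg$blend_amplitude * stats::runif(k_b, 0.5, 1.25)
      at_b <- c(at_b_m[ok], at_b_o)
      amp_b <- c(amp_b_m[ok], amp_b_o)
      for (p in 1:2) {
        at <- if (p == 1) at_a else at_b
        amp <- if (p == 1) amp_a else amp_b
        latent <- events_to_signal(n, at, amp, kern)
        for (ch in pairs[[item]]) {
          sig[[p]][, ch] <- sig[[p]][, ch] + latent
        }
      }
    }
    streams <- list()
    for (p in 1:2) {
      # smooth tracking noise doubles as the left/right asymmetry noise
      noise <- cfg$blend_noise_sd *
        smooth_noise(n, cfg$rate_hz, 2, ncol = length(chans), coarse = 3)
      vals <- clamp(sig[[p]] + abs(noise), 0, 1)
      tb <- sample_timebase(n, cfg)
      streams[[p]] <- list(timestamps = tb$timestamps,
                           values = vals[tb$idx, , drop = FALSE],
                           valid = rep(TRUE, length(tb$idx)))
    }
    streams
  })
}

# smooth head-pose (degrees) and gaze (normalized screen coords) streams
generate_head_gaze <- function(cfg, seed) {
  with_seed(seed, {
    n <- floor(cfg$duration_s * cfg$rate_hz) + 1
    hp <- 4 * smooth_noise(n, cfg$rate_hz, 0.3, ncol = 3, coarse = 6)
    colnames(hp) <- c("pitch", "yaw", "roll")
    gz <- clamp(0.5 + 0.08 * smooth_noise(n, cfg$rate_hz, 0.5, ncol = 2,
                                          coarse = 6), 0, 1)
    colnames(gz) <- c("gx", "gy")
    tb1 <- sample_timebase(n, cfg)
    tb2 <- sample_timebase(n, cfg)
    list(head_pose = list(timestamps = tb1$timestamps,
                          values = hp[tb1$idx, , drop = FALSE],
                          valid = rep(TRUE, length(tb1$idx))),
         gaze = list(timestamps = tb2$timestamps,
                     values = gz[tb2$idx, , drop = FALSE],
                     valid = rep(TRUE, length(tb2$idx))))
  })
}

#' Generate one synthetic dyad session from a ground-truth row
#'
#' @param truth one row of the dyad table returned by [cohort_truth()].
#' @param cfg a [synth_config].
#' @return a [dyad_session].
#' @export
generate_dyad_session <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synth_config"), nrow(truth) == 1)
  seed <- truth$seed
  gain <- cfg$movement_gain * truth$gain_mult
  sk <- generate_skeleton_pair(cfg, child_seed(seed, 11),
                               alpha = truth$coupling_alpha,
                               lag_s = truth$coupling_lag_s,
                               gain_a = gain, gain_b = gain)
  bs <- generate_blendshape_pair(cfg, child_seed(seed, 12),
                                 alpha = truth$coupling_alpha,
                                 lag_s = truth$coupling_lag_s,
                                 rate_mult_a = truth$gain_mult,
                                 rate_mult_b = truth$gain_mult)
  recs <- lapply(1:2, function(p) {
    hg <- generate_head_gaze(cfg, child_seed(seed, 12 + p))
    participant_recording(
      participant_id = sprintf("%s_p%d", truth$dyad_id, p),
      skeleton = sk[[p]], blendshapes = bs[[p]],
      head_pose = hg$head_pose, gaze = hg$gaze)
  })
  dyad_session(truth$dyad_id, recs,
               body_visible = truth$body_visible,
               face_visible = truth$face_visible,
               gender = truth$gender, task_order = truth$task_order)
}

#' Ground-truth table for a synthetic cohort
#'
#' Draws the latent state of every dyad before any stream is generated:
#' latent attraction (standard normal), the dyad's coupling strength and
#' movement-gain multiplier (both shifted by latent attraction in proportion
#' to `attraction_effect_size`), balanced assignment to the four cells of
#' the 2x2 design, gender (constant within dyad, balanced within cell), task
#' order, and a per-dyad child seed.
#'
#' @param n_dyads number of dyads.
#' @param cfg a [synth_config].
#' @param seed cohort seed (default `cfg$seed`).
#' @return list with elements `dyads` (data frame, one row per dyad,
#'   including `attraction_class`), `participants` (data frame, one row per
#'   participant with latent attraction and valence), and `traits` (matrix
#'   of latent 15-item personality profiles, one row per participant).
#' @export
cohort_truth <- function(n_dyads, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"), n_dyads >= 1)
  with_seed(seed, {
    cells <- expand.grid(body_visible = c(TRUE, FALSE),
                         face_visible = c(TRUE, FALSE))
    cell_idx <- rep(seq_len(4), length.out = n_dyads)
    # gender alternates within each cell: equal male/female dyads when n permits
    gender <- character(n_dyads)
    for (cl in seq_len(4)) {
      pos <- which(cell_idx == cl)
      gender[pos] <- rep(c("F", "M"), length.out = length(pos))
    }
    latent <- stats::rnorm(n_dyads)
    e <- cfg$attraction_effect_size
    dyads <- data.frame(
      dyad_id = sprintf("dyad%03d", seq_len(n_dyads)),
      body_visible = cells$body_visible[cell_idx],
      face_visible = cells$face_visible[cell_idx],
      gender = gender,
      task_order = rep(c("visual_first", "semantic_first"),
                       length.out = n_dyads),
      latent_attraction = latent,
      coupling_alpha = clamp(cfg$coupling_alpha +
                               cfg$alpha_slope * e * latent, 0, 0.95),
      coupling_lag_s = cfg$coupling_lag_s,
      gain_mult = exp(cfg$gain_slope * e * latent),
      seed = vapply(seq_len(n_dyads), function(k) child_seed(seed, 100 + k),
                    integer(1)),
      stringsAsFactors = FALSE
    )
    med <- stats::median(dyads$latent_attraction)
    dyads$attraction_class <- ifelse(dyads$latent_attraction > med,
                                     "high", "low")
    pid <- as.vector(t(outer(dyads$dyad_id, 1:2, function(d, p)
      sprintf("%s_p%d", d, p))))
    lat_p <- rep(latent, each = 2) + stats::rnorm(2 * n_dyads, 0, 0.3)
    participants <- data.frame(
      participant_id = pid,
      dyad_id = rep(dyads$dyad_id, each = 2),
      gender = rep(dyads$gender, each = 2),
      latent_attraction = lat_p,
      latent_valence = 3.6 + 1.2 * lat_p + stats::rnorm(2 * n_dyads, 0, 2.5),
      stringsAsFactors = FALSE
    )
    traits <- matrix(stats::rnorm(2 * n_dyads * 15, 4, 1.2), 2 * n_dyads, 15,
                     dimnames = list(pid, sprintf("bfi%02d", 1:15)))
    list(dyads = dyads, participants = participants, traits = traits)
  })
}

#' Generate questionnaire records from ground truth
#'
#' Attraction items load on the participant's latent attraction and are
#' discretized to the 1..7 Likert scale; self BFI items discretize the
#' latent trait profile; observer BFI items (the participant's ratings of
#' their partner) add observer noise with SD `cfg$observer_noise_sd` to the
#' partner's latent profile, with occasional "Cannot make judgment" (`NA`)
#' entries; positive/negative emotion-word percentages derive from latent
#' valence.
#'
#' @param truth a [cohort_truth()] result.
#' @param cfg a [synth_config].
#' @param seed integer seed.
#' @return data frame of class `questionnaire_records`, one row per
#'   participant, with list-columns `attraction_items`, `bfi_self`,
#'   `bfi_observer` and scalar columns `pos_pct`, `neg_pct`, `gender`.
#' @export
generate_questionnaires <- function(truth, cfg, seed = cfg$seed) {
  with_seed(child_seed(seed, 31), {
    pp <- truth$participants
    np <- nrow(pp)
    partner_of <- function(i) i + ifelse(i %% 2 == 1, 1, -1)
    att <- lapply(seq_len(np), function(i) {
      likert(5 + cfg$attraction_item_scale * pp$latent_attraction[i] +
               stats::rnorm(8, 0, cfg$item_noise_sd))
    })
    bfi_self <- lapply(seq_len(np), function(i) likert(truth$traits[i, ]))
    bfi_obs <- lapply(seq_len(np), function(i) {
      x <- likert(truth$traits[partner_of(i), ] +
                    stats::rnorm(15, 0, cfg$observer_noise_sd))
      x[stats::runif(15) < cfg$observer_na_prob] <- NA_integer_
      x
    })
    neg <- clamp(abs(stats::rnorm(np, 1.2, 0.8)), 0, 20)
    pos <- clamp(neg + pp$latent_valence, 0, 100 - neg)
    out <- data.frame(participant_id = pp$participant_id,
                      dyad_id = pp$dyad_id,
                      gender = pp$gender,
                      pos_pct = pos, neg_pct = neg,
                      stringsAsFactors = FALSE)
    out$attraction_items <- att
    out$bfi_self <- bfi_self
    out$bfi_observer <- bfi_obs
    class(out) <- c("questionnaire_records", "data.frame")
    out
  })
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: ground truth, one [dyad_session] per dyad, and the
#' questionnaire records.  Sessions for large cohorts are memory-heavy;
#' [run_pipeline()] streams dyads one at a time instead.
#'
#' @inheritParams cohort_truth
#' @return list with `sessions` (list of [dyad_session]), `questionnaires`,
#'   and `truth`.
#' @export
generate_cohort <- function(n_dyads, cfg, seed = cfg$seed) {
  truth <- cohort_truth(n_dyads, cfg, seed)
  sessions <- lapply(seq_len(n_dyads), function(k) {
    generate_dyad_session(truth$dyads[k, , drop = FALSE], cfg)
  })
  quest <- generate_questionnaires(truth, cfg, seed)
  list(sessions = sessions, questionnaires = quest, truth = truth)
}
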
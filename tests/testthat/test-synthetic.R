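test_that("uncoupled drives are uncorrelated at every lag", {
  cfg <- synth_config(duration_s = 300, coupling_alpha = 0, seed = 5)
  d <- generate_drive_pair(cfg, 5)
  n <- length(d$drive_a)
  for (lag in c(-2, -0.5, 0, 0.5, 2)) {
    s <- round(lag * 30)
    r <- if (s >= 0) {
      stats::cor(d$drive_a[1:(n - s)], d$drive_b[(1 + s):n])
    } else {
      stats::cor(d$drive_a[(1 - s):n], d$drive_b[1:(n + s)])
    }
    expect_lt(abs(r), 3 / sqrt(n - abs(s)) * 3)  # wide bound: smooth series
  }
})

test_that("fully coupled noise-free drives are identical with r(0) = 1", {
  cfg <- synth_config(duration_s = 60, coupling_alpha = 1,
                      coupling_lag_s = 0, drive_noise_scale = 0, seed = 6)
  d <- generate_drive_pair(cfg, 6)
  expect_equal(d$drive_a, d$drive_b, tolerance = 1e-12)
  expect_equal(stats::cor(d$drive_a, d$drive_b), 1, tolerance = 1e-9)
})

test_that("drive pair respects nonnegativity and the lag-grid bound", {
  cfg <- synth_config(duration_s = 60, seed = 7)
  d <- generate_drive_pair(cfg, 7)
  expect_true(all(d$drive_a >= 0) && all(d$drive_b >= 0))
  expect_error(generate_drive_pair(cfg, 7, lag_s = 6),
               "exceeds the configured 5 s maximum")
  expect_error(synth_config(coupling_alpha = 1.2), "coupling_alpha")
})

test_that("drive cross-correlation peaks at the configured lag", {
  cfg <- synth_config(duration_s = 300, coupling_alpha = 0.8,
                      coupling_lag_s = 0.5, seed = 8)
  d <- generate_drive_pair(cfg, 8)
  n <- length(d$drive_a)
  lags <- seq(-2, 2, by = 0.1)
  r <- vapply(lags, function(L) {
    s <- round(L * 30)
    if (s >= 0) stats::cor(d$drive_a[1:(n - s)], d$drive_b[(1 + s):n])
    else stats::cor(d$drive_a[(1 - s):n], d$drive_b[1:(n + s)])
  }, numeric(1))
  expect_equal(lags[which.max(r)], 0.5, tolerance = 0.101)
})

test_that("zero drive leaves every joint at the template", {
  cfg <- synth_config(duration_s = 5, drive_baseline = 0, drive_sd = 0,
                      drive_noise_scale = 0, dropout_fraction = 0, seed = 9)
  sk <- generate_skeleton_pair(cfg, 9)
  tmpl <- dyadsync:::default_skeleton_template()
  for (j in upper_body_joints()) {
    cols <- paste(j, c("x", "y", "z"), sep = "_")
    expect_equal(max(abs(sweep(sk[[1]]$values[, cols], 2, tmpl[j, ]))), 0,
                 tolerance = 1e-12)
  }
})

test_that("generator streams are deterministic given (cfg, seed)", {
  cfg <- quick_synth()
  expect_identical(generate_skeleton_pair(cfg, 3),
                   generate_skeleton_pair(cfg, 3))
  expect_identical(generate_blendshape_pair(cfg, 3),
                   generate_blendshape_pair(cfg, 3))
  expect_identical(cohort_truth(6, cfg, 3), cohort_truth(6, cfg, 3))
})

test_that("dropout removes the configured fraction of nominal frames", {
  cfg <- synth_config(duration_s = 120, dropout_fraction = 0.2, seed = 10)
  sk <- generate_skeleton_pair(cfg, 10)
  n_nominal <- floor(120 * 30) + 1
  missing <- 1 - length(sk[[1]]$timestamps) / n_nominal
  expect_equal(missing, 0.2, tolerance = 0.03)
  expect_true(all(diff(sk[[1]]$timestamps) > 0))
})

test_that("blendshape streams stay in [0, 1] and clip extreme events", {
  cfg <- synth_config(duration_s = 30, blend_amplitude = 1.4,
                      blend_event_rate = 30, coupling_alpha = 1,
                      coupling_lag_s = 0, seed = 11)
  bs <- generate_blendshape_pair(cfg, 11)
  expect_true(all(bs[[1]]$values >= 0 & bs[[1]]$values <= 1))
  expect_equal(max(bs[[1]]$values), 1)  # amplitude 1.4 events clip at 1
  # zero event rate and zero noise -> all-zero channels
  cfg0 <- synth_config(duration_s = 10, blend_event_rate = 0,
                       blend_noise_sd = 0, seed = 12)
  bs0 <- generate_blendshape_pair(cfg0, 12)
  expect_true(all(bs0[[1]]$values == 0) && all(bs0[[2]]$values == 0))
})

test_that("cohort design is balanced across cells, gender, task order", {
  cfg <- quick_synth()
  tr <- cohort_truth(8, cfg, 21)
  cell <- paste(tr$dyads$body_visible, tr$dyads$face_visible)
  expect_equal(unname(table(cell)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(tr$dyads$gender)), c(4L, 4L), ignore_attr = TRUE)
  tr124 <- cohort_truth(124, cfg, 21)
  expect_equal(nrow(tr124$participants), 248)
  expect_equal(sort(unique(tr124$dyads$attraction_class)), c("high", "low"))
  # class is a deterministic function of latent attraction given the cohort
  med <- stats::median(tr124$dyads$latent_attraction)
  expect_identical(tr124$dyads$attraction_class,
                   ifelse(tr124$dyads$latent_attraction > med, "high", "low"))
})

test_that("questionnaires reflect the latent state", {
  cfg <- quick_synth(observer_noise_sd = 0, observer_na_prob = 0)
  tr <- cohort_truth(10, cfg, 31)
  q <- generate_questionnaires(tr, cfg, 31)
  # zero observer noise: observer profile identical to partner self profile
  for (i in seq_len(4)) {
    j <- i + ifelse(i %% 2 == 1, 1, -1)
    expect_identical(q$bfi_observer[[i]], q$bfi_self[[j]])
  }
  expect_true(all(unlist(q$attraction_items) %in% 1:7))
  expect_true(all(q$pos_pct + q$neg_pct <= 100))
  # zero item scale and noise: every item sits at the model's item center
  cfg0 <- quick_synth(attraction_item_scale = 0, item_noise_sd = 0)
  q0 <- generate_questionnaires(cohort_truth(4, cfg0, 32), cfg0, 32)
  expect_true(all(unlist(q0$attraction_items) == 5))
})

test_that("attraction effect size shifts item means between classes", {
  cfg <- synth_config(duration_s = 30, attraction_effect_size = 0.8,
                      seed = 33)
  # two disjoint large cohorts agree on the class difference (MC stability)
  diffs <- vapply(c(33, 34), function(s) {
    tr <- cohort_truth(100, cfg, s)
    q <- generate_questionnaires(tr, cfg, s)
    att <- vapply(q$attraction_items, mean, numeric(1))
    cls <- rep(tr$dyads$attraction_class, each = 2)
    mean(att[cls == "high"]) - mean(att[cls == "low"])
  }, numeric(1))
  expect_gt(min(diffs), 0.5)
  expect_lt(abs(diffs[1] - diffs[2]), 0.3)
})

test_that("higher coupling yields higher downstream synchrony", {
  means <- vapply(c(0, 0.4, 0.8), function(a) {
    vals <- vapply(1:3, function(k) {
      ses <- make_test_session(duration_s = 110, alpha = a, lag_s = 0,
                               seed = 40 + k)
      body_synchrony(ses)$summary$max_r
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(means[1] < means[2] && means[2] < means[3])
})
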
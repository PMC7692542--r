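test_that("stat block matches closed forms and a hand-computed series", {
  # constant series
  expect_equal(unname(stat_block(rep(2.5, 50), rate_hz = 30)),
               c(2.5, 0, 0, 0, 0, 0))
  # linear ramp with slope m (per second)
  m <- 0.7
  ramp <- m * (0:99) / 30
  sb <- stat_block(ramp, rate_hz = 30)
  expect_equal(unname(sb["grad_mean"]), m, tolerance = 1e-9)
  expect_equal(unname(sb["grad_sd"]), 0, tolerance = 1e-9)
  expect_equal(unname(sb["grad2_max"]), 0, tolerance = 1e-6)
  # hand series [0, 1, 3, 2, 2] at 1 Hz:
  # gradient [1, 2, -1, 0], second gradient [1, -3, 1]
  sb2 <- stat_block(c(0, 1, 3, 2, 2), rate_hz = 1)
  expect_equal(unname(sb2["mean"]), 1.6)
  expect_equal(unname(sb2["sd"]), sqrt(sum((c(0, 1, 3, 2, 2) - 1.6)^2) / 4))
  expect_equal(unname(sb2["grad_mean"]), 0.5)
  expect_equal(unname(sb2["grad_sd"]), sqrt(sum((c(1, 2, -1, 0) - 0.5)^2) / 3))
  expect_equal(unname(sb2["grad_max"]), 2)
  expect_equal(unname(sb2["grad2_max"]), 1)
  # fewer than 3 valid frames -> all six missing
  expect_true(all(is.na(stat_block(c(1, 2), rate_hz = 30))))
  # gradients only span jointly valid frames
  v <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  sb3 <- stat_block(c(0, 1, 100, 2, 2), valid = v, rate_hz = 1)
  expect_equal(unname(sb3["grad_max"]), 1)  # the 100 never enters
})

test_that("feature names are unique and total the documented enumeration", {
  nms <- candidate_feature_names()
  expect_equal(anyDuplicated(nms), 0)
  # independent count over the documented blocks
  expected <- 5 * (1 + 17 + 10 + 1 + 52) +  # synchrony summaries
    6 * 17 * 3 +                            # per-coordinate statistics
    2 * 17 +                                # displacement per 0.1 s
    4 * 10 +                                # joint-angle statistics
    4 * 3 +                                 # head rotation
    2 * 34 +                                # merged blendshape items
    2 * 2 +                                 # gaze
    2 * 4 +                                 # tracking validity
    1                                       # gender
  expect_equal(n_candidate_features(), expected)
  expect_equal(length(nms), expected)
})

test_that("the data dictionary covers every candidate feature once", {
  dict <- feature_dictionary()
  expect_identical(dict$name, candidate_feature_names())
  expect_false(any(dict$units == "" | dict$definition == ""))
  expect_equal(sum(dict$block == "synchrony"), 405)
  expect_equal(sum(dict$block == "joint_coordinate_stats"), 306)
})

test_that("dyad members share the synchrony block; vectors are reproducible", {
  ses <- make_test_session(duration_s = 110, seed = 81)
  f1 <- participant_features(ses, 1)
  f2 <- participant_features(ses, 2)
  expect_identical(names(f1), candidate_feature_names())
  sync_cols <- grep("^sync_", names(f1), value = TRUE)
  expect_identical(f1[sync_cols], f2[sync_cols])
  expect_identical(f1["gender_female"], f2["gender_female"])
  # participant-specific blocks differ
  expect_false(identical(f1[grep("^pos_", names(f1))],
                         f2[grep("^pos_", names(f2))]))
  # bit-identical on recomputation
  expect_identical(f1, participant_features(ses, 1))
})

test_that("a static participant yields zero motion and missing synchrony", {
  scfg <- synth_config(duration_s = 110, drive_baseline = 0, drive_sd = 0,
                       drive_noise_scale = 0, blend_event_rate = 0,
                       blend_noise_sd = 0, dropout_fraction = 0, seed = 82)
  tr <- cohort_truth(1, scfg, 82)
  ses <- generate_dyad_session(tr$dyads[1, , drop = FALSE], scfg)
  f <- participant_features(ses, 1)
  expect_equal(unname(f["disp10_Head_mean"]), 0)
  expect_equal(unname(f["pos_Head_x_grad_max"]), 0, tolerance = 1e-9)
  # constant extent series has no defined correlation: missing, not zero
  expect_true(is.na(f["sync_body_composite_mean"]))
  expect_true(is.na(f["sync_face_composite_mean"]))
})

test_that("motion features are rigid-transform invariant, positions not", {
  ses <- make_test_session(duration_s = 110, seed = 83)
  f <- participant_features(ses, 1)
  moved <- ses
  for (p in 1:2) {
    moved$participants[[p]]$skeleton$values <-
      rigid_transform_skeleton(moved$participants[[p]]$skeleton$values)
  }
  fm <- participant_features(moved, 1)
  inv <- grep("^(sync_body|sync_joint|sync_angle|disp10_|angle_)",
              names(f), value = TRUE)
  expect_equal(fm[inv], f[inv], tolerance = 1e-6)
  pos_mean <- grep("^pos_.*_mean$", names(f), value = TRUE)
  expect_false(isTRUE(all.equal(fm[pos_mean], f[pos_mean],
                                tolerance = 1e-3)))
})

test_that("feature table assembly: shape, dropping, imputation", {
  scfg <- synth_config(duration_s = 110, seed = 84)
  cohort <- generate_cohort(4, scfg, 84)
  outcomes <- outcome_table(cohort$questionnaires)
  feats <- list()
  for (ses in cohort$sessions) {
    prep <- lapply(ses$participants, dyadsync:::preprocess_participant,
                   cfg = pipeline_config())
    sync <- dyadsync:::dyad_synchrony_features(prep[[1]], prep[[2]],
                                               pipeline_config())
    for (p in 1:2) {
      feats[[ses$participants[[p]]$participant_id]] <-
        participant_features(ses, p, prep = prep, sync = sync)
    }
  }
  tab <- build_feature_table(feats, outcomes)
  expect_equal(nrow(tab), 8)
  expect_s3_class(tab, "feature_table")
  # a column missing everywhere is dropped and reported
  feats2 <- lapply(feats, function(f) { f["gaze_gx_mean"] <- NA; f })
  tab2 <- build_feature_table(feats2, outcomes)
  expect_true("gaze_gx_mean" %in% attr(tab2, "dropped_features"))
  expect_false("gaze_gx_mean" %in% attr(tab2, "feature_names"))
  # imputation fills a sporadic hole with the median, others bit-identical
  feats3 <- feats
  feats3[[1]]["gaze_gx_mean"] <- NA
  tab3 <- build_feature_table(feats3, outcomes)
  others <- setdiff(seq_len(8), 1)
  expect_identical(tab3$gaze_gy_mean, tab$gaze_gy_mean)
  expect_equal(tab3$gaze_gx_mean[others], tab$gaze_gx_mean[others])
  expect_equal(tab3$gaze_gx_mean[1],
               stats::median(tab$gaze_gx_mean[others]))
  expect_equal(attr(tab3, "n_imputed"), attr(tab, "n_imputed") + 1L)
  # duplicate participant ids are rejected
  dup <- feats
  names(dup)[2] <- names(dup)[1]
  expect_error(build_feature_table(dup, outcomes), "duplicate")
})
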
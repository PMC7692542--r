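# skeleton series where one joint moves at constant velocity along x
make_moving_skeleton <- function(n = 90, rate = 30, v = 0.30,
                                 joint = "HandRight") {
  tmpl <- dyadsync:::default_skeleton_template()
  vals <- matrix(rep(t(tmpl), each = n), n, 51)
  colnames(vals) <- dyadsync:::skeleton_colnames()
  vals[, paste0(joint, "_x")] <-
    vals[, paste0(joint, "_x")] + v * (seq_len(n) - 1) / rate
  uniform_series(vals, rate)
}

test_that("per-frame displacement matches closed forms", {
  s <- make_moving_skeleton(v = 0.30)
  ext <- frame_displacement(s)
  # 0.30 m/s at 30 Hz -> 0.010 m per frame
  expect_equal(unname(ext$values[5, "HandRight"]), 0.010, tolerance = 1e-12)
  expect_false(ext$valid[1])  # first frame has no predecessor
  # static joints show zero displacement
  expect_equal(max(ext$values[-1, "Head"]), 0, tolerance = 1e-12)
  # 3-4-5 triangle: (0.003, 0.004, 0) step -> 0.005
  vals <- s$values
  vals[2, c("Head_x", "Head_y")] <- vals[2, c("Head_x", "Head_y")] +
    c(0.003, 0.004)
  e2 <- frame_displacement(uniform_series(vals, 30))
  expect_equal(unname(e2$values[2, "Head"]), 0.005, tolerance = 1e-12)
})

test_that("composite extent averages the 17 joints", {
  s <- make_moving_skeleton(v = 0.30)
  be <- body_extent(s)
  expect_equal(unname(be$per_joint["HandRight"]), 0.010, tolerance = 1e-12)
  expect_equal(be$composite, 0.010 / 17, tolerance = 1e-12)
  # all joints moving identically -> composite equals the common value
  tmpl <- dyadsync:::default_skeleton_template()
  n <- 60
  vals <- matrix(rep(t(tmpl), each = n), n, 51)
  colnames(vals) <- dyadsync:::skeleton_colnames()
  vals[, seq(1, 51, by = 3)] <- vals[, seq(1, 51, by = 3)] +
    0.30 * (seq_len(n) - 1) / 30
  expect_equal(body_extent(uniform_series(vals, 30))$composite, 0.010,
               tolerance = 1e-12)
  # zero valid frames -> error
  bad <- uniform_series(vals, 30, valid = rep(FALSE, n))
  expect_error(body_extent(bad), "no valid frames")
})

test_that("composite extent tracks the generator's analytic expectation", {
  # joints orbit at arc speed gain * drive / rate, so mean displacement per
  # frame is gain * mean(drive) / rate (to small-angle accuracy)
  cfg <- synth_config(duration_s = 60, dropout_fraction = 0,
                      jitter_sd_s = 0, seed = 17)
  sk <- generate_skeleton_pair(cfg, 17)
  drive <- sk$drives$drive_a
  s <- uniform_series(sk[[1]]$values, 30)
  be <- body_extent(s)
  expected <- cfg$movement_gain * mean(drive[-1]) / 30
  expect_equal(be$composite, expected, tolerance = 0.02 * expected)
})

test_that("face extent merges pairs, screens variance, averages the rest", {
  n <- 200
  chans <- blendshape_channels()
  vals <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  vals[, "mouthSmileLeft"] <- 0.4
  vals[, "mouthSmileRight"] <- 0.6
  vals[, "jawOpen"] <- rep(c(0.1, 0.5), length.out = n)
  s <- uniform_series(vals, 30)
  fe <- face_extent(s, low_variance_threshold = 0)
  expect_equal(unname(fe$per_channel["mouthSmile"]), 0.5, tolerance = 1e-12)
  # with a positive threshold the constant smile items are excluded
  fe2 <- face_extent(s, low_variance_threshold = 1e-4)
  expect_false("mouthSmile" %in% names(fe2$per_channel))
  expect_equal(fe2$composite, mean(c(0.1, 0.5)), tolerance = 1e-12)
  expect_true("mouthSmile" %in% fe2$excluded)
  # all channels constant -> error naming the threshold
  expect_error(face_extent(uniform_series(vals * 0, 30), 1e-4), "1e-04")
})

test_that("hand-built three-channel composite matches manual arithmetic", {
  n <- 100
  chans <- blendshape_channels()
  vals <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  vals[, "jawOpen"] <- rep(c(0.2, 0.4), length.out = n)    # mean 0.3
  vals[, "cheekPuff"] <- rep(c(0.0, 0.8), length.out = n)  # mean 0.4
  vals[, "tongueOut"] <- 0.9                               # flat: excluded
  fe <- face_extent(uniform_series(vals, 30), 1e-4)
  expect_equal(fe$composite, mean(c(0.3, 0.4)), tolerance = 1e-12)
})

test_that("joint angles hit the textbook configurations", {
  tmpl <- dyadsync:::default_skeleton_template()
  vals <- matrix(rep(t(tmpl), each = 2), 2, 51)
  colnames(vals) <- dyadsync:::skeleton_colnames()
  # collinear arm: shoulder-elbow-wrist along one line -> 180 degrees
  vals[, "ShoulderRight_x"] <- 0.2; vals[, "ShoulderRight_y"] <- 1.4
  vals[, "ShoulderRight_z"] <- 2
  vals[, "ElbowRight_x"] <- 0.5; vals[, "ElbowRight_y"] <- 1.4
  vals[, "ElbowRight_z"] <- 2
  vals[, "WristRight_x"] <- 0.8; vals[, "WristRight_y"] <- 1.4
  vals[, "WristRight_z"] <- 2
  # right angle at the left elbow: bones along -x and -y
  vals[, "ShoulderLeft_x"] <- -0.5; vals[, "ShoulderLeft_y"] <- 1.4
  vals[, "ShoulderLeft_z"] <- 2
  vals[, "ElbowLeft_x"] <- -0.2; vals[, "ElbowLeft_y"] <- 1.4
  vals[, "ElbowLeft_z"] <- 2
  vals[, "WristLeft_x"] <- -0.2; vals[, "WristLeft_y"] <- 1.1
  vals[, "WristLeft_z"] <- 2
  ang <- joint_angles(uniform_series(vals, 30))
  expect_equal(unname(ang$values[1, "ElbowRightAngle"]), 180,
               tolerance = 1e-9)
  expect_equal(unname(ang$values[1, "ElbowLeftAngle"]), 90,
               tolerance = 1e-9)
  expect_true(all(ang$values >= 0 & ang$values <= 180, na.rm = TRUE))
  expect_equal(ncol(ang$values), 10)
  # zero-length bone -> angle invalid for that frame
  vals2 <- vals
  vals2[1, c("WristRight_x", "WristRight_y", "WristRight_z")] <-
    vals2[1, c("ElbowRight_x", "ElbowRight_y", "ElbowRight_z")]
  a2 <- joint_angles(uniform_series(vals2, 30))
  expect_true(is.na(a2$values[1, "ElbowRightAngle"]))
  expect_false(is.na(a2$values[2, "ElbowRightAngle"]))
})

test_that("extent and angles are rigid-transform invariant; extent scales", {
  ses <- make_test_session(duration_s = 10, seed = 55)
  sk <- ses$participants[[1]]$skeleton
  s <- interpolate_uniform(sk$timestamps, sk$values, 30, sk$valid)
  ext <- frame_displacement(s)
  ang <- joint_angles(s)
  moved <- uniform_series(rigid_transform_skeleton(s$values), 30,
                          valid = s$valid)
  ext_m <- frame_displacement(moved)
  ang_m <- joint_angles(moved)
  expect_lt(max(abs(ext$values - ext_m$values), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(ang$values - ang_m$values), na.rm = TRUE), 1e-6)
  # uniform scaling scales displacements linearly, leaves angles alone
  scaled <- uniform_series(s$values * 3, 30, valid = s$valid)
  expect_equal(frame_displacement(scaled)$values, ext$values * 3,
               tolerance = 1e-9)
  expect_lt(max(abs(joint_angles(scaled)$values - ang$values),
                na.rm = TRUE), 1e-6)
})
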
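test_that("body_com reduces to segment_com for a single segment", {
  tab <- default_segment_table("male")[1, ]
  model <- body_model("male", 80, segments = tab)
  pose <- matrix(0, 25, 3)
  pose[9, ] <- c(0, 0, 0)    # mid hip (index 8)
  pose[2, ] <- c(0, 55, -3)  # neck (index 1)
  s <- body_com(pose, model)
  expect_equal(s$com, segment_com(pose[9, ], pose[2, ], tab$k))
  expect_equal(s$pelvis, pose[9, ])
})

test_that("two equal-mass midpoint segments average their midpoints", {
  tab <- default_segment_table("male")[c(3, 4), ]  # both upper arms
  tab$mass_fraction <- c(0.1, 0.1)
  tab$k <- 0.5
  model <- body_model("male", 70, segments = tab)
  pose <- matrix(0, 25, 3)
  pose[3, ] <- c(-18, 50, 0); pose[4, ] <- c(-20, 20, 5)   # right arm
  pose[6, ] <- c(18, 50, 0);  pose[7, ] <- c(22, 24, -3)   # left arm
  pose[9, ] <- c(0, 0, 0)
  s <- body_com(pose, model)
  mids <- rbind((pose[3, ] + pose[4, ]) / 2, (pose[6, ] + pose[7, ]) / 2)
  expect_equal(s$com, colMeans(mids))
})

test_that("a three-segment toy matches the brute-force point-mass oracle", {
  tab <- data.frame(name = c("a", "b", "c"), side = "mid",
                    proximal_idx = c(8L, 1L, 2L), distal_idx = c(1L, 0L, 3L),
                    mass_fraction = c(2, 3, 5) / 100, k = c(0.43, 0.436, 0.63))
  model <- body_model("male", 100, segments = tab)  # masses 2, 3, 5 kg
  pose <- matrix(0, 25, 3)
  pose[9, ] <- c(0, 0, 0); pose[2, ] <- c(1, 52, -4)
  pose[1, ] <- c(2, 70, 6); pose[3, ] <- c(-17, 49, -2); pose[4, ] <- c(-20, 18, 9)
  s <- body_com(pose, model)
  expect_lt(max(abs(s$com - brute_force_com(pose, model, n = 1e5))), 1e-6)
})

test_that("body_com equals the brute-force oracle on randomized poses/models", {
  set.seed(2024)
  for (i in 1:40) {
    model <- random_body_model()
    pose <- random_pose()
    s <- body_com(pose, model)
    expect_lt(max(abs(s$com - brute_force_com(pose, model))), 1e-6)
    # convexity: the CoM stays inside the bounding box of the used keypoints
    used <- unique(c(model$segments$proximal_idx, model$segments$distal_idx)) + 1L
    expect_true(all(s$com >= apply(pose[used, ], 2, min) - 1e-9 &
                      s$com <= apply(pose[used, ], 2, max) + 1e-9))
  }
})

test_that("frames missing required keypoints yield missing samples, not guesses", {
  model <- body_model("female", 56)
  pose <- random_pose()
  valid <- rep(TRUE, 25); valid[5] <- FALSE  # right wrist (index 4), needed
  s <- body_com(pose, model, valid = valid)
  expect_false(s$valid)
  expect_true(4L %in% s$missing_keypoints)
  expect_true(is.na(s$dY))
  # an unused keypoint (left heel) can be missing without harm
  valid <- rep(TRUE, 25); valid[22] <- FALSE
  expect_true(body_com(pose, model, valid = valid)$valid)
})

test_that("displacement axes follow the configured sign conventions", {
  expect_equal(displacement_axes(c(0, 0, 0), c(0, 0, 0)), c(dY = 0, dZ = 0))
  # CoM 10 cm above the pelvis: downward-positive dY = -10
  expect_equal(displacement_axes(c(0, 10, 0), c(0, 0, 0))[["dY"]], -10)
  # CoM 5 cm anterior: posterior-positive dZ = -5
  expect_equal(displacement_axes(c(0, 0, 5), c(0, 0, 0))[["dZ"]], -5)
  expect_equal(displacement_axes(c(0, 10, 5), c(0, 0, 0),
                                 down_positive = FALSE,
                                 posterior_positive = FALSE),
               c(dY = 10, dZ = 5))
})

test_that("endurance-time windows average analytic signals exactly", {
  # constant signal: every window mean equals the constant
  t <- seq(0, 120, by = 1 / 30)
  s <- data.frame(time = t, dY = 3, dZ = -1)
  w <- et_windows(s, et_min = 2, window_s = 5)
  expect_equal(w$dY, rep(3, 3))
  expect_equal(w$dZ, rep(-1, 3))
  # linear ramp dY(t) = t: each window mean is the mean of its sample times
  s2 <- data.frame(time = t, dY = t, dZ = 0)
  w2 <- et_windows(s2, et_min = 2, window_s = 5)
  b <- et_window_bounds(2, 5)
  for (i in 1:3) {
    sel <- t >= b[i, "t0"] - 1e-9 & t <= b[i, "t1"] + 1e-9
    expect_equal(w2$dY[i], mean(t[sel]))
    # and matches the analytic interval midpoint within one sample spacing
    expect_lt(abs(w2$dY[i] - mean(b[i, ])), 1 / 30)
  }
})

test_that("a 14.93 min trial sampled at 30 Hz puts 150 frames in each window", {
  et <- 14.93
  t <- seq(0, et * 60, by = 1 / 30)
  t <- t[t < et * 60]  # half-open sampling grid
  s <- data.frame(time = t, dY = 1, dZ = 1)
  w <- et_windows(s, et_min = et, window_s = 5)
  expect_equal(w$n_frames, c(150L, 150L, 150L), tolerance = 1)
})

test_that("window means are invariant to sample order and flag empty windows", {
  set.seed(8)
  t <- seq(0, 60, by = 0.1)
  s <- data.frame(time = t, dY = rnorm(length(t)), dZ = rnorm(length(t)))
  w1 <- et_windows(s, et_min = 1)
  w2 <- et_windows(s[sample(nrow(s)), ], et_min = 1)
  expect_equal(w1, w2)
  # samples stop before the end window: it is missing, with a warning
  s3 <- s[s$time < 45, ]
  expect_warning(w3 <- et_windows(s3, et_min = 1), "end")
  expect_true(is.na(w3$dY[3])); expect_equal(w3$n_frames[3], 0L)
})
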
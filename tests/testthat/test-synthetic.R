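test_that("cohorts reproduce the configured anthropometrics", {
  cfg <- generator_config(n_male = 10000, n_female = 0, seed = 21)
  coh <- generate_cohort(cfg)
  # truncation at the cohort min/max shifts the male height mean by < 1 cm
  expect_lt(abs(mean(coh$height_m) - 1.83), 0.01)
  expect_lt(abs(mean(coh$mass_kg) - 82.92), 1.0)
  expect_true(all(coh$height_m >= 1.54 & coh$height_m <= 1.95))

  # degenerate draw: zero SDs put every participant at the mean
  a <- default_anthropometrics()
  a[, grep("_sd$", names(a))] <- 0
  cfg0 <- generator_config(n_male = 5, n_female = 5, anthropometrics = a)
  coh0 <- generate_cohort(cfg0)
  expect_equal(coh0$height_m, rep(c(1.83, 1.66), c(5, 5)))
  expect_equal(coh0$torso_vol_dm3[1:5], rep(44.71, 5))

  # determinism: identical seed, identical cohort
  cfg1 <- generator_config(seed = 77)
  expect_identical(generate_cohort(cfg1), generate_cohort(cfg1))
})

test_that("noiseless effect injection shows the gravity effect exactly", {
  eff <- default_effect_table()
  eff$residual_sd <- 0
  cfg <- generator_config(effects = eff, primary_axis = "dZ", fps = 5, seed = 3)
  coh <- generate_cohort(cfg)
  part <- coh[coh$sex == "female", ][1, ]
  off <- study_offsets(cfg, "female")
  t_lo <- generate_trial(part, "1/6g", "static", 1, cfg, "lo", off)
  t_hi <- generate_trial(part, "1g", "static", 1, cfg, "hi", off)
  beta_g <- eff$beta_g[eff$sex == "female" & eff$axis == "dZ"]
  for (w in c("start", "middle", "end")) {
    expect_false(t_lo$windows[[w]]$clamped || t_hi$windows[[w]]$clamped)
    expect_equal(t_hi$windows[[w]]$realized[["dZ"]] -
                   t_lo$windows[[w]]$realized[["dZ"]], beta_g,
                 tolerance = 1e-6)
  }
})

test_that("posing to a target then measuring recovers the target", {
  tmpl <- seated_template(1.75)
  model <- body_model("male", 75)
  for (primary in c("dY", "dZ")) {
    span <- pose_reach(tmpl, model, primary)
    set.seed(31)
    for (tgt_p in seq(span[1] + 1, span[2] - 1, length.out = 7)) {
      target <- c(dY = 0, dZ = 0)
      target[primary] <- tgt_p
      target[setdiff(c("dY", "dZ"), primary)] <- runif(1, -30, 30)
      sol <- solve_pose(tmpl, model, target, primary)
      meas <- body_com(pose_skeleton(tmpl, sol$theta, arm_dir(sol$phi)), model)
      expect_lt(abs(meas[[primary]] - tgt_p), 1e-6)
    }
    expect_error(solve_pose(tmpl, model,
                            c(dY = span[1] - 50, dZ = span[1] - 50), primary),
                 "unreachable")
  }
})

test_that("dynamic trials respect the hand-speed cap", {
  cfg <- generator_config(fps = 30, seed = 5, pose_jitter_sd = 0)
  coh <- generate_cohort(cfg)
  part <- coh[coh$sex == "male", ][1, ]
  tr <- generate_trial(part, "1/6g", "dynamic", 1, cfg, "dyn")
  for (w in tr$windows) {
    wrists <- t(vapply(w$frames, function(P) P[5, ], numeric(3)))  # r_wrist
    speeds <- sqrt(rowSums(diff(wrists)^2)) * cfg$fps
    expect_lte(max(speeds), cfg$max_hand_speed_cms + 1e-6)
    expect_gt(max(speeds), 0)  # the forearm does move
  }
})

test_that("window means reproduce the realized targets through the full chain", {
  cfg <- tiny_config(seed = 13, pixel_noise_sd = 0, dropout_prob = 0)
  st <- generate_study(cfg, sexes = "male")
  rows <- analyze_study(st)
  m <- merge(rows, st$truth, by = c("trial", "window"))
  expect_gt(nrow(m), 0)
  expect_lt(max(abs(m$dY - m$dY_realized)), 1e-6)
  expect_lt(max(abs(m$dZ - m$dZ_realized)), 1e-6)
})

test_that("rendered views survive a camera blackout at min_views = 2", {
  cfg <- tiny_config(seed = 19, dropout_prob = 0)
  coh <- generate_cohort(cfg)
  tr <- generate_trial(coh[1, ], "1g", "static", 1, cfg, "blk")
  views <- render_views(tr, cfg)
  views[[1]] <- lapply(views[[1]], function(p) { p[, 3] <- 0; p })  # camera 1 dark
  f <- triangulate_pose(cfg$rig, lapply(views, `[[`, 1L))
  expect_true(all(f$valid))
  # two-view reconstruction is less precise than three-view but stays
  # centimetre-scale at 1 px noise
  expect_lt(max(abs(f$points - tr$windows$start$frames[[1]])), 2)
})

test_that("study trees on disk round-trip the rendered keypoints exactly", {
  cfg <- generator_config(n_rows = c(male = 3, female = 0), fps = 5, seed = 23)
  dir <- tempfile("study")
  st <- generate_study(cfg, dir = dir, sexes = "male")
  tr <- st$trials[[1]]
  back <- read_openpose_frames(file.path(dir, tr$trial_id, "cam2"))
  expect_length(back, length(tr$views[[2]]))
  for (j in seq_along(back)) {
    expect_identical(unname(back[[j]]), unname(tr$views[[2]][[j]]))
  }
  expect_true(file.exists(file.path(dir, "calib.yaml")))
  meta <- read.csv(file.path(dir, "meta.csv"))
  expect_equal(nrow(meta), 1L)
})

test_that("studies are deterministic and sized to the configured row counts", {
  cfg <- tiny_config(seed = 29)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_identical(st1$truth, st2$truth)
  expect_identical(st1$trials[[1]]$views[[1]][[1]],
                   st2$trials[[1]]$views[[1]][[1]])
  rows <- analyze_study(st1)
  expect_equal(sum(rows$sex == "male"), 12L)
  expect_equal(sum(rows$sex == "female"), 12L)
})

test_that("statistics-level rows follow the configured linear model", {
  cfg <- generator_config(n_rows = c(male = 6000, female = 0), seed = 37)
  rows <- generate_design_rows(cfg, "male")
  expect_equal(nrow(rows), 6000L)
  eff <- default_effect_table()
  e <- eff[eff$sex == "male" & eff$axis == "dY", ]
  for (g in 0:1) {
    sel <- rows$g_level == g & rows$task_dynamic == 0
    mu <- e$constant + e$beta_g * g
    expect_lt(abs(mean(rows$dY[sel]) - mu), 4 * e$residual_sd / sqrt(sum(sel)))
    expect_lt(abs(sd(rows$dY[sel]) - e$residual_sd), 0.5)
  }
})
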
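effect_row <- function(effects, sx, axis) {
  r <- effects[effects$sex == sx & effects$axis == axis, ]
  if (nrow(r) != 1L) stop("no effect parameters for ", sx, " / ", axis)
  r
}

mean_template <- function(config, sx) {
  a <- config$anthropometrics
  p <- a[a$sex == sx, ]
  list(tmpl = seated_template(p$height_mean, p$upper_arm_len_mean,
                              p$forearm_len_mean),
       model = body_model(sx, p$mass_mean))
}

#' Study-level neutral posture offsets
#'
#' The window targets drawn from the effect model are displacements relative
#' to a neutral seated posture; this computes, from the sex-mean template, the
#' absolute pelvis-relative displacement of that neutral reference: the
#' midpoint of the reachable primary-axis span, and the secondary-axis value
#' the template takes there. Offsets shift only the regression constant, never
#' the gravity/task coefficients or the residual noise.
#'
#' @param config a [generator_config()].
#' @param sex `"male"` or `"female"`.
#' @return `list(offset = c(dY, dZ), span = c(lo, hi))` (cm; span is for the
#'   configured primary axis).
#' @export
study_offsets <- function(config, sex) {
  mt <- mean_template(config, sex)
  primary <- config$primary_axis
  span <- pose_reach(mt$tmpl, mt$model, primary)
  c_p <- mean(span)
  tb <- theta_bounds(primary)
  phi0 <- if (primary == "dY") 0.6 else 0
  f <- function(th) pose_displacement(mt$tmpl, mt$model, th, phi0)[[primary]] - c_p
  th0 <- stats::uniroot(f, tb, tol = 1e-10)$root
  d0 <- pose_displacement(mt$tmpl, mt$model, th0, phi0)
  offset <- d0
  offset[primary] <- c_p
  list(offset = offset, span = span)
}

trial_cells <- function() {
  expand.grid(gravity = c("1/6g", "1g"), task = c("static", "dynamic"),
              load_kg = c(1, 3), stringsAsFactors = FALSE)
}

draw_et <- function(config, sx, gravity, task, load_kg) {
  et <- config$et_table
  r <- et[et$task == task & et$gravity == gravity & et$load_kg == load_kg, ]
  if (nrow(r) != 1L) stop("no endurance-time entry for the requested cell")
  mu <- if (sx == "male") r$et_male else r$et_female
  if (config$et_cv == 0) return(mu)
  sdl <- sqrt(log(1 + config$et_cv^2))
  stats::rlnorm(1, log(mu) - sdl^2 / 2, sdl)
}

#' Generate one synthetic trial
#'
#' Draws the endurance time and the per-window displacement targets from the
#' configured effect model, solves the seated pose for each analysis window
#' (the primary axis exactly, the secondary axis best-effort), and synthesizes
#' the 3D keypoint frames of the three windows: the static task holds the
#' solved pose with small mean-centred jitter; the dynamic task additionally
#' oscillates the forearm over one cycle per window with the wrist speed
#' capped at the configured maximum. Window means of the primary-axis
#' displacement reproduce the (clamped) targets exactly because the CoM is
#' linear in keypoint positions and both jitter and oscillation are
#' mean-centred per window.
#'
#' @param participant one row of [generate_cohort()].
#' @param gravity `"1/6g"` or `"1g"`.
#' @param task `"static"` or `"dynamic"`.
#' @param load_kg held load, kg.
#' @param config a [generator_config()].
#' @param trial_id identifier used for the per-trial random stream.
#' @param offsets optional result of [study_offsets()] (computed if missing).
#' @return List of class `synthetic_trial`: `meta`, `et_min`, `windows` (each
#'   with `times`, `frames` (list of 25x3 matrices), solved pose and the
#'   drawn/realized ground-truth values) and `truth` (one data-frame row per
#'   window).
#' @export
generate_trial <- function(participant, gravity, task, load_kg, config,
                           trial_id = "trial", offsets = NULL) {
  sx <- participant$sex
  if (is.null(offsets)) offsets <- study_offsets(config, sx)
  primary <- config$primary_axis
  secondary <- setdiff(c("dY", "dZ"), primary)
  eff <- list(dY = effect_row(config$effects, sx, "dY"),
              dZ = effect_row(config$effects, sx, "dZ"))
  tmpl <- seated_template(participant$height_m, participant$upper_arm_len_m,
                          participant$forearm_len_m)
  model <- body_model(sx, participant$mass_kg)
  span <- pose_reach(tmpl, model, primary)
  margin <- 0.02 * diff(span)
  clamp_lo <- span[1] + margin; clamp_hi <- span[2] - margin

  set.seed(derive_seed(config$seed, "trial", trial_id))
  et_min <- draw_et(config, sx, gravity, task, load_kg)
  bounds <- et_window_bounds(et_min, config$window_s)
  g_ind <- as.integer(gravity == "1g")
  t_ind <- as.integer(task == "dynamic")

  windows <- list()
  truth <- list()
  for (w in rownames(bounds)) {
    mu <- vapply(c("dY", "dZ"), function(ax) {
      e <- eff[[ax]]
      e$constant + e$beta_g * g_ind + e$beta_task * t_ind
    }, numeric(1))
    eps <- vapply(c("dY", "dZ"), function(ax)
      stats::rnorm(1, 0, eff[[ax]]$residual_sd), numeric(1))
    model_val <- mu + eps
    target <- model_val + offsets$offset[c("dY", "dZ")]
    clamped <- FALSE
    if (target[primary] < clamp_lo || target[primary] > clamp_hi) {
      target[primary] <- min(max(target[primary], clamp_lo), clamp_hi)
      clamped <- TRUE
    }

    t0 <- bounds[w, "t0"]; t1 <- bounds[w, "t1"]
    nf <- max(2L, floor((t1 - t0) * config$fps))
    times <- t0 + (seq_len(nf) - 1L) / config$fps
    if (t_ind == 1L) {
      omega <- 2 * pi / (t1 - t0)                       # one cycle per window
      amp <- min(0.5, 0.95 * config$max_hand_speed_cms / (tmpl$fa_len * omega))
      beta <- amp * sin(2 * pi * (seq_len(nf) - 1L) / nf)
      fore_scale <- mean(cos(beta))
    } else {
      beta <- rep(0, nf)
      fore_scale <- 1
    }
    sol <- solve_pose(tmpl, model, target, primary, fore_scale = fore_scale)

    jitter <- array(stats::rnorm(nf * 75L, 0, config$pose_jitter_sd),
                    dim = c(nf, 25L, 3L))
    jmean <- apply(jitter, c(2L, 3L), mean)
    frames <- lapply(seq_len(nf), function(j) {
      P <- pose_skeleton(tmpl, sol$theta, arm_dir(sol$phi),
                         arm_dir(sol$phi + beta[j]))
      P + jitter[j, , ] - jmean
    })
    windows[[w]] <- list(window = w, t0 = t0, t1 = t1, times = times,
                         frames = frames, theta = sol$theta, phi = sol$phi,
                         target = target, realized = sol$realized,
                         model_val = model_val, clamped = clamped)
    truth[[w]] <- data.frame(
      trial = trial_id, window = w, gravity = gravity, task = task,
      load_kg = load_kg, sex = sx,
      dY_model = model_val[["dY"]], dZ_model = model_val[["dZ"]],
      dY_target = target[["dY"]], dZ_target = target[["dZ"]],
      dY_realized = sol$realized[["dY"]], dZ_realized = sol$realized[["dZ"]],
      primary_axis = primary, clamped = clamped,
      offset_dY = offsets$offset[["dY"]], offset_dZ = offsets$offset[["dZ"]],
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    trial_id = trial_id,
    meta = data.frame(trial = trial_id, participant = participant$participant,
                      sex = sx, gravity = gravity, task = task,
                      load_kg = load_kg, et_min = et_min,
                      mass_kg = participant$mass_kg,
                      height_m = participant$height_m,
                      stringsAsFactors = FALSE),
    et_min = et_min, windows = windows, truth = do.call(rbind, truth)
  ), class = "synthetic_trial")
}

render_frame <- function(camera, points, pixel_noise_sd, dropout_prob) {
  Xc <- points %*% t(camera$rotation) +
    matrix(camera$translation, nrow(points), 3L, byrow = TRUE)
  out <- matrix(0, nrow(points), 3L)
  infront <- Xc[, 3L] > 0
  if (!all(infront)) {
    warning(sum(!infront), " keypoint(s) behind the camera; observation dropped")
  }
  if (any(infront)) {
    px <- project(camera, points[infront, , drop = FALSE])
    px <- px + matrix(stats::rnorm(length(px), 0, pixel_noise_sd),
                      nrow(px), 2L)
    out[infront, 1:2] <- px
    out[infront, 3L] <- 1
  }
  drop_k <- stats::runif(nrow(points)) < dropout_prob
  out[drop_k, ] <- 0
  out
}

#' Render a synthetic trial into per-camera 2D keypoint frames
#'
#' Projects every 3D keypoint of every window frame through each rig camera,
#' adds Gaussian pixel noise and zeroes the confidence of dropped keypoints.
#'
#' @param trial a [generate_trial()] result.
#' @param config a [generator_config()] (rig, noise, dropout, seed).
#' @return List, one entry per camera, each a list of 25x3 `(x, y,
#'   confidence)` matrices matching the trial's frames in order.
#' @export
render_views <- function(trial, config) {
  set.seed(derive_seed(config$seed, "render", trial$trial_id))
  frames <- unlist(lapply(trial$windows, `[[`, "frames"), recursive = FALSE)
  lapply(config$rig, function(cam) {
    lapply(frames, render_frame, camera = cam,
           pixel_noise_sd = config$pixel_noise_sd,
           dropout_prob = config$dropout_prob)
  })
}

trial_times <- function(trial) {
  unlist(lapply(trial$windows, `[[`, "times"), use.names = FALSE)
}

#' Generate a complete synthetic study
#'
#' Builds the cohort, assigns trials round-robin over the (gravity, task,
#' load) cells and the cohort, generates and renders every trial, and
#' optionally writes the study tree to disk
#' (`<dir>/<trial_id>/cam<k>/frame_NNNNNN.json` plus `calib.yaml`, `meta.csv`,
#' `truth.csv`, `frames.csv`). Trial counts are sized so the analysis yields
#' the configured number of rows per sex (the last windows of the final trial
#' are trimmed when the row count is not a multiple of three).
#'
#' @param config a [generator_config()].
#' @param dir optional output directory.
#' @param sexes which cohorts to generate.
#' @return List of class `synthetic_study`: `config`, `cohort`, `trials`
#'   (each with `$views` attached), `meta`, `truth`, `offsets` per sex.
#' @export
generate_study <- function(config, dir = NULL,
                           sexes = c("male", "female")) {
  cohort <- generate_cohort(config)
  cells <- trial_cells()
  trials <- list(); meta <- list(); truth <- list(); offsets <- list()
  for (sx in sexes) {
    n_rows <- config$n_rows[[sx]]
    if (is.null(n_rows) || n_rows == 0) next
    offsets[[sx]] <- study_offsets(config, sx)
    coh <- cohort[cohort$sex == sx, , drop = FALSE]
    n_trials <- ceiling(n_rows / 3)
    for (i in seq_len(n_trials)) {
      cell <- cells[(i - 1L) %% nrow(cells) + 1L, ]
      part <- coh[(i - 1L) %% nrow(coh) + 1L, ]
      id <- sprintf("%s_t%03d", sx, i)
      tr <- generate_trial(part, cell$gravity, cell$task, cell$load_kg,
                           config, trial_id = id, offsets = offsets[[sx]])
      tr$views <- render_views(tr, config)
      trials[[id]] <- tr
      meta[[id]] <- tr$meta
      truth[[id]] <- tr$truth
    }
  }
  study <- structure(list(config = config, cohort = cohort, trials = trials,
                          meta = do.call(rbind, meta),
                          truth = do.call(rbind, truth), offsets = offsets),
                     class = "synthetic_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @rdname generate_study
#' @param study a `synthetic_study`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_calibration(study$config$rig, file.path(dir, "calib.yaml"))
  utils::write.csv(study$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  frame_rows <- list()
  for (tr in study$trials) {
    tdir <- file.path(dir, tr$trial_id)
    times <- trial_times(tr)
    wins <- rep(vapply(tr$windows, `[[`, "", "window"),
                vapply(tr$windows, function(w) length(w$times), integer(1)))
    for (v in seq_along(tr$views)) {
      vdir <- file.path(tdir, sprintf("cam%d", v))
      dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
      for (j in seq_along(tr$views[[v]])) {
        write_openpose_frame(tr$views[[v]][[j]],
                             file.path(vdir, sprintf("frame_%06d.json", j)))
      }
    }
    frame_rows[[tr$trial_id]] <- data.frame(trial = tr$trial_id,
                                            frame = seq_along(times),
                                            time = times, window = wins,
                                            stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, frame_rows), file.path(dir, "frames.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' For every trial: triangulate each rendered frame from all camera views,
#' compute the per-frame whole-body CoM and pelvis-relative displacements with
#' the participant's body model, and summarize the endurance-time windows.
#' Rows are trimmed per sex to the configured analysis row count.
#'
#' @param study a [generate_study()] result (with rendered views).
#' @param min_views minimum camera views per triangulated keypoint.
#' @return Data frame of window-level analysis rows (see [summarize_trial()]).
#' @export
analyze_study <- function(study, min_views = 2L) {
  config <- study$config
  rows <- list()
  for (tr in study$trials) {
    model <- body_model(tr$meta$sex, tr$meta$mass_kg)
    times <- trial_times(tr)
    frames3d <- lapply(seq_along(times), function(j) {
      poses2d <- lapply(tr$views, `[[`, j)
      triangulate_pose(config$rig, poses2d, min_views = min_views)
    })
    samples <- com_samples(frames3d, times, model)
    meta <- list(participant = tr$meta$participant, sex = tr$meta$sex,
                 gravity = tr$meta$gravity, task = tr$meta$task,
                 load_kg = tr$meta$load_kg, et_min = tr$meta$et_min)
    rows[[tr$trial_id]] <- cbind(trial = tr$trial_id,
                                 summarize_trial(samples, meta,
                                                 window_s = config$window_s))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  trim_rows(out, config$n_rows)
}

trim_rows <- function(rows, n_rows) {
  keep <- unlist(lapply(unique(rows$sex), function(sx) {
    i <- which(rows$sex == sx)
    n <- n_rows[[sx]]
    if (!is.null(n) && length(i) > n) i <- i[seq_len(n)]
    i
  }))
  out <- rows[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Statistics-level synthetic analysis rows
#'
#' Draws window-level analysis rows directly from the configured effect model
#' (no geometry or rendering): the fast path for regression-calibration
#' studies and replicate simulations. Trials are assigned to (gravity, task,
#' load) cells round-robin exactly as in [generate_study()].
#'
#' Replicate simulations use antithetic pairing (`antithetic = TRUE` mirrors
#' the residual draws of the same seed): because the OLS coefficients are
#' linear in the residuals, averaging an antithetic pair cancels the
#' first-order Monte-Carlo noise, so the mean over paired replicates is a
#' sharp probe of genuine pipeline bias rather than of simulation noise.
#'
#' @param config a [generator_config()].
#' @param sex cohort to draw.
#' @param seed optional stream seed (defaults to a stream derived from the
#'   config master seed).
#' @param antithetic if `TRUE`, negate the drawn residuals (same seed gives
#'   the mirrored replicate).
#' @return Data frame of analysis rows with columns as in [summarize_trial()].
#' @export
generate_design_rows <- function(config, sex, seed = NULL, antithetic = FALSE) {
  n_rows <- config$n_rows[[sex]]
  stopifnot(!is.null(n_rows), n_rows >= 1)
  cells <- trial_cells()
  eff <- list(dY = effect_row(config$effects, sex, "dY"),
              dZ = effect_row(config$effects, sex, "dZ"))
  set.seed(if (is.null(seed)) derive_seed(config$seed, "rows", sex) else seed)
  n_trials <- ceiling(n_rows / 3)
  rows <- lapply(seq_len(n_trials), function(i) {
    cell <- cells[(i - 1L) %% nrow(cells) + 1L, ]
    g <- as.integer(cell$gravity == "1g")
    td <- as.integer(cell$task == "dynamic")
    sgn <- if (antithetic) -1 else 1
    vals <- vapply(c("dY", "dZ"), function(ax) {
      e <- eff[[ax]]
      e$constant + e$beta_g * g + e$beta_task * td +
        sgn * stats::rnorm(3, 0, e$residual_sd)
    }, numeric(3))
    data.frame(trial = sprintf("%s_t%03d", sex, i),
               participant = sprintf("%s%02d", substr(sex, 1, 1),
                                     (i - 1L) %% max(config$n_male,
                                                     config$n_female) + 1L),
               sex = sex, gravity = cell$gravity, task = cell$task,
               load_kg = cell$load_kg, et_min = NA_real_,
               window = c("start", "middle", "end"),
               g_level = g, task_dynamic = td,
               dY = vals[, "dY"], dZ = vals[, "dZ"], n_frames = NA_integer_,
               stringsAsFactors = FALSE)
  })
  trim_rows(do.call(rbind, rows), config$n_rows)
}
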
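#' Synthetic study generator configuration
#'
#' Bundles every knob of the synthetic-study generator. Defaults reproduce the
#' study conditions: an 18-male / 14-female cohort with the published
#' sex-stratified anthropometrics, endurance-time means per (task, gravity,
#' load) cell, gravity/task effects on pelvis-relative CoM displacement with
#' the published residual noise, a rig of three 1920x1080 cameras 2 m from the
#' subject, and 114 male / 56 female analysis rows.
#'
#' @param n_male,n_female cohort sizes.
#' @param anthropometrics data frame from [default_anthropometrics()].
#' @param et_table endurance-time means (min) from [default_et_table()].
#' @param effects effect parameters (cm) from [default_effect_table()].
#' @param n_rows named vector: analysis rows per sex.
#' @param primary_axis `"dY"` or `"dZ"`: the axis whose window targets the
#'   pose solver realizes exactly (see the package vignette).
#' @param window_s analysis window length, s.
#' @param fps frame rate at which window frames are synthesized, Hz.
#' @param pixel_noise_sd Gaussian pixel noise added to rendered keypoints, px.
#' @param dropout_prob probability a rendered keypoint observation is dropped
#'   (confidence zeroed).
#' @param pose_jitter_sd per-frame 3D keypoint jitter, cm (mean-centred per
#'   window, so window means are unaffected).
#' @param et_cv coefficient of variation of the log-normal endurance times.
#' @param max_hand_speed_cms cap on wrist speed during dynamic tasks, cm/s.
#' @param rig camera rig from [default_camera_rig()].
#' @param seed master seed; every drawn quantity derives from it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_male = 18, n_female = 14,
                             anthropometrics = default_anthropometrics(),
                             et_table = default_et_table(),
                             effects = default_effect_table(),
                             n_rows = c(male = 114, female = 56),
                             primary_axis = c("dY", "dZ"),
                             window_s = 5, fps = 30,
                             pixel_noise_sd = 1, dropout_prob = 0.02,
                             pose_jitter_sd = 0.3, et_cv = 0.3,
                             max_hand_speed_cms = 47,
                             rig = default_camera_rig(), seed = 1L) {
  primary_axis <- match.arg(primary_axis)
  stopifnot(n_male + n_female >= 1, window_s > 0, fps > 0,
            pixel_noise_sd >= 0, dropout_prob >= 0, dropout_prob <= 1,
            pose_jitter_sd >= 0, et_cv >= 0, max_hand_speed_cms > 0,
            all(effects$residual_sd >= 0))
  structure(list(
    n_male = n_male, n_female = n_female, anthropometrics = anthropometrics,
    et_table = et_table, effects = effects, n_rows = n_rows,
    primary_axis = primary_axis, window_s = window_s, fps = fps,
    pixel_noise_sd = pixel_noise_sd, dropout_prob = dropout_prob,
    pose_jitter_sd = pose_jitter_sd, et_cv = et_cv,
    max_hand_speed_cms = max_hand_speed_cms, rig = rig,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default sex-stratified anthropometrics (cohort means/SDs)
#'
#' Height (m), body mass (kg), segment volumes (dm^3) and arm segment lengths
#' (m) per sex, with whole-cohort min/max truncation bounds.
#'
#' @return Data frame, one row per sex.
#' @export
default_anthropometrics <- function() {
  data.frame(
    sex = c("male", "female"),
    height_mean = c(1.83, 1.66), height_sd = c(0.07, 0.06),
    height_min = 1.54, height_max = 1.95,
    mass_mean = c(82.92, 56.19), mass_sd = c(13.02, 5.95),
    mass_min = 43.8, mass_max = 114.10,
    torso_vol_mean = c(44.71, 27.00), torso_vol_sd = c(6.93, 4.42),
    upper_arm_vol_mean = c(2.70, 1.48), upper_arm_vol_sd = c(0.67, 0.38),
    forearm_vol_mean = c(1.37, 0.72), forearm_vol_sd = c(0.20, 0.16),
    upper_arm_len_mean = c(0.35, 0.32), upper_arm_len_sd = c(0.03, 0.03),
    forearm_len_mean = c(0.30, 0.25), forearm_len_sd = c(0.02, 0.02),
    stringsAsFactors = FALSE
  )
}

#' Default endurance-time means (min) per task, gravity and load
#' @return Data frame with columns `task`, `gravity`, `load_kg`, `et_male`,
#'   `et_female` (minutes).
#' @export
default_et_table <- function() {
  data.frame(
    task = rep(c("static", "dynamic"), each = 4),
    gravity = rep(c("1g", "1g", "1/6g", "1/6g"), 2),
    load_kg = rep(c(1, 3), 4),
    et_male = c(1.67, 0.85, 7.73, 2.65, 1.30, 0.79, 14.93, 2.16),
    et_female = c(0.95, 0.34, 6.21, 0.65, 0.80, 0.35, 9.34, 0.82),
    stringsAsFactors = FALSE
  )
}

#' Default gravity/task effect parameters on CoM displacement (cm)
#'
#' Per (sex, axis): the model constant, the gravity-level effect (1/6 g to
#' 1 g), the task effect (static to dynamic) and the residual noise SD.
#'
#' @return Data frame, one row per (sex, axis).
#' @export
default_effect_table <- function() {
  data.frame(
    sex = c("male", "female", "male", "female"),
    axis = c("dY", "dY", "dZ", "dZ"),
    constant = c(-8.47, 5.70, 6.67, -3.77),
    beta_g = c(17.06, 5.87, -1.45, 6.02),
    beta_task = c(3.17, -0.94, -2.17, 0.44),
    residual_sd = c(8.45, 2.11, 8.01, 5.26),
    stringsAsFactors = FALSE
  )
}

#' Default three-camera rig
#'
#' Three cameras on a 2 m-radius circle around the subject, 120 degrees apart
#' at chest height, 1920x1080, shared synthetic intrinsics, aimed at a point
#' 30 cm above the pelvis.
#'
#' @param n_cameras,radius_cm,height_cm,focal_px,image_size rig geometry.
#' @param target aim point (cm, world frame at the pelvis).
#' @return List of [camera_model()] objects.
#' @export
default_camera_rig <- function(n_cameras = 3, radius_cm = 200, height_cm = 30,
                               focal_px = 1200, image_size = c(1920, 1080),
                               target = c(0, 30, 0)) {
  angles <- 2 * pi * (seq_len(n_cameras) - 1) / n_cameras
  lapply(angles, function(a) {
    pos <- c(radius_cm * sin(a), height_cm, radius_cm * cos(a))
    z <- target - pos; z <- z / sqrt(sum(z^2))
    x <- c(z[3], 0, -z[1]); x <- x / sqrt(sum(x^2))   # horizontal right vector
    y <- c(z[2] * x[3] - z[3] * x[2],
           z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])                 # z cross x
    R <- rbind(x, y, z)
    camera_model(focal_px, image_size / 2, image_size, R, -drop(R %*% pos))
  })
}

#' Deterministic sub-stream seed
#'
#' Derives a reproducible integer seed (< 2^31) from a master seed and any
#' number of string identifiers, so that regenerating a subset of trials
#' yields the same draws regardless of generation order.
#'
#' @param master integer master seed.
#' @param ... identifiers (coerced to character).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  s <- paste(..., sep = "/")
  h <- sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1))
  as.integer((as.numeric(master) * 48271 + h * 131) %% 2147483647)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (lo > hi || (sd == 0 && (mean < lo || mean > hi))) {
    stop("impossible truncation bounds for mean ", mean)
  }
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws participants from sex-specific normal distributions truncated at the
#' cohort min/max bounds; segment volumes scale with each participant's drawn
#' body mass relative to the sex mean.
#'
#' @param config a [generator_config()].
#' @return Data frame, one row per participant: `participant`, `sex`,
#'   `height_m`, `mass_kg`, segment volumes (dm^3), arm segment lengths (m).
#' @export
generate_cohort <- function(config) {
  a <- config$anthropometrics
  rows <- lapply(c("male", "female"), function(sx) {
    n <- if (sx == "male") config$n_male else config$n_female
    if (n == 0L) return(NULL)
    p <- a[a$sex == sx, ]
    set.seed(derive_seed(config$seed, "cohort", sx))
    height <- rtruncnorm1(n, p$height_mean, p$height_sd, p$height_min, p$height_max)
    mass <- rtruncnorm1(n, p$mass_mean, p$mass_sd, p$mass_min, p$mass_max)
    scale_m <- mass / p$mass_mean
    data.frame(
      participant = paste0(substr(sx, 1, 1), sprintf("%02d", seq_len(n))),
      sex = sx, height_m = height, mass_kg = mass,
      torso_vol_dm3 = rtruncnorm1(n, p$torso_vol_mean, p$torso_vol_sd,
                                  0, Inf) * scale_m,
      upper_arm_vol_dm3 = rtruncnorm1(n, p$upper_arm_vol_mean,
                                      p$upper_arm_vol_sd, 0, Inf) * scale_m,
      forearm_vol_dm3 = rtruncnorm1(n, p$forearm_vol_mean, p$forearm_vol_sd,
                                    0, Inf) * scale_m,
      upper_arm_len_m = rtruncnorm1(n, p$upper_arm_len_mean, p$upper_arm_len_sd,
                                    0.1, 0.6),
      forearm_len_m = rtruncnorm1(n, p$forearm_len_mean, p$forearm_len_sd,
                                  0.1, 0.6),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Seated skeleton template
#'
#' Segment lengths (cm) of a seated 25-keypoint skeleton scaled to a
#' participant's height, using standard anthropometric length fractions; arm
#' segment lengths can be overridden with measured values.
#'
#' @param height_m standing height, m.
#' @param upper_arm_len_m,forearm_len_m optional measured arm lengths, m.
#' @return List of class `seated_template` (lengths in cm).
#' @export
seated_template <- function(height_m, upper_arm_len_m = NULL,
                            forearm_len_m = NULL) {
  h <- height_m * 100
  structure(list(
    trunk_len = 0.30 * h, head_len = 0.13 * h,
    shoulder_hw = 0.105 * h, hip_hw = 0.065 * h,
    ua_len = if (is.null(upper_arm_len_m)) 0.188 * h else upper_arm_len_m * 100,
    fa_len = if (is.null(forearm_len_m)) 0.16 * h else forearm_len_m * 100,
    thigh_len = 0.245 * h, shank_len = 0.246 * h
  ), class = "seated_template")
}

#' Pose the seated template
#'
#' Builds the 25x3 keypoint matrix (cm, pelvis at the origin) for a torso
#' pitch `theta` (radians; 0 = upright, positive = backward lean) and a common
#' arm direction vector. The arm/forearm directions live in the sagittal
#' (Y-Z) plane; a direction of norm < 1 is admitted so that the time-average
#' of an oscillating forearm can be posed directly (the CoM is linear in
#' keypoint positions, so the posed average equals the average of the posed
#' frames).
#'
#' @param tmpl a [seated_template()].
#' @param theta torso pitch, rad.
#' @param u_arm length-3 upper-arm direction (world frame).
#' @param u_fore forearm direction; defaults to `u_arm` (straight arm).
#' @return 25x3 numeric matrix, rows in keypoint-index order.
#' @export
pose_skeleton <- function(tmpl, theta, u_arm, u_fore = u_arm) {
  ut <- c(0, cos(theta), -sin(theta))       # along the trunk, hip -> shoulder
  ant <- c(0, sin(theta), cos(theta))       # anterior, perpendicular to trunk
  xv <- c(1, 0, 0)
  pelvis <- c(0, 0, 0)
  neck <- tmpl$trunk_len * ut
  nose <- neck + tmpl$head_len * ut + 3 * ant
  r_sh <- neck - tmpl$shoulder_hw * xv
  l_sh <- neck + tmpl$shoulder_hw * xv
  r_el <- r_sh + tmpl$ua_len * u_arm
  l_el <- l_sh + tmpl$ua_len * u_arm
  r_wr <- r_el + tmpl$fa_len * u_fore
  l_wr <- l_el + tmpl$fa_len * u_fore
  r_hip <- pelvis - tmpl$hip_hw * xv
  l_hip <- pelvis + tmpl$hip_hw * xv
  knee_off <- c(0, -2, tmpl$thigh_len)
  r_kn <- r_hip + knee_off; l_kn <- l_hip + knee_off
  ank_off <- c(0, -tmpl$shank_len, 0)
  r_an <- r_kn + ank_off; l_an <- l_kn + ank_off
  P <- rbind(
    nose, neck, r_sh, r_el, r_wr, l_sh, l_el, l_wr,
    pelvis, r_hip, r_kn, r_an, l_hip, l_kn, l_an,
    nose + c(-3.5, 1, 1), nose + c(3.5, 1, 1),       # eyes
    nose + c(-8, 0, -2), nose + c(8, 0, -2),         # ears
    l_an + c(0, -3, 14), l_an + c(3, -3, 12), l_an + c(0, -3, -4),
    r_an + c(0, -3, 14), r_an + c(-3, -3, 12), r_an + c(0, -3, -4)
  )
  dimnames(P) <- list(body25_keypoints, c("x", "y", "z"))
  P
}

#' Sagittal-plane arm direction vector
#'
#' Unit direction for both arms at elevation `phi` (radians): 0 points
#' straight down, `pi/2` straight forward (anterior).
#'
#' @param phi arm elevation angle, rad.
#' @return Length-3 unit vector in world coordinates.
#' @export
arm_dir <- function(phi) c(0, -cos(phi), sin(phi))

pose_displacement <- function(tmpl, model, theta, phi, fore_dir = NULL) {
  uf <- if (is.null(fore_dir)) arm_dir(phi) else fore_dir
  s <- body_com(pose_skeleton(tmpl, theta, arm_dir(phi), uf), model)
  c(dY = s$dY, dZ = s$dZ)
}

theta_bounds <- function(primary) {
  if (primary == "dY") c(0.03, pi - 0.03) else c(-pi / 2 + 0.03, pi / 2 - 0.03)
}

#' Reachable span of pelvis-relative displacement for a template
#'
#' Conservative reachable interval of the primary-axis displacement over the
#' admissible torso pitch range, minimized/maximized over arm direction (so
#' any target inside the span is realizable whatever arm direction the
#' secondary-axis adjustment selects).
#'
#' @param tmpl a [seated_template()].
#' @param model a [body_model()].
#' @param primary `"dY"` or `"dZ"`.
#' @return `c(lo, hi)`, cm.
#' @export
pose_reach <- function(tmpl, model, primary = "dY") {
  tb <- theta_bounds(primary)
  phis <- seq(-pi, pi, length.out = 25)
  lo <- max(vapply(phis, function(p)
    pose_displacement(tmpl, model, tb[1], p)[[primary]], numeric(1)))
  hi <- min(vapply(phis, function(p)
    pose_displacement(tmpl, model, tb[2], p)[[primary]], numeric(1)))
  sort(c(lo, hi))
}

#' Solve the seated pose for a displacement target
#'
#' Alternating 1-D root finds: torso pitch is solved so the primary-axis
#' displacement matches its target exactly; the arm direction is then chosen
#' to bring the secondary axis as close to its target as the arm's reach
#' allows (the CoM of an articulated chain is confined to a band around the
#' torso arc, so the secondary axis is best-effort by construction). Errors
#' if the primary target lies outside the template's reachable span.
#'
#' @param tmpl a [seated_template()].
#' @param model a [body_model()].
#' @param target named numeric `c(dY =, dZ =)`, cm.
#' @param primary axis realized exactly.
#' @param fore_scale scalar in (0, 1]: time-average norm of the forearm
#'   direction (1 for a static straight arm).
#' @return `list(theta, phi, realized)` with `realized` the posed `c(dY, dZ)`.
#' @export
solve_pose <- function(tmpl, model, target, primary = "dY", fore_scale = 1) {
  secondary <- setdiff(c("dY", "dZ"), primary)
  tb <- theta_bounds(primary)
  disp <- function(theta, phi) {
    ua <- arm_dir(phi)
    pose_displacement(tmpl, model, theta, phi, fore_dir = fore_scale * ua)
  }
  phi <- if (primary == "dY") 0.6 else 0
  theta <- mean(tb)
  for (it in 1:12) {
    f <- function(th) disp(th, phi)[[primary]] - target[[primary]]
    flo <- f(tb[1]); fhi <- f(tb[2])
    if (flo * fhi > 0) {
      stop(sprintf(
        "primary-axis target %.2f cm unreachable; reachable range [%.2f, %.2f] cm",
        target[[primary]],
        min(flo, fhi) + target[[primary]], max(flo, fhi) + target[[primary]]))
    }
    theta <- stats::uniroot(f, tb, tol = 1e-12)$root
    g <- function(ph) (disp(theta, ph)[[secondary]] - target[[secondary]])^2
    phi_new <- stats::optimize(g, c(-pi, pi), tol = 1e-10)$minimum
    if (abs(phi_new - phi) < 1e-10 && it > 1) { phi <- phi_new; break }
    phi <- phi_new
  }
  f <- function(th) disp(th, phi)[[primary]] - target[[primary]]
  theta <- stats::uniroot(f, tb, tol = 1e-13)$root
  list(theta = theta, phi = phi, realized = disp(theta, phi))
}
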
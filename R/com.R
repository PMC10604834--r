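#' Whole-body center of mass of one 3D pose
#'
#' Segmental weighted sum over the model's segments:
#' `CoM = (1/M) * sum m_ij [P_i + k_ij (P_j - P_i)]`, with `P_i` the proximal
#' joint, `m_ij = mass_fraction * total_mass` and `M` the summed segment mass.
#' The mid-hip keypoint is the pelvis reference; pelvis-relative displacements
#' `dY` (downward positive) and `dZ` (posterior positive) are returned with it.
#'
#' @param points 25x3 matrix of keypoint coordinates (cm), rows in 0-based
#'   keypoint-index order.
#' @param model a [body_model()].
#' @param valid logical 25; keypoints flagged `FALSE` are unusable. A frame
#'   missing any keypoint the model requires yields a missing sample (`valid =
#'   FALSE` in the result, with the offending keypoints listed) — never a
#'   silently interpolated one.
#' @param down_positive,posterior_positive sign conventions, see
#'   [displacement_axes()].
#' @return `list(com, pelvis, dY, dZ, valid, missing_keypoints)`.
#' @export
body_com <- function(points, model, valid = rep(TRUE, 25L),
                     down_positive = TRUE, posterior_positive = TRUE) {
  stopifnot(is.matrix(points), nrow(points) == 25L, ncol(points) == 3L,
            inherits(model, "body_model"))
  seg <- model$segments
  need <- sort(unique(c(seg$proximal_idx, seg$distal_idx, PELVIS_KEYPOINT)))
  ok <- valid[kp_row(need)] & apply(is.finite(points[kp_row(need), , drop = FALSE]), 1L, all)
  if (!all(ok)) {
    return(list(com = rep(NA_real_, 3L), pelvis = rep(NA_real_, 3L),
                dY = NA_real_, dZ = NA_real_, valid = FALSE,
                missing_keypoints = need[!ok]))
  }
  m <- seg$mass_fraction * model$total_mass
  P_i <- points[kp_row(seg$proximal_idx), , drop = FALSE]
  P_j <- points[kp_row(seg$distal_idx), , drop = FALSE]
  centers <- P_i + seg$k * (P_j - P_i)
  com <- colSums(centers * m) / sum(m)
  pelvis <- points[kp_row(PELVIS_KEYPOINT), ]
  d <- displacement_axes(com, pelvis, down_positive, posterior_positive)
  list(com = com, pelvis = pelvis, dY = d[["dY"]], dZ = d[["dZ"]],
       valid = TRUE, missing_keypoints = integer(0))
}

#' Pelvis-relative displacement components
#'
#' `dY = pelvis_y - com_y` (a CoM below the pelvis is positive: downward
#' shift), `dZ = pelvis_z - com_z` (a CoM behind the pelvis is positive:
#' posterior shift / backward lean). Both conventions can be flipped.
#'
#' @param com,pelvis length-3 points (cm).
#' @param down_positive if `FALSE`, `dY = com_y - pelvis_y`.
#' @param posterior_positive if `FALSE`, `dZ = com_z - pelvis_z`.
#' @return Named numeric `c(dY =, dZ =)`, cm.
#' @export
displacement_axes <- function(com, pelvis, down_positive = TRUE,
                              posterior_positive = TRUE) {
  stopifnot(is_finite_point(com), is_finite_point(pelvis))
  dY <- pelvis[2L] - com[2L]
  dZ <- pelvis[3L] - com[3L]
  if (!down_positive) dY <- -dY
  if (!posterior_positive) dZ <- -dZ
  c(dY = unname(dY), dZ = unname(dZ))
}

#' Endurance-time analysis windows
#'
#' Start / middle / end windows over a trial of endurance time `ET`:
#' `[0, w]`, `[ET/2 - w/2, ET/2 + w/2]`, `[ET - w, ET]` (seconds), with the
#' window length `w` clamped to `[window_s, max_window_s]` per the protocol of
#' averaging the first 5 s up to 1 min of each phase.
#'
#' @param et_min endurance time, minutes.
#' @param window_s nominal window length, s.
#' @param max_window_s longest allowed window, s.
#' @return 3x2 matrix (rows `start`, `middle`, `end`; columns `t0`, `t1`), s.
#' @export
et_window_bounds <- function(et_min, window_s = 5, max_window_s = 60) {
  stopifnot(et_min > 0, window_s > 0, max_window_s >= window_s)
  et_s <- et_min * 60
  w <- min(max(window_s, 0), max_window_s, et_s)
  mid <- et_s / 2
  m <- rbind(start = c(0, w),
             middle = c(mid - w / 2, mid + w / 2),
             end = c(et_s - w, et_s))
  colnames(m) <- c("t0", "t1")
  m
}

#' Windowed trial summary of pelvis-relative CoM displacement
#'
#' Means of `dY` and `dZ` over the three endurance-time windows, using only
#' valid samples. An empty window is reported missing (`NA`, `n = 0`) with a
#' warning rather than interpolated.
#'
#' @param samples data frame with columns `time` (s), `dY`, `dZ` (cm) and
#'   optionally `valid` (logical); rows are sorted by time internally.
#' @param et_min endurance time, minutes.
#' @param window_s,max_window_s see [et_window_bounds()].
#' @return Data frame, one row per window: `window`, `t0`, `t1`, `dY`, `dZ`,
#'   `n_frames`.
#' @export
et_windows <- function(samples, et_min, window_s = 5, max_window_s = 60) {
  stopifnot(is.data.frame(samples), all(c("time", "dY", "dZ") %in% names(samples)))
  ok <- if ("valid" %in% names(samples)) samples$valid else rep(TRUE, nrow(samples))
  ok <- ok & is.finite(samples$dY) & is.finite(samples$dZ)
  samples <- samples[ok, , drop = FALSE]
  samples <- samples[order(samples$time), , drop = FALSE]
  b <- et_window_bounds(et_min, window_s, max_window_s)
  out <- lapply(rownames(b), function(wn) {
    sel <- samples$time >= b[wn, "t0"] - 1e-9 & samples$time <= b[wn, "t1"] + 1e-9
    n <- sum(sel)
    if (n == 0L) {
      warning("window '", wn, "' contains no valid samples; marked missing")
      data.frame(window = wn, t0 = b[wn, "t0"], t1 = b[wn, "t1"],
                 dY = NA_real_, dZ = NA_real_, n_frames = 0L)
    } else {
      data.frame(window = wn, t0 = b[wn, "t0"], t1 = b[wn, "t1"],
                 dY = mean(samples$dY[sel]), dZ = mean(samples$dZ[sel]),
                 n_frames = n)
    }
  })
  do.call(rbind, out)
}

#' Per-frame CoM samples from a triangulated pose sequence
#'
#' @param frames list of triangulated frames as returned by
#'   [triangulate_pose()] (each `list(points, valid, rms)`).
#' @param times numeric vector of frame times, s.
#' @param model a [body_model()].
#' @param ... passed to [body_com()] (sign conventions).
#' @return Data frame: `time`, `dY`, `dZ`, `valid` plus CoM and pelvis
#'   coordinates (`com_x..com_z`, `pel_x..pel_z`), cm.
#' @export
com_samples <- function(frames, times, model, ...) {
  stopifnot(length(frames) == length(times))
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    s <- body_com(f$points, model, valid = f$valid, ...)
    data.frame(time = times[i], dY = s$dY, dZ = s$dZ, valid = s$valid,
               com_x = s$com[1], com_y = s$com[2], com_z = s$com[3],
               pel_x = s$pelvis[1], pel_y = s$pelvis[2], pel_z = s$pelvis[3])
  })
  do.call(rbind, rows)
}

#' Tidy window-level analysis rows for one trial
#'
#' Combines [com_samples()] and [et_windows()] with the trial metadata into
#' the rows consumed by [com_gravfit()].
#'
#' @param samples per-frame samples from [com_samples()].
#' @param meta one-row data frame (or named list) with `participant`, `sex`,
#'   `gravity` (`"1/6g"` or `"1g"`), `task` (`"static"` or `"dynamic"`),
#'   `load_kg`, `et_min`.
#' @param window_s,max_window_s see [et_window_bounds()].
#' @return Data frame, one row per window, with metadata, indicator columns
#'   `g_level` (1 = 1 g) and `task_dynamic` (1 = dynamic), `dY`, `dZ`,
#'   `n_frames`.
#' @export
summarize_trial <- function(samples, meta, window_s = 5, max_window_s = 60) {
  w <- et_windows(samples, meta$et_min, window_s, max_window_s)
  data.frame(
    participant = meta$participant, sex = meta$sex,
    gravity = meta$gravity, task = meta$task, load_kg = meta$load_kg,
    et_min = meta$et_min, window = w$window,
    g_level = as.integer(meta$gravity == "1g"),
    task_dynamic = as.integer(meta$task == "dynamic"),
    dY = w$dY, dZ = w$dZ, n_frames = w$n_frames,
    stringsAsFactors = FALSE
  )
}
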
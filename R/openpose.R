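#' Read per-frame OpenPose JSON keypoint files
#'
#' Parses the per-frame JSON dialect written by the pose software (v1.4 layout:
#' a `people` array whose entries carry a flat `pose_keypoints_2d` vector of 25
#' `(x, y, confidence)` triplets). Frames are ordered by the numeric index
#' embedded in the file name. When a frame contains several detected people,
#' the one whose mid-hip keypoint is nearest the previous frame's mid-hip is
#' kept (first frame: the person with the largest keypoint bounding box) —
#' trials are single-participant, so extra detections are spurious.
#'
#' @param path directory containing `*.json` frame files, or a character vector
#'   of file paths.
#' @return List of class `pose2d_sequence`: per frame, either a 25x3 numeric
#'   matrix (columns `x`, `y`, `confidence`; confidence 0 marks an undetected
#'   keypoint) or `NULL` for an empty/missing frame. Names are frame indices.
#' @export
read_openpose_frames <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, pattern = "\\.json$", full.names = TRUE)
  } else path
  if (length(files) == 0L || !all(file.exists(files))) {
    stop("no JSON frame files found in ", paste(path, collapse = ", "))
  }
  idx <- frame_index_from_name(files)
  files <- files[order(idx)]
  idx <- sort(idx)
  out <- vector("list", length(files))
  prev_hip <- NULL
  for (i in seq_along(files)) {
    doc <- tryCatch(jsonlite::fromJSON(files[i], simplifyVector = FALSE),
                    error = function(e) {
                      stop("malformed JSON in ", files[i], ": ", conditionMessage(e))
                    })
    people <- doc$people
    if (is.null(people) || length(people) == 0L) {
      out[i] <- list(NULL)
      next
    }
    poses <- lapply(people, function(p) {
      kv <- as.numeric(unlist(p$pose_keypoints_2d))
      if (length(kv) != 75L) {
        stop("expected 75 keypoint values (25 x/y/confidence triplets) in ", files[i])
      }
      matrix(kv, 25L, 3L, byrow = TRUE, dimnames = list(body25_keypoints,
                                                        c("x", "y", "confidence")))
    })
    pose <- select_person(poses, prev_hip)
    hip <- pose[kp_row(PELVIS_KEYPOINT), ]
    if (hip[3L] > 0) prev_hip <- hip[1:2]
    out[[i]] <- pose
  }
  names(out) <- idx
  class(out) <- "pose2d_sequence"
  out
}

frame_index_from_name <- function(files) {
  m <- regmatches(basename(files), regexpr("[0-9]+", basename(files)))
  idx <- suppressWarnings(as.integer(m))
  idx[is.na(idx)] <- seq_along(files)[is.na(idx)]
  idx
}

select_person <- function(poses, prev_hip) {
  if (length(poses) == 1L) return(poses[[1L]])
  if (!is.null(prev_hip)) {
    d <- vapply(poses, function(p) {
      hip <- p[kp_row(PELVIS_KEYPOINT), ]
      if (hip[3L] <= 0) Inf else sum((hip[1:2] - prev_hip)^2)
    }, numeric(1))
    if (any(is.finite(d))) return(poses[[which.min(d)]])
  }
  area <- vapply(poses, function(p) {
    det <- p[, 3L] > 0
    if (!any(det)) return(0)
    diff(range(p[det, 1L])) * diff(range(p[det, 2L]))
  }, numeric(1))
  poses[[which.max(area)]]
}

#' Write one frame of 2D keypoints in the OpenPose JSON dialect
#'
#' Inverse of [read_openpose_frames()]; numbers are written at full double
#' precision so a write/read round trip reproduces keypoints exactly.
#'
#' @param pose 25x3 numeric matrix `(x, y, confidence)`, or `NULL` for an empty
#'   frame (no people).
#' @param file output path.
#' @export
write_openpose_frame <- function(pose, file) {
  people <- if (is.null(pose)) list() else {
    stopifnot(is.matrix(pose), nrow(pose) == 25L, ncol(pose) == 3L)
    list(list(person_id = list(-1L),
              pose_keypoints_2d = as.numeric(t(pose))))
  }
  doc <- list(version = 1.4, people = people)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = I(17))
  invisible(file)
}
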
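#' The 25-keypoint body layout
#'
#' Index-to-name mapping for the 25-keypoint skeleton produced by markerless
#' pose software (the BODY_25 layout). Indices are 0-based on disk (as written
#' in the per-frame JSON) and used 0-based throughout this package's segment
#' tables; helper accessors convert to R's 1-based rows where needed.
#'
#' @format Character vector of length 25, names in index order (index 0 first).
#' @export
body25_keypoints <- c(
  "nose", "neck", "r_shoulder", "r_elbow", "r_wrist",
  "l_shoulder", "l_elbow", "l_wrist", "mid_hip", "r_hip",
  "r_knee", "r_ankle", "l_hip", "l_knee", "l_ankle",
  "r_eye", "l_eye", "r_ear", "l_ear", "l_bigtoe",
  "l_smalltoe", "l_heel", "r_bigtoe", "r_smalltoe", "r_heel"
)

#' Index (0-based) of the pelvis reference keypoint (mid hip)
#' @export
PELVIS_KEYPOINT <- 8L

# 0-based keypoint index -> row of a 25-row matrix
kp_row <- function(idx0) as.integer(idx0) + 1L

is_finite_point <- function(p) is.numeric(p) && length(p) == 3L && all(is.finite(p))
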
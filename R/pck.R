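#' Percentage of correct keypoints (PCK)
#'
#' Fraction (x100) of predicted keypoints lying within `alpha` times a
#' reference distance of their manual annotation. The reference is either the
#' annotated torso diagonal (mid-hip to neck distance, per frame) or a fixed
#' pixel threshold. Keypoints are evaluated only where the annotation is valid
#' (confidence > 0); predicted keypoints with confidence 0 count as incorrect.
#'
#' @param predicted,annotated lists of 25x3 matrices `(x, y, confidence)` (a
#'   single matrix is accepted), matched frame by frame.
#' @param alpha threshold fraction of the reference distance.
#' @param reference `"torso_diagonal"` or `"fixed_px"`.
#' @param fixed_px reference distance in px when `reference = "fixed_px"`.
#' @return Percentage in `[0, 100]`.
#' @export
pck <- function(predicted, annotated, alpha = 0.2,
                reference = c("torso_diagonal", "fixed_px"), fixed_px = NULL) {
  reference <- match.arg(reference)
  if (is.matrix(predicted)) predicted <- list(predicted)
  if (is.matrix(annotated)) annotated <- list(annotated)
  stopifnot(length(predicted) == length(annotated))
  correct <- 0L; total <- 0L
  for (f in seq_along(predicted)) {
    pr <- predicted[[f]]; an <- annotated[[f]]
    if (is.null(an)) next
    eval_k <- which(an[, 3L] > 0)
    if (length(eval_k) == 0L) next
    thr <- alpha * switch(reference,
      torso_diagonal = {
        hip <- an[kp_row(PELVIS_KEYPOINT), ]
        neck <- an[kp_row(1L), ]
        if (hip[3L] <= 0 || neck[3L] <= 0) {
          stop("torso_diagonal reference needs valid mid-hip and neck annotations")
        }
        sqrt(sum((hip[1:2] - neck[1:2])^2))
      },
      fixed_px = {
        if (is.null(fixed_px) || fixed_px <= 0) stop("fixed_px must be a positive distance")
        fixed_px
      })
    for (k in eval_k) {
      total <- total + 1L
      if (!is.null(pr) && pr[k, 3L] > 0) {
        d <- sqrt(sum((pr[k, 1:2] - an[k, 1:2])^2))
        if (d <= thr) correct <- correct + 1L
      }
    }
  }
  if (total == 0L) stop("no evaluable keypoints (no valid annotations)")
  100 * correct / total
}
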
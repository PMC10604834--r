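#' Pinhole camera model
#'
#' World coordinates are right-handed, in cm: Y up (proximodistal), Z anterior,
#' X mediolateral. A point `X` maps to camera coordinates `Xc = R X + t` (t in
#' cm) and to pixels through the intrinsics; optional radial distortion
#' `(k1, k2)` applies to normalized image coordinates.
#'
#' @param focal length-2 focal lengths (fx, fy), px (a scalar is recycled).
#' @param center principal point (cx, cy), px.
#' @param image_size image size (width, height), px.
#' @param rotation 3x3 orthonormal world-to-camera rotation.
#' @param translation length-3 world-to-camera translation, cm.
#' @param distortion optional radial coefficients (k1, k2).
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(focal, center, image_size, rotation, translation,
                         distortion = NULL) {
  focal <- rep_len(as.numeric(focal), 2L)
  stopifnot(length(center) == 2L, length(image_size) == 2L,
            all(image_size > 0), all(focal > 0),
            is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be orthonormal (R'R = I within 1e-9)")
  }
  if (!is.null(distortion)) distortion <- rep_len(as.numeric(distortion), 2L)
  dimnames(rotation) <- NULL
  structure(list(focal = focal, center = as.numeric(center),
                 image_size = as.numeric(image_size),
                 rotation = rotation, translation = unname(as.numeric(translation)),
                 distortion = distortion),
            class = "camera_model")
}

#' 3x4 homogeneous projection matrix K [R | t]
#' @param camera a [camera_model()].
#' @return 3x4 numeric matrix.
#' @export
projection_matrix <- function(camera) {
  K <- matrix(c(camera$focal[1], 0, 0,
                0, camera$focal[2], 0,
                camera$center[1], camera$center[2], 1), 3, 3)
  K %*% cbind(camera$rotation, camera$translation)
}

#' Project 3D points into a camera
#'
#' @param camera a [camera_model()].
#' @param points length-3 vector or Nx3 matrix of world points (cm).
#' @return Nx2 matrix of pixel coordinates.
#' @export
project <- function(camera, points) {
  P <- if (is.matrix(points)) points else matrix(points, 1L)
  stopifnot(ncol(P) == 3L)
  Xc <- P %*% t(camera$rotation) +
    matrix(camera$translation, nrow(P), 3L, byrow = TRUE)
  z <- Xc[, 3L]
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop("point(s) at non-positive depth: behind or in the plane of the camera")
  }
  xn <- Xc[, 1L] / z
  yn <- Xc[, 2L] / z
  if (!is.null(camera$distortion)) {
    r2 <- xn^2 + yn^2
    d <- 1 + camera$distortion[1] * r2 + camera$distortion[2] * r2^2
    xn <- xn * d; yn <- yn * d
  }
  cbind(camera$focal[1] * xn + camera$center[1],
        camera$focal[2] * yn + camera$center[2])
}

# pixel -> normalized image coordinates, undoing radial distortion by
# fixed-point iteration (exact when the camera has no distortion)
undistort_normalized <- function(camera, px) {
  xn <- (px[1] - camera$center[1]) / camera$focal[1]
  yn <- (px[2] - camera$center[2]) / camera$focal[2]
  if (is.null(camera$distortion)) return(c(xn, yn))
  x <- xn; y <- yn
  for (i in 1:20) {
    r2 <- x^2 + y^2
    d <- 1 + camera$distortion[1] * r2 + camera$distortion[2] * r2^2
    x <- xn / d; y <- yn / d
  }
  c(x, y)
}

#' Triangulate one 3D point from multiple calibrated views
#'
#' Confidence-weighted linear (DLT) triangulation: each observation contributes
#' two homogeneous equations scaled by its confidence; the point is the null
#' vector of the stacked system (smallest eigenvector of A'A). Observations
#' with confidence 0 are ignored. The solution is independent of observation
#' order.
#'
#' @param observations list of `list(camera =, pixel =, confidence =)` entries.
#' @param min_views minimum number of positive-confidence views required.
#' @return `list(point, rms, valid, n_views)`; `valid = FALSE` (point `NA`)
#'   when fewer than `min_views` usable observations remain or the system is
#'   degenerate, with a `reason` attribute.
#' @export
triangulate <- function(observations, min_views = 2L) {
  obs <- Filter(function(o) isTRUE(o$confidence > 0), observations)
  n <- length(obs)
  invalid <- function(reason) {
    structure(list(point = rep(NA_real_, 3L), rms = NA_real_,
                   valid = FALSE, n_views = n, reason = reason))
  }
  if (n < min_views) return(invalid("fewer than min_views valid observations"))
  A <- matrix(0, 2L * n, 4L)
  for (i in seq_len(n)) {
    o <- obs[[i]]
    nc <- undistort_normalized(o$camera, o$pixel)
    Pn <- cbind(o$camera$rotation, o$camera$translation)  # normalized projection
    w <- o$confidence
    A[2L * i - 1L, ] <- w * (nc[1] * Pn[3L, ] - Pn[1L, ])
    A[2L * i, ]      <- w * (nc[2] * Pn[3L, ] - Pn[2L, ])
  }
  e <- eigen(crossprod(A), symmetric = TRUE)
  X <- e$vectors[, 4L]
  if (abs(X[4L]) < 1e-12 * max(abs(X))) return(invalid("point at infinity"))
  # rank check: a well-posed system has exactly one (near-)zero eigenvalue
  if (e$values[3L] < 1e-12 * max(e$values[1L], .Machine$double.eps)) {
    return(invalid("degenerate geometry (rank-deficient system)"))
  }
  pt <- X[1:3] / X[4L]
  err2 <- vapply(obs, function(o) {
    sum((as.numeric(project(o$camera, pt)) - as.numeric(o$pixel))^2)
  }, numeric(1))
  list(point = pt, rms = sqrt(mean(err2)), valid = TRUE, n_views = n)
}

#' Triangulate a full 25-keypoint frame from per-camera 2D poses
#'
#' @param cameras list of [camera_model()] objects, one per view.
#' @param poses2d list (same length) of 25x3 matrices `(x, y, confidence)`; a
#'   `NULL` entry marks a camera with no detection for this frame.
#' @param min_views passed to [triangulate()].
#' @return `list(points)` 25x3 matrix (cm), `valid` logical 25, `rms` numeric 25.
#' @export
triangulate_pose <- function(cameras, poses2d, min_views = 2L) {
  stopifnot(length(cameras) == length(poses2d))
  pts <- matrix(NA_real_, 25L, 3L)
  valid <- logical(25L)
  rms <- rep(NA_real_, 25L)
  for (k in 1:25) {
    obs <- list()
    for (v in seq_along(cameras)) {
      p2 <- poses2d[[v]]
      if (is.null(p2)) next
      if (p2[k, 3L] > 0) {
        obs[[length(obs) + 1L]] <- list(camera = cameras[[v]],
                                        pixel = p2[k, 1:2],
                                        confidence = p2[k, 3L])
      }
    }
    tr <- triangulate(obs, min_views = min_views)
    if (tr$valid) {
      pts[k, ] <- tr$point; valid[k] <- TRUE; rms[k] <- tr$rms
    }
  }
  list(points = pts, valid = valid, rms = rms)
}

#' Write / read a multi-camera calibration file (YAML)
#'
#' @param cameras list of [camera_model()] objects.
#' @param path file path.
#' @return `read_calibration` returns a list of [camera_model()] objects.
#' @export
write_calibration <- function(cameras, path) {
  ser <- lapply(cameras, function(cm) {
    list(focal = as.numeric(cm$focal), center = as.numeric(cm$center),
         image_size = as.numeric(cm$image_size),
         rotation = as.numeric(t(cm$rotation)),  # row-major
         translation = as.numeric(cm$translation),
         distortion = if (is.null(cm$distortion)) NULL else as.numeric(cm$distortion))
  })
  yaml::write_yaml(list(cameras = ser), path, precision = 17L)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw$cameras, function(cm) {
    camera_model(cm$focal, cm$center, cm$image_size,
                 matrix(cm$rotation, 3L, 3L, byrow = TRUE),
                 cm$translation, cm$distortion)
  })
}
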
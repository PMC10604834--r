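# Independent oracles and fixture builders shared across the test files.

# Brute-force segmental CoM: discretizes every segment into n point masses
# whose positions along the segment average to exactly k (a symmetric
# sinusoidal spread about k), then mass-weights the resulting point cloud.
# Independent of the closed-form path in body_com().
brute_force_com <- function(points, model, n = 1e4) {
  seg <- model$segments
  i <- seq_len(n)
  total <- c(0, 0, 0); mass <- 0
  for (s in seq_len(nrow(seg))) {
    p <- points[seg$proximal_idx[s] + 1L, ]
    q <- points[seg$distal_idx[s] + 1L, ]
    k <- seg$k[s]
    delta <- 0.9 * min(k, 1 - k)
    u <- k + delta * sin(2 * pi * i / n)
    cloud <- cbind(p[1] + u * (q[1] - p[1]),
                   p[2] + u * (q[2] - p[2]),
                   p[3] + u * (q[3] - p[3]))
    m <- seg$mass_fraction[s] * model$total_mass
    total <- total + m * colMeans(cloud)
    mass <- mass + m
  }
  total / mass
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# small camera ring looking at the origin from random positions
random_rig <- function(n_cameras = 3, radius = 200) {
  lapply(seq_len(n_cameras), function(i) {
    a <- stats::runif(1, 0, 2 * pi)
    h <- stats::runif(1, -40, 80)
    pos <- c(radius * sin(a), h, radius * cos(a))
    z <- -pos / sqrt(sum(pos^2))
    x <- c(z[3], 0, -z[1]); x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    camera_model(1200, c(960, 540), c(1920, 1080), rbind(x, y, z),
                 -drop(rbind(x, y, z) %*% pos))
  })
}

observe_point <- function(rig, pt, confidence = rep(1, length(rig))) {
  lapply(seq_along(rig), function(v) {
    list(camera = rig[[v]], pixel = as.numeric(project(rig[[v]], pt)),
         confidence = confidence[v])
  })
}

# random plausible pose: keypoints scattered in a body-sized box
random_pose <- function() {
  matrix(stats::rnorm(75, 0, 30), 25, 3)
}

random_body_model <- function(sex = sample(c("male", "female"), 1)) {
  tab <- default_segment_table(sex)
  tab$k <- stats::runif(nrow(tab))
  f <- stats::runif(nrow(tab))
  tab$mass_fraction <- 0.9 * f / sum(f)
  body_model(sex, stats::runif(1, 45, 110), segments = tab)
}

# nonlinear reprojection refinement used as the independent triangulation
# oracle on noisy observations
refine_triangulation <- function(observations, start) {
  sse <- function(p) {
    sum(vapply(observations, function(o) {
      o$confidence^2 * sum((as.numeric(project(o$camera, p)) -
                              as.numeric(o$pixel))^2)
    }, numeric(1)))
  }
  stats::optim(start, sse, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))$par
}

tiny_config <- function(...) {
  generator_config(n_rows = c(male = 12, female = 12), fps = 10, ...)
}
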
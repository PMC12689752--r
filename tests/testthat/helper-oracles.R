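# Shared fixtures and independent oracles used across the suite.

rand_point <- function(scale = 100) runif(3, -scale, scale)

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Random well-conditioned landmark triangle (rejection-sampled on area).
rand_landmarks <- function(scale = 100) {
  repeat {
    a <- rand_point(scale); b <- rand_point(scale); s <- rand_point(scale)
    area <- 0.5 * sqrt(sum(pracma_cross(b - a, s - a)^2))
    if (area > 500) return(landmark_set(a, b, s))
  }
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

rand_similarity <- function(scale_range = c(0.6, 1.8)) {
  similarity_transform(rand_rotation(), runif(3, -150, 150),
                       runif(1, scale_range[1], scale_range[2]))
}

rand_trajectory <- function(scale = 80) {
  repeat {
    e <- rand_point(scale); a <- rand_point(scale)
    if (sqrt(sum((a - e)^2)) > 20) break
  }
  trajectory(e, a, diameter = runif(1, 4, 9), depth = runif(1, 40, 120))
}

# Independent Gram-Schmidt frame construction (oracle for build_frame).
gram_schmidt_frame <- function(lm) {
  origin <- (lm$left_asis + lm$right_asis) / 2
  u1 <- lm$right_asis - lm$left_asis
  e1 <- u1 / sqrt(sum(u1^2))
  u2 <- lm$symphysis - origin
  u2 <- u2 - sum(u2 * e1) * e1
  e2 <- u2 / sqrt(sum(u2^2))                       # inferior
  e3 <- pracma_cross(e1, e2)                       # anterior
  list(origin = origin, lateral_right = e1, inferior = e2, anterior = e3)
}

# Dense-sampling MLD oracle: max orthogonal distance of sampled points on
# the drilled inserted segment to the planned infinite axis.
mld_dense <- function(planned, drilled, n = 1e5) {
  dirp <- trajectory_direction(planned)
  t <- seq(0, 1, length.out = n)
  seg <- outer(t, trajectory_tip(drilled) - drilled$entry) +
    matrix(drilled$entry, n, 3, byrow = TRUE)
  d <- seg - matrix(planned$entry, n, 3, byrow = TRUE)
  proj <- as.numeric(d %*% dirp)
  perp <- d - outer(proj, dirp)
  dist <- sqrt(rowSums(perp^2))
  list(mld = max(dist), location = if (which.max(dist) > n / 2) "tip" else "base",
       t = t[which.max(dist)])
}

# Brute-force perforation oracle: sample the screw capsule surface and test
# each point against the corridor capsule (distance to axis segment vs
# corridor radius).
perforation_sampled <- function(drilled, corridor, n = 1e4) {
  a <- drilled$entry; b <- trajectory_tip(drilled)
  r <- drilled$diameter / 2
  axis <- (b - a) / sqrt(sum((b - a)^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- pracma_cross(axis, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(axis, e1)
  L <- sqrt(sum((b - a)^2))
  n_cyl <- round(0.7 * n); n_cap <- n - n_cyl
  th <- runif(n_cyl, 0, 2 * pi); h <- runif(n_cyl, 0, L)
  cyl <- matrix(a, n_cyl, 3, byrow = TRUE) + outer(h, axis) +
    r * (outer(cos(th), e1) + outer(sin(th), e2))
  u <- matrix(rnorm(3 * n_cap), n_cap, 3)
  u <- u / sqrt(rowSums(u^2))
  ax_proj <- as.numeric(u %*% axis)
  centers <- ifelse(ax_proj >= 0, 1, 0)  # +axis hemisphere -> tip cap
  caps <- u * r + t(vapply(centers, function(ci) if (ci == 1) b else a,
                           numeric(3)))
  pts <- rbind(cyl, caps)
  d <- seg_dist_matrix(pts, corridor$axis_entry, corridor$axis_end)
  max_excess <- max(d) - corridor$radius
  list(perforated = max_excess > 0, max_excess = max_excess)
}

seg_dist_matrix <- function(p, a, b) {
  ab <- b - a
  tt <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
           (p[, 3] - a[3]) * ab[3]) / sum(ab^2)
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((p[, 1] - a[1] - tt * ab[1])^2 +
         (p[, 2] - a[2] - tt * ab[2])^2 +
         (p[, 3] - a[3] - tt * ab[3])^2)
}

# Temp-file helper for I/O round-trip tests.
withr_local_file <- function(name, env = parent.frame()) {
  path <- file.path(tempdir(), name)
  withr::defer(unlink(path), envir = env)
  path
}

shared_direction_flag_test <- function(x) pelvnav:::shared_direction_flag(x)

# Geodesic distance between two rotations, in radians.
rotation_geodesic <- function(R1, R2) {
  R <- t(R1) %*% R2
  acos(min(max((sum(diag(R)) - 1) / 2, -1), 1))
}

# Build a perfect-insertion pose log for a list of planned trajectories:
# approach the entry, align to the aim, advance to depth, per screw.
perfect_pose_log <- function(plans, order, dt = 0.1) {
  rows <- list(); t <- 0
  for (label in order) {
    tr <- plans[[label]]
    dir <- trajectory_direction(tr)
    approach <- tr$entry - 30 * dir
    for (p in list(approach, tr$entry)) {
      rows[[length(rows) + 1]] <- data.frame(
        t = t, tip_x = p[1], tip_y = p[2], tip_z = p[3],
        dir_x = dir[1], dir_y = dir[2], dir_z = dir[3])
      t <- t + dt
    }
    for (frac in seq(0.25, 1, by = 0.25)) {
      p <- tr$entry + frac * tr$depth * dir
      rows[[length(rows) + 1]] <- data.frame(
        t = t, tip_x = p[1], tip_y = p[2], tip_z = p[3],
        dir_x = dir[1], dir_y = dir[2], dir_z = dir[3])
      t <- t + dt
    }
  }
  do.call(rbind, rows)
}
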
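# Core 3-D types: points, landmark sets, anatomical frames, similarity
# transforms and trajectories. All lengths are millimetres; angles are
# reported in degrees, internal math in radians.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vnormalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p))) {
    stop(sprintf("%s must be 3 finite coordinates", what), call. = FALSE)
  }
  p
}

# Runs `code` with a temporarily seeded RNG stream, restoring the caller's
# stream afterwards; NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Create a labelled three-landmark set
#'
#' The registration fiducials are the two anterior superior iliac spines
#' (ASIS) and the pubic symphysis, in one common coordinate space
#' (millimetres). The three points must be non-collinear: the triangle they
#' span defines the registration plane.
#'
#' @param left_asis,right_asis,symphysis Numeric length-3 coordinates (mm).
#' @param min_area Minimum admissible triangle area in mm^2. Palpable pelvic
#'   landmarks are centimetres apart, so the default of 1 mm^2 only rejects
#'   genuinely degenerate input.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(left_asis, right_asis, symphysis, min_area = 1) {
  lm <- structure(
    list(
      left_asis = as_point3(left_asis, "left_asis"),
      right_asis = as_point3(right_asis, "right_asis"),
      symphysis = as_point3(symphysis, "symphysis")
    ),
    class = "landmark_set"
  )
  area <- 0.5 * vnorm(vcross(lm$right_asis - lm$left_asis,
                             lm$symphysis - lm$left_asis))
  if (!is.finite(area) || area < min_area) {
    stop(sprintf(
      "degenerate landmark geometry: triangle area %.3g mm^2 < %g mm^2",
      area, min_area
    ), call. = FALSE)
  }
  lm
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> (mm)\n")
  for (nm in names(x)) {
    cat(sprintf("  %-10s [%9.3f %9.3f %9.3f]\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  invisible(x)
}

landmark_matrix <- function(lm) {
  rbind(left_asis = lm$left_asis, right_asis = lm$right_asis,
        symphysis = lm$symphysis)
}

#' Build the anatomical reference frame from the three landmarks
#'
#' The frame origin is the midpoint of the two ASIS. `lateral_right` points
#' from the left to the right ASIS; `inferior` is the direction towards the
#' symphysis orthogonalised against the inter-ASIS axis (so the symphysis
#' lies, by construction, in the plane spanned by `lateral_right` and
#' `inferior` at the origin); `anterior = lateral_right x inferior` completes
#' a right-handed orthonormal triad, and `superior = -inferior`.
#'
#' This is the plane the matching step aligns; tilting it about the
#' inter-ASIS axis (e.g. by marking the symphysis too far anteriorly) is the
#' error mode the sensitivity module quantifies.
#'
#' @param landmarks A [landmark_set()].
#' @return An object of class `anatomical_frame` with fields `origin`,
#'   `lateral_right`, `inferior`, `anterior`, `superior`.
#' @export
build_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  origin <- (landmarks$left_asis + landmarks$right_asis) / 2
  lateral <- vnormalize(landmarks$right_asis - landmarks$left_asis)
  u <- landmarks$symphysis - origin
  u_perp <- u - sum(u * lateral) * lateral
  if (vnorm(u_perp) < 1e-9) {
    stop("degenerate landmark geometry: symphysis lies on the inter-ASIS axis",
         call. = FALSE)
  }
  inferior <- vnormalize(u_perp)
  anterior <- vcross(lateral, inferior)
  structure(
    list(
      origin = origin,
      lateral_right = lateral,
      inferior = inferior,
      anterior = anterior,
      superior = -inferior
    ),
    class = "anatomical_frame"
  )
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-13s [%8.4f %8.4f %8.4f]\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  invisible(x)
}

#' Orthogonal distance from a point to an infinite line
#'
#' @param p Point (mm), length-3.
#' @param line_point Any point on the line.
#' @param line_dir Unit direction of the line.
#' @return Distance in mm (>= 0).
#' @export
point_line_distance <- function(p, line_point, line_dir) {
  p <- as_point3(p); line_point <- as_point3(line_point)
  line_dir <- as_point3(line_dir, "line_dir")
  if (abs(vnorm(line_dir) - 1) > 1e-6) line_dir <- vnormalize(line_dir)
  d <- p - line_point
  vnorm(d - sum(d * line_dir) * line_dir)
}

# Distance from point(s) to a finite segment [a, b]; `p` may be a vector or
# an n x 3 matrix (vectorised for the sampling oracles).
point_segment_distance <- function(p, a, b) {
  a <- as_point3(a); b <- as_point3(b)
  ab <- b - a
  len2 <- sum(ab * ab)
  if (len2 < 1e-18) stop("degenerate segment", call. = FALSE)
  if (is.matrix(p)) {
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
            (p[, 3] - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- p[, 1] - (a[1] + t * ab[1])
    dy <- p[, 2] - (a[2] + t * ab[2])
    dz <- p[, 3] - (a[3] + t * ab[3])
    sqrt(dx * dx + dy * dy + dz * dz)
  } else {
    p <- as_point3(p)
    t <- min(max(sum((p - a) * ab) / len2, 0), 1)
    vnorm(p - (a + t * ab))
  }
}

#' Similarity transform (rotation, translation, isotropic scale)
#'
#' Maps model-space points into world space as `scale * R %*% p + t`. The
#' matching step that "resizes and aligns" the planned pelvis is exactly such
#' a transform.
#'
#' @param rotation 3x3 proper orthonormal matrix (det = +1).
#' @param translation Length-3 translation (mm).
#' @param scale Positive isotropic scale factor.
#' @return Object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                 scale = 1) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as_point3(translation, "translation")
  scale <- as.numeric(scale)
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be proper (det = +1); reflections are not admissible",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation, scale = scale),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<similarity_transform> scale %.6g, rotation %.3f deg, translation [%.3f %.3f %.3f] mm\n",
              x$scale, ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a similarity transform to one or many points
#'
#' @param transform A [similarity_transform()].
#' @param p A length-3 point or an n x 3 matrix of points.
#' @return Transformed point(s), same shape as `p`.
#' @export
transform_point <- function(transform, p) {
  stopifnot(inherits(transform, "similarity_transform"))
  if (is.matrix(p)) {
    sweep(p %*% t(transform$rotation) * transform$scale, 2,
          transform$translation, "+")
  } else {
    as.numeric(transform$scale * (transform$rotation %*% as_point3(p)) +
                 transform$translation)
  }
}

#' Compose two similarity transforms
#'
#' `compose_transform(a, b)` returns the transform that applies `b` first and
#' then `a`, i.e. `(a o b)(p) = a(b(p))`.
#'
#' @param a,b [similarity_transform()] objects.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "similarity_transform"),
            inherits(b, "similarity_transform"))
  similarity_transform(
    rotation = a$rotation %*% b$rotation,
    translation = as.numeric(a$scale * (a$rotation %*% b$translation)) +
      a$translation,
    scale = a$scale * b$scale
  )
}

#' Invert a similarity transform
#'
#' @param transform A [similarity_transform()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  rinv <- t(transform$rotation)
  similarity_transform(
    rotation = rinv,
    translation = as.numeric(-(rinv %*% transform$translation) / transform$scale),
    scale = 1 / transform$scale
  )
}

#' Apply a similarity transform to a landmark set
#' @param transform A [similarity_transform()].
#' @param landmarks A [landmark_set()].
#' @export
transform_landmarks <- function(transform, landmarks) {
  landmark_set(
    transform_point(transform, landmarks$left_asis),
    transform_point(transform, landmarks$right_asis),
    transform_point(transform, landmarks$symphysis)
  )
}

# Rotation angle (deg) of a 3x3 rotation matrix.
rotation_angle_deg <- function(R) {
  cosang <- (sum(diag(R)) - 1) / 2
  acos(min(max(cosang, -1), 1)) * RAD2DEG
}

# Rotation axis (unit vector) of a 3x3 rotation matrix; undefined (NA) for
# the identity.
rotation_axis <- function(R) {
  ang <- rotation_angle_deg(R) * DEG2RAD
  if (ang < 1e-12) return(c(NA_real_, NA_real_, NA_real_))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(ax) < 1e-9) {
    # angle near pi: axis from the dominant column of R + I
    M <- R + diag(3)
    ax <- M[, which.max(colSums(M^2))]
  }
  vnormalize(ax)
}

# Rodrigues rotation matrix about unit `axis` by `angle` radians.
rotation_about_axis <- function(axis, angle) {
  axis <- vnormalize(as_point3(axis, "axis"))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniform random rotation via a normalised quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Planned or drilled screw trajectory
#'
#' A trajectory is the axis of a screw: the skin-side entry point, the
#' central aim point (the planned target at the vertebral body centre), the
#' screw diameter and the insertion depth measured from the entry along the
#' axis to the screw tip. When `depth` is omitted it defaults to the
#' entry-to-aim distance (tip at the central aim point).
#'
#' @param entry,central_aim Length-3 points (mm); must differ.
#' @param diameter Screw diameter in mm (> 0). Default 7.5 mm, a standard
#'   cannulated SI screw.
#' @param depth Insertion depth in mm (> 0).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(entry, central_aim, diameter = 7.5, depth = NULL) {
  entry <- as_point3(entry, "entry")
  central_aim <- as_point3(central_aim, "central_aim")
  if (vnorm(central_aim - entry) < 1e-9) {
    stop("entry and central_aim must differ", call. = FALSE)
  }
  if (is.null(depth)) depth <- vnorm(central_aim - entry)
  diameter <- as.numeric(diameter); depth <- as.numeric(depth)
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be > 0", call. = FALSE)
  if (!is.finite(depth) || depth <= 0) stop("depth must be > 0", call. = FALSE)
  structure(list(entry = entry, central_aim = central_aim,
                 diameter = diameter, depth = depth),
            class = "trajectory")
}

#' Unit direction of a trajectory (entry towards central aim)
#' @param traj A [trajectory()].
#' @export
trajectory_direction <- function(traj) {
  vnormalize(traj$central_aim - traj$entry)
}

#' Tip of the inserted screw: entry + depth * direction
#' @param traj A [trajectory()].
#' @export
trajectory_tip <- function(traj) {
  traj$entry + traj$depth * trajectory_direction(traj)
}

#' Apply a similarity transform to a trajectory
#'
#' Entry and aim points are mapped through the transform; the depth scales
#' with the transform's scale factor, the diameter (a physical screw
#' property) does not.
#'
#' @param transform A [similarity_transform()].
#' @param traj A [trajectory()].
#' @export
transform_trajectory <- function(transform, traj) {
  trajectory(
    entry = transform_point(transform, traj$entry),
    central_aim = transform_point(transform, traj$central_aim),
    diameter = traj$diameter,
    depth = traj$depth * transform$scale
  )
}
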
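# Screw-placement evaluation geometry: maximal lateral deviation (MLD) with
# base/tip localisation, entry / central-aim / angular deviations, cortical
# perforation detection with anatomical direction classification, and the
# per-screw placement report.

#' Maximal lateral deviation (MLD) of a drilled screw
#'
#' The MLD is the biggest orthogonal distance of any point on the drilled
#' axis from the planned axis. The drilled axis is evaluated over the
#' inserted segment, from the entry (base) to the screw tip (entry + depth
#' along the axis); the planned axis is the infinite line through the
#' planned entry and central aim. The distance from a point moving affinely
#' along the drilled segment to a fixed line is convex in the segment
#' parameter, so the maximum is always attained at an endpoint — MLD
#' localises to the base or the tip by construction.
#'
#' Ties between base and tip are reported as `"tip"` (the clinically riskier
#' end, deep near the neural structures).
#'
#' @param planned,drilled [trajectory()] objects in a common space.
#' @return List with `mld` (mm) and `location` (`"base"` or `"tip"`).
#' @export
mld <- function(planned, drilled) {
  stopifnot(inherits(planned, "trajectory"), inherits(drilled, "trajectory"))
  dir_p <- trajectory_direction(planned)
  d_base <- point_line_distance(drilled$entry, planned$entry, dir_p)
  d_tip <- point_line_distance(trajectory_tip(drilled), planned$entry, dir_p)
  if (d_tip >= d_base) {
    list(mld = d_tip, location = "tip")
  } else {
    list(mld = d_base, location = "base")
  }
}

#' Entry-point deviation
#'
#' Euclidean distance between the planned and drilled entry points.
#' @param planned,drilled [trajectory()] objects.
#' @return Distance in mm.
#' @export
entry_deviation <- function(planned, drilled) {
  vnorm(drilled$entry - planned$entry)
}

#' Central-aim-point deviation
#'
#' Euclidean distance between the planned central aim point and the drilled
#' screw tip. Using the tip (not the closest approach of the drilled axis)
#' makes the metric depth-dependent: drilling short or past the target shows
#' up here even on a perfectly aligned axis.
#'
#' @param planned,drilled [trajectory()] objects.
#' @return Distance in mm.
#' @export
central_aim_deviation <- function(planned, drilled) {
  vnorm(trajectory_tip(drilled) - planned$central_aim)
}

#' Angular deviation between planned and drilled axes
#'
#' Angle between the two direction vectors in degrees, in [0, 180] with no
#' folding (antiparallel axes report 180).
#'
#' @param planned,drilled [trajectory()] objects.
#' @return Angle in degrees.
#' @export
angular_deviation <- function(planned, drilled) {
  u <- trajectory_direction(planned)
  v <- trajectory_direction(drilled)
  # atan2 of |u x v| against u.v is accurate near 0 and 180 degrees, where
  # the arccos of the dot product loses half the significant digits
  atan2(vnorm(vcross(u, v)), sum(u * v)) * RAD2DEG
}

# Direction labels from the radial offset projected on the (anterior,
# superior) plane, 8-sector compass: the primary label is the dominant
# component; a secondary label is added when the minor component is at
# least tan(22.5 deg) of the major one (sector boundaries at 22.5 deg).
classify_breach_direction <- function(offset, frame) {
  a <- sum(offset * frame$anterior)
  s <- sum(offset * frame$superior)
  lab_a <- if (a >= 0) "anterior" else "posterior"
  lab_s <- if (s >= 0) "superior" else "inferior"
  if (abs(a) < 1e-12 && abs(s) < 1e-12) return(lab_a)  # degenerate: axial breach
  thresh <- tan(22.5 * DEG2RAD)
  if (abs(a) >= abs(s)) {
    if (abs(s) >= thresh * abs(a)) c(lab_a, lab_s) else lab_a
  } else {
    if (abs(a) >= thresh * abs(s)) c(lab_s, lab_a) else lab_s
  }
}

#' Detect cortical perforation of a drilled screw in its corridor
#'
#' The screw is modelled as a capsule of radius `diameter/2` along the
#' drilled inserted segment; the corridor as a capsule of its radius along
#' its axis segment. A perforation (breach of the cortical layer bounding
#' the corridor) occurs iff at some normalised position `t` along the
#' insertion the distance from the drilled axis point to the corridor axis
#' plus the screw radius exceeds the corridor radius. That excess is convex
#' in `t`, so the worst breach is found exactly at an endpoint.
#'
#' The breach direction is classified from the radial offset vector at the
#' worst breach (drilled axis point minus its closest point on the corridor
#' axis), projected onto the anatomical (anterior, superior) plane, using
#' 8-sector compass logic: pure labels (anterior into the small pelvis,
#' superior/inferior into the neuroforamina, posterior into the spinal
#' canal) or adjacent combinations such as anterior+superior.
#'
#' @param drilled The drilled [trajectory()].
#' @param corridor A corridor (see [make_phantom()]), same space.
#' @param frame The [build_frame()] anatomical frame, same space.
#' @return List of class `perforation_finding`: `perforated` (logical),
#'   `directions` (character, empty when not perforated), `breach_depth`
#'   (mm beyond the corridor surface, 0 when not perforated),
#'   `breach_location_t` (normalised insertion position of the worst
#'   breach, NA when not perforated), `regions` (semantic regions breached).
#' @export
detect_perforation <- function(drilled, corridor, frame) {
  stopifnot(inherits(drilled, "trajectory"), inherits(frame, "anatomical_frame"))
  if (vnorm(corridor$axis_end - corridor$axis_entry) < 1e-9) {
    stop("degenerate corridor axis", call. = FALSE)
  }
  r_screw <- drilled$diameter / 2
  ends <- rbind(drilled$entry, trajectory_tip(drilled))
  d <- point_segment_distance(ends, corridor$axis_entry, corridor$axis_end)
  excess <- d + r_screw - corridor$radius
  worst <- which.max(excess)
  if (excess[worst] <= 0) {
    return(structure(
      list(perforated = FALSE, directions = character(0), breach_depth = 0,
           breach_location_t = NA_real_, regions = character(0)),
      class = "perforation_finding"
    ))
  }
  p_worst <- ends[worst, ]
  # closest point on the corridor axis segment
  ab <- corridor$axis_end - corridor$axis_entry
  t_ax <- min(max(sum((p_worst - corridor$axis_entry) * ab) / sum(ab * ab), 0), 1)
  offset <- p_worst - (corridor$axis_entry + t_ax * ab)
  dirs <- classify_breach_direction(offset, frame)
  structure(
    list(
      perforated = TRUE,
      directions = dirs,
      breach_depth = excess[worst],
      breach_location_t = c(0, 1)[worst],
      regions = unique(unname(corridor$forbidden_regions[dirs]))
    ),
    class = "perforation_finding"
  )
}

#' Detect perforation against a triangle-mesh corridor
#'
#' Mesh-based variant of [detect_perforation()]: points sampled on the screw
#' capsule surface (default density 1 point per mm^2) are tested for
#' containment in the closed corridor mesh by ray-parity; the screw
#' perforates iff any sampled surface point lies outside. Directions are
#' classified from the worst outside point relative to its nearest point on
#' the drilled axis.
#'
#' @param drilled The drilled [trajectory()].
#' @param mesh A closed `pelvnav_mesh` bounding the safe channel.
#' @param frame The anatomical frame.
#' @param density Surface sampling density, points per mm^2.
#' @return A `perforation_finding` (breach depth is the mesh distance proxy:
#'   distance from the worst point to the drilled axis minus screw radius is
#'   not meaningful here, so `breach_depth` reports the count-weighted
#'   maximum penetration is unavailable and is set to `NA` when perforated).
#' @export
detect_perforation_mesh <- function(drilled, mesh, frame, density = 1) {
  stopifnot(inherits(mesh, "pelvnav_mesh"))
  pts <- sample_capsule_surface(drilled$entry, trajectory_tip(drilled),
                                drilled$diameter / 2, density = density)
  inside <- point_in_mesh(mesh, pts)
  if (all(inside)) {
    return(structure(
      list(perforated = FALSE, directions = character(0), breach_depth = 0,
           breach_location_t = NA_real_, regions = character(0)),
      class = "perforation_finding"
    ))
  }
  out_pts <- pts[!inside, , drop = FALSE]
  # worst point: farthest from the drilled axis segment
  dax <- point_segment_distance(out_pts, drilled$entry, trajectory_tip(drilled))
  # surface points sit at r_screw from the axis; caps can be closer in t
  worst_p <- out_pts[which.max(dax), ]
  ab <- trajectory_tip(drilled) - drilled$entry
  t_ax <- min(max(sum((worst_p - drilled$entry) * ab) / sum(ab * ab), 0), 1)
  offset <- worst_p - (drilled$entry + t_ax * ab)
  dirs <- classify_breach_direction(offset, frame)
  structure(
    list(perforated = TRUE, directions = dirs, breach_depth = NA_real_,
         breach_location_t = t_ax,
         regions = unique(unname(FORBIDDEN_REGIONS[dirs]))),
    class = "perforation_finding"
  )
}

# Quasi-uniform sample of a capsule surface (cylinder + both spherical
# caps) at `density` points per mm^2; returns an n x 3 matrix.
sample_capsule_surface <- function(a, b, radius, density = 1, n_min = 64) {
  axis <- vnormalize(b - a)
  L <- vnorm(b - a)
  basis <- perpendicular_basis(axis)
  area_cyl <- 2 * pi * radius * L
  area_caps <- 4 * pi * radius^2
  n_total <- max(n_min, ceiling(density * (area_cyl + area_caps)))
  n_cyl <- max(8, round(n_total * area_cyl / (area_cyl + area_caps)))
  n_cap <- max(8, ceiling((n_total - n_cyl) / 2))
  th <- runif(n_cyl, 0, 2 * pi)
  h <- runif(n_cyl, 0, L)
  cyl <- t(vapply(seq_len(n_cyl), function(i) {
    a + h[i] * axis + radius * (cos(th[i]) * basis[[1]] + sin(th[i]) * basis[[2]])
  }, numeric(3)))
  cap_pts <- function(center, sign_axis) {
    u <- matrix(rnorm(3 * n_cap), n_cap, 3)
    u <- u / sqrt(rowSums(u^2))
    # reflect into the hemisphere pointing along sign_axis * axis
    proj <- u %*% axis
    flip <- as.numeric(proj) * sign_axis < 0
    u[flip, ] <- -u[flip, , drop = FALSE]
    sweep(u * radius, 2, center, "+")
  }
  rbind(cyl, cap_pts(a, -1), cap_pts(b, +1))
}

#' Point-in-mesh test by ray parity
#'
#' Casts a fixed-direction ray from each query point and counts
#' intersections with the mesh triangles (Moeller-Trumbore); an odd count
#' means inside. Suitable for closed, watertight meshes such as
#' [phantom_mesh()] capsules.
#'
#' @param mesh A `pelvnav_mesh`.
#' @param points An n x 3 matrix of query points.
#' @return Logical vector of length n.
#' @export
point_in_mesh <- function(mesh, points) {
  stopifnot(inherits(mesh, "pelvnav_mesh"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  V <- mesh$vertices; FA <- mesh$faces
  # slightly irrational direction to dodge edge-on hits
  dir <- vnormalize(c(0.577215, 0.301029, 0.693147))
  v0 <- V[FA[, 1], , drop = FALSE]
  e1 <- V[FA[, 2], , drop = FALSE] - v0
  e2 <- V[FA[, 3], , drop = FALSE] - v0
  # h = dir x e2 (constant dir)
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det_a <- rowSums(e1 * h)
  ok <- abs(det_a) > 1e-12
  inv_det <- ifelse(ok, 1 / det_a, NA_real_)
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    s <- sweep(-v0, 2, p, "+")  # p - v0
    u <- rowSums(s * h) * inv_det
    q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
               s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
               s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
    v <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) * inv_det
    t <- rowSums(e2 * q) * inv_det
    hit <- ok & !is.na(u) & u >= 0 & u <= 1 & v >= 0 & (u + v) <= 1 & t > 1e-9
    sum(hit, na.rm = TRUE) %% 2L == 1L
  }, logical(1))
}

#' Evaluate one screw placement against its plan and corridor
#'
#' Assembles the full per-screw report: MLD with base/tip location, entry
#' and central-aim deviations, angular deviation, perforation finding, and
#' the correct/incorrect verdict — correct placement is defined by the
#' absence of perforation.
#'
#' @param planned,drilled [trajectory()] objects in a common (world) space.
#' @param corridor The screw's corridor, same space.
#' @param frame The anatomical frame, same space.
#' @param screw_label Label for the report row (defaults to the corridor's).
#' @return One-row tibble with columns `screw_label`, `screw_type`,
#'   `mld_mm`, `mld_location`, `entry_dev_mm`, `central_aim_dev_mm`,
#'   `angular_dev_deg`, `perforated`, `directions` (comma-joined),
#'   `breach_depth_mm`, `breach_location_t`, `correct`.
#' @export
evaluate_placement <- function(planned, drilled, corridor, frame,
                               screw_label = corridor$label) {
  m <- mld(planned, drilled)
  perf <- detect_perforation(drilled, corridor, frame)
  tibble::tibble(
    screw_label = screw_label,
    screw_type = sub("_(left|right)$", "", screw_label),
    mld_mm = m$mld,
    mld_location = m$location,
    entry_dev_mm = entry_deviation(planned, drilled),
    central_aim_dev_mm = central_aim_deviation(planned, drilled),
    angular_dev_deg = angular_deviation(planned, drilled),
    perforated = perf$perforated,
    directions = paste(perf$directions, collapse = ","),
    breach_depth_mm = perf$breach_depth,
    breach_location_t = perf$breach_location_t,
    correct = !perf$perforated
  )
}

# Stable column order for placement-report CSVs.
PLACEMENT_COLUMNS <- c("screw_label", "mld_mm", "mld_location", "entry_dev_mm",
                       "central_aim_dev_mm", "angular_dev_deg", "perforated",
                       "directions", "correct")
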
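# Parametric pelvis phantom: landmark geometry, the four sacroiliac screw
# corridors (two S1, two S2), planned trajectories along their axes, and
# the noise model for landmark probing and drilling.
#
# Model space is the anatomical frame itself: origin at the inter-ASIS
# midpoint, +x lateral-right, +y anterior, +z superior (so the sacrum sits
# at negative y, below the inter-ASIS axis at negative z).

CORRIDOR_LABELS <- c("S1_right", "S1_left", "S2_right", "S2_left")

# Semantic regions breached per direction, used in reporting.
FORBIDDEN_REGIONS <- c(
  anterior = "small pelvis",
  superior = "neuroforamina",
  inferior = "neuroforamina",
  posterior = "spinal canal"
)

#' Parameters of the synthetic pelvis phantom
#'
#' The phantom is parametric-geometric: the navigation analysis depends only
#' on the landmark geometry (how far the symphysis sits from the inter-ASIS
#' axis) and on corridor width, both of which are parameters here, not an
#' anatomical atlas.
#'
#' Defaults describe an adult pelvis at order of magnitude: ASIS 240 mm
#' apart; symphysis 90 mm below the inter-ASIS axis. The S1 vertebral body
#' offers a wider osseous corridor than the flatter, narrower S2, and sits
#' closer to the inter-ASIS axis; both structural asymmetries are encoded in
#' the defaults (`s1_radius > s2_radius`, `|z|` of the S1 centre smaller).
#' Corridor radii are phantom parameters (the narrowest safe-channel radius),
#' not published measurements; the default screw diameter of 7.5 mm is a
#' standard cannulated SI screw.
#'
#' @param asis_span Distance between the two ASIS (mm).
#' @param symphysis_drop Distance of the symphysis from the inter-ASIS axis
#'   (mm), straight inferior in model space.
#' @param s1_center,s2_center Midline centres of the S1/S2 vertebral bodies
#'   (model-space mm, length-3).
#' @param s1_radius,s2_radius Corridor radii (mm); S1 must be wider than S2.
#' @param s1_entry_x,s2_entry_x Lateral (|x|) coordinate of the corridor
#'   entry point on the iliac cortex (mm).
#' @param s1_tip_margin,s2_tip_margin How far the osseous corridor continues
#'   past the central aim point before the far cortex (mm); the S1 tip has
#'   more room than the S2 tip.
#' @param screw_diameter Screw diameter (mm).
#' @param anatomy_jitter_sigma Per-coordinate Gaussian jitter (mm) applied to
#'   landmarks and corridor centres to emulate inter-pelvis anatomical
#'   variation. Default 0: all phantoms identical, like a series of identical
#'   foam pelvis models.
#' @return Object of class `phantom_params` (a validated list).
#' @export
phantom_params <- function(asis_span = 240,
                           symphysis_drop = 90,
                           s1_center = c(0, -80, -40),
                           s2_center = c(0, -85, -70),
                           s1_radius = 7.5,
                           s2_radius = 5.5,
                           s1_entry_x = 95,
                           s2_entry_x = 90,
                           s1_tip_margin = 15,
                           s2_tip_margin = 8,
                           screw_diameter = 7.5,
                           anatomy_jitter_sigma = 0) {
  p <- list(
    asis_span = asis_span, symphysis_drop = symphysis_drop,
    s1_center = as_point3(s1_center, "s1_center"),
    s2_center = as_point3(s2_center, "s2_center"),
    s1_radius = s1_radius, s2_radius = s2_radius,
    s1_entry_x = s1_entry_x, s2_entry_x = s2_entry_x,
    s1_tip_margin = s1_tip_margin, s2_tip_margin = s2_tip_margin,
    screw_diameter = screw_diameter,
    anatomy_jitter_sigma = anatomy_jitter_sigma
  )
  num_pos <- c("asis_span", "symphysis_drop", "s1_radius", "s2_radius",
               "s1_entry_x", "s2_entry_x", "s1_tip_margin", "s2_tip_margin",
               "screw_diameter")
  for (nm in num_pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop(sprintf("phantom parameter '%s' must be a positive number", nm),
           call. = FALSE)
    }
  }
  if (!is.finite(p$anatomy_jitter_sigma) || p$anatomy_jitter_sigma < 0) {
    stop("anatomy_jitter_sigma must be >= 0", call. = FALSE)
  }
  if (p$s1_radius <= p$s2_radius) {
    stop("the S1 corridor must be wider than S2 (s1_radius > s2_radius)",
         call. = FALSE)
  }
  if (p$asis_span > 400 || p$asis_span < 120) {
    stop("asis_span outside plausible adult range [120, 400] mm", call. = FALSE)
  }
  structure(p, class = "phantom_params")
}

#' Noise model for landmark probing and drilling
#'
#' Probing noise is isotropic Gaussian per landmark (`landmark_sigma`), plus
#' one systematic term: a displacement of the probed symphysis along the
#' world anterior axis (`symphysis_anterior_bias`) — marking the symphysis
#' too far anteriorly through the soft tissue, the specific failure mode that
#' tilts the registration plane about the inter-ASIS axis. Operator error is
#' an entry-point jitter and an angular jitter of the drill axis.
#'
#' Defaults are the study conditions of the in-silico trial: 2 mm landmark
#' sigma (the typical fiducial localisation error when probing palpable bony
#' landmarks percutaneously), 1 mm entry jitter and 1 degree of axis jitter
#' for freehand alignment against a displayed trajectory, no systematic
#' bias.
#'
#' @param landmark_sigma Per-coordinate sd of probing noise (mm).
#' @param symphysis_anterior_bias Systematic symphysis offset along the
#'   world anterior axis (mm).
#' @param operator_entry_sigma Per-coordinate sd of drill entry jitter (mm).
#' @param operator_angle_sigma Sd of drill axis angular jitter (degrees).
#' @param seed Optional integer; when given, sampling functions use a local
#'   RNG stream seeded with it (the caller's stream is untouched).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(landmark_sigma = 2,
                        symphysis_anterior_bias = 0,
                        operator_entry_sigma = 1,
                        operator_angle_sigma = 1,
                        seed = NULL) {
  vals <- c(landmark_sigma = landmark_sigma,
            symphysis_anterior_bias = symphysis_anterior_bias,
            operator_entry_sigma = operator_entry_sigma,
            operator_angle_sigma = operator_angle_sigma)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all noise magnitudes must be finite and >= 0", call. = FALSE)
  }
  structure(list(landmark_sigma = landmark_sigma,
                 symphysis_anterior_bias = symphysis_anterior_bias,
                 operator_entry_sigma = operator_entry_sigma,
                 operator_angle_sigma = operator_angle_sigma,
                 seed = seed),
            class = "noise_model")
}

#' A noise model with every term zero (noiseless conditions)
#' @param seed Optional seed, see [noise_model()].
#' @export
zero_noise <- function(seed = NULL) noise_model(0, 0, 0, 0, seed = seed)

new_corridor <- function(label, axis_entry, axis_end, radius) {
  axis_entry <- as_point3(axis_entry, "axis_entry")
  axis_end <- as_point3(axis_end, "axis_end")
  if (vnorm(axis_end - axis_entry) < 1e-9) {
    stop("corridor axis must have positive length", call. = FALSE)
  }
  if (!is.finite(radius) || radius <= 0) {
    stop("corridor radius must be > 0", call. = FALSE)
  }
  structure(
    list(label = label, axis_entry = axis_entry, axis_end = axis_end,
         radius = radius, forbidden_regions = FORBIDDEN_REGIONS),
    class = "corridor"
  )
}

#' Apply a similarity transform to a corridor
#' @param transform A [similarity_transform()].
#' @param corridor A corridor as found in `PhantomPelvis$corridors`.
#' @export
transform_corridor <- function(transform, corridor) {
  new_corridor(
    corridor$label,
    transform_point(transform, corridor$axis_entry),
    transform_point(transform, corridor$axis_end),
    corridor$radius * transform$scale
  )
}

#' Generate a parametric pelvis phantom
#'
#' Builds the model-space landmark set, the four corridors ("Two S1 and two
#' S2"), and the planned trajectory along each corridor axis (entry at the
#' iliac cortex, central aim at the vertebral body centre, depth =
#' entry-to-aim distance). Deterministic for a fixed seed.
#'
#' @param params A [phantom_params()].
#' @param seed Integer seed for the anatomical jitter (only consulted when
#'   `anatomy_jitter_sigma > 0`; otherwise the phantom is fully determined by
#'   `params`).
#' @param mesh If `TRUE`, attach a triangle mesh of the corridor capsules
#'   (see [phantom_mesh()]).
#' @return Object of class `phantom_pelvis` with fields `landmarks`,
#'   `corridors` (named list of 4), `planned` (named list of 4
#'   [trajectory()]), `frame`, `mesh`, `params`.
#' @export
make_phantom <- function(params = phantom_params(), seed = NULL, mesh = FALSE) {
  stopifnot(inherits(params, "phantom_params"))
  jit <- function(p) p  # identity unless jitter requested
  if (params$anatomy_jitter_sigma > 0) {
    draws <- with_seed(seed, rnorm(18, sd = params$anatomy_jitter_sigma))
    k <- 0
    jit <- function(p) {
      idx <- k + seq_len(3); k <<- k + 3
      p + draws[idx]
    }
  }
  half <- params$asis_span / 2
  landmarks <- landmark_set(
    left_asis = jit(c(-half, 0, 0)),
    right_asis = jit(c(half, 0, 0)),
    symphysis = jit(c(0, 0, -params$symphysis_drop))
  )
  centers <- list(S1 = jit(params$s1_center), S2 = jit(params$s2_center))
  spec <- list(
    S1 = list(entry_x = params$s1_entry_x, radius = params$s1_radius,
              margin = params$s1_tip_margin),
    S2 = list(entry_x = params$s2_entry_x, radius = params$s2_radius,
              margin = params$s2_tip_margin)
  )
  corridors <- list(); planned <- list()
  for (label in CORRIDOR_LABELS) {
    lv <- sub("_(left|right)$", "", label)
    side <- if (grepl("right$", label)) 1 else -1
    s <- spec[[lv]]
    center <- centers[[lv]]
    entry <- c(side * s$entry_x, center[2], center[3])
    dir_in <- vnormalize(center - entry)
    corridors[[label]] <- new_corridor(
      label, axis_entry = entry, axis_end = center + s$margin * dir_in,
      radius = s$radius
    )
    planned[[label]] <- trajectory(entry = entry, central_aim = center,
                                   diameter = params$screw_diameter)
  }
  ph <- structure(
    list(landmarks = landmarks, corridors = corridors, planned = planned,
         frame = build_frame(landmarks), mesh = NULL, params = params),
    class = "phantom_pelvis"
  )
  if (isTRUE(mesh)) ph$mesh <- phantom_mesh(ph)
  ph
}

#' @export
print.phantom_pelvis <- function(x, ...) {
  cat("<phantom_pelvis>\n")
  cat(sprintf("  ASIS span %.0f mm, symphysis drop %.0f mm\n",
              x$params$asis_span, x$params$symphysis_drop))
  for (co in x$corridors) {
    cat(sprintf("  %-9s radius %.2f mm, axis length %.1f mm\n",
                co$label, co$radius, vnorm(co$axis_end - co$axis_entry)))
  }
  if (!is.null(x$mesh)) {
    cat(sprintf("  mesh: %d vertices, %d faces\n",
                nrow(x$mesh$vertices), nrow(x$mesh$faces)))
  }
  invisible(x)
}

#' Probe the phantom landmarks in world space with noise
#'
#' Returns the world-space landmark coordinates a navigator would probe:
#' `world_transform(model landmarks)` plus isotropic Gaussian noise per
#' landmark, with the probed symphysis additionally displaced by
#' `symphysis_anterior_bias` along the world anterior axis (the anterior
#' axis of the frame built from the noise-free transformed landmarks).
#'
#' @param phantom A [make_phantom()] result.
#' @param world_transform Model-to-world [similarity_transform()] (the true
#'   pose of the pelvis on the table).
#' @param noise A [noise_model()].
#' @return A [landmark_set()] in world space.
#' @export
probe_landmarks <- function(phantom, world_transform = similarity_transform(),
                            noise = zero_noise()) {
  stopifnot(inherits(phantom, "phantom_pelvis"),
            inherits(noise, "noise_model"))
  true_world <- transform_landmarks(world_transform, phantom$landmarks)
  world_frame <- build_frame(true_world)
  with_seed(noise$seed, {
    eps <- if (noise$landmark_sigma > 0) {
      matrix(rnorm(9, sd = noise$landmark_sigma), 3, 3)
    } else matrix(0, 3, 3)
    landmark_set(
      left_asis = true_world$left_asis + eps[1, ],
      right_asis = true_world$right_asis + eps[2, ],
      symphysis = true_world$symphysis + eps[3, ] +
        noise$symphysis_anterior_bias * world_frame$anterior
    )
  })
}

#' Simulate one drilling against a displayed (possibly misregistered) plan
#'
#' The navigator displays the planned trajectory where the registration puts
#' it; the drilled trajectory is therefore the planned one mapped through
#' `guidance_error` — the world-space error transform `est o truth^-1`
#' combining matching imprecision and hologram drift — then perturbed by the
#' operator: Gaussian entry jitter and an exact (Rodrigues) angular jitter of
#' the axis about a random direction perpendicular to it. Depth is preserved.
#'
#' @param planned_world The planned [trajectory()] in (true) world space.
#' @param guidance_error World-space [similarity_transform()]; identity means
#'   perfect registration.
#' @param noise A [noise_model()] (only the operator terms are used).
#' @return The drilled [trajectory()].
#' @export
simulate_drilling <- function(planned_world,
                              guidance_error = similarity_transform(),
                              noise = zero_noise()) {
  stopifnot(inherits(planned_world, "trajectory"),
            inherits(noise, "noise_model"))
  displayed <- transform_trajectory(guidance_error, planned_world)
  with_seed(noise$seed, {
    entry <- displayed$entry
    if (noise$operator_entry_sigma > 0) {
      entry <- entry + rnorm(3, sd = noise$operator_entry_sigma)
    }
    dir <- trajectory_direction(displayed)
    if (noise$operator_angle_sigma > 0) {
      # two small tilt components about perpendicular axes -> exact rotation
      basis <- perpendicular_basis(dir)
      tilt <- rnorm(2, sd = noise$operator_angle_sigma * DEG2RAD)
      ang <- sqrt(sum(tilt^2))
      if (ang > 0) {
        axis <- vnormalize(tilt[1] * basis[[1]] + tilt[2] * basis[[2]])
        dir <- vnormalize(as.numeric(rotation_about_axis(axis, ang) %*% dir))
      }
    }
    aim_dist <- vnorm(displayed$central_aim - displayed$entry)
    trajectory(
      entry = entry,
      central_aim = entry + aim_dist * dir,
      diameter = planned_world$diameter,
      depth = planned_world$depth
    )
  })
}

# Two unit vectors completing `dir` to an orthonormal triad.
perpendicular_basis <- function(dir) {
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- vnormalize(vcross(dir, ref))
  e2 <- vcross(dir, e1)
  list(e1, e2)
}

#' Triangle mesh of the phantom's osseous corridors
#'
#' Triangulates each corridor as a closed capsule (cylinder with
#' hemispherical caps) and merges them into one mesh. The mesh models
#' exactly the structures the navigation analysis uses — the safe channels —
#' not the full pelvic cortex.
#'
#' @param phantom A [make_phantom()] result.
#' @param n_theta Circumferential segments per capsule (default 24).
#' @param n_cap Latitudinal rings per hemispherical cap (default 6).
#' @return Object of class `pelvnav_mesh`: list with `vertices` (n x 3) and
#'   `faces` (m x 3, 1-based vertex indices).
#' @export
phantom_mesh <- function(phantom, n_theta = 24, n_cap = 6) {
  stopifnot(inherits(phantom, "phantom_pelvis"))
  meshes <- lapply(phantom$corridors, function(co) {
    capsule_mesh(co$axis_entry, co$axis_end, co$radius, n_theta, n_cap)
  })
  merge_meshes(meshes)
}

# Closed capsule mesh from a to b with given radius.
capsule_mesh <- function(a, b, radius, n_theta = 24, n_cap = 6) {
  axis <- vnormalize(b - a)
  basis <- perpendicular_basis(axis)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ring <- function(center, r, drop_along = 0) {
    t(vapply(theta, function(th) {
      center + r * (cos(th) * basis[[1]] + sin(th) * basis[[2]]) +
        drop_along * axis
    }, numeric(3)))
  }
  verts <- list(); faces <- list(); nv <- 0
  add_ring <- function(v) {
    verts[[length(verts) + 1]] <<- v
    nv <<- nv + nrow(v)
    (nv - nrow(v) + 1):nv
  }
  # cap at a (pointing -axis), cylinder, cap at b
  pole_a_idx <- {
    verts[[length(verts) + 1]] <- matrix(a - radius * axis, 1, 3)
    nv <- nv + 1; nv
  }
  rings_a <- lapply(seq(n_cap - 1, 0), function(k) {
    phi <- (pi / 2) * k / n_cap  # near pole (large phi) down to equator (0)
    ring(a, radius * cos(phi), drop_along = -radius * sin(phi))
  })
  idx_prev <- NULL
  for (v in rings_a) {
    idx <- add_ring(v)
    if (is.null(idx_prev)) {
      # fan from pole
      for (i in seq_len(n_theta)) {
        j <- if (i == n_theta) 1 else i + 1
        faces[[length(faces) + 1]] <- c(pole_a_idx, idx[j], idx[i])
      }
    } else {
      faces <- c(faces, band_faces(idx_prev, idx, flip = TRUE))
    }
    idx_prev <- idx
  }
  idx_b_start <- add_ring(ring(b, radius))
  faces <- c(faces, band_faces(idx_prev, idx_b_start, flip = TRUE))
  idx_prev <- idx_b_start
  rings_b <- lapply(seq_len(n_cap - 1), function(k) {
    phi <- (pi / 2) * k / n_cap
    ring(b, radius * cos(phi), drop_along = radius * sin(phi))
  })
  for (v in rings_b) {
    idx <- add_ring(v)
    faces <- c(faces, band_faces(idx_prev, idx, flip = TRUE))
    idx_prev <- idx
  }
  pole_b_idx <- {
    verts[[length(verts) + 1]] <- matrix(b + radius * axis, 1, 3)
    nv <- nv + 1; nv
  }
  for (i in seq_len(n_theta)) {
    j <- if (i == n_theta) 1 else i + 1
    faces[[length(faces) + 1]] <- c(pole_b_idx, idx_prev[i], idx_prev[j])
  }
  structure(
    list(vertices = do.call(rbind, verts),
         faces = do.call(rbind, faces)),
    class = "pelvnav_mesh"
  )
}

band_faces <- function(idx1, idx2, flip = FALSE) {
  n <- length(idx1)
  out <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (flip) {
      out[[2 * i - 1]] <- c(idx1[i], idx2[j], idx2[i])
      out[[2 * i]] <- c(idx1[i], idx1[j], idx2[j])
    } else {
      out[[2 * i - 1]] <- c(idx1[i], idx2[i], idx2[j])
      out[[2 * i]] <- c(idx1[i], idx2[j], idx1[j])
    }
  }
  out
}

merge_meshes <- function(meshes) {
  offset <- 0; V <- list(); FA <- list()
  for (m in meshes) {
    V[[length(V) + 1]] <- m$vertices
    FA[[length(FA) + 1]] <- m$faces + offset
    offset <- offset + nrow(m$vertices)
  }
  structure(list(vertices = do.call(rbind, V), faces = do.call(rbind, FA)),
            class = "pelvnav_mesh")
}
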
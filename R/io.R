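# File formats: STL (ASCII + binary) and OBJ triangle meshes, JSON plan /
# landmark / transform documents, JSONL pose and event streams, YAML trial
# configuration, CSV placement reports. Coordinates are serialised as
# arrays of 3 floats in millimetres in the document's declared space; no
# implicit unit conversion anywhere.

new_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("mesh face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "pelvnav_mesh")
}

#' @export
print.pelvnav_mesh <- function(x, ...) {
  cat(sprintf("<pelvnav_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangle mesh (STL or OBJ, chosen by extension)
#'
#' @param path File path ending in `.stl` or `.obj`. STL may be ASCII or
#'   binary (detected from content). Vertices are in mm.
#' @return A `pelvnav_mesh` (vertices n x 3, faces m x 3 1-based).
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         obj = read_obj(path),
         stop(sprintf("unknown mesh extension '.%s' (use .stl or .obj)", ext),
              call. = FALSE))
}

#' Write a triangle mesh (STL or OBJ, chosen by extension)
#'
#' @param mesh A `pelvnav_mesh`.
#' @param path Output path ending in `.stl` or `.obj`.
#' @param ascii For STL: write the ASCII dialect (default `FALSE`, binary).
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, ascii = ascii),
         obj = write_obj(mesh, path),
         stop(sprintf("unknown mesh extension '.%s' (use .stl or .obj)", ext),
              call. = FALSE))
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  size <- file.info(path)$size
  if (is.na(size) || size == 0) {
    stop(sprintf("STL parse error in %s: empty file", path), call. = FALSE)
  }
  head_bytes <- readBin(path, "raw", n = min(size, 512))
  head_txt <- rawToChar(head_bytes[head_bytes != as.raw(0)])
  # byte-wise matching: a binary STL header is arbitrary bytes
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, fixed = TRUE, useBytes = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vert_lines <- grep("^\\s*vertex\\s", lines)
  if (length(vert_lines) == 0 || length(vert_lines) %% 3 != 0) {
    stop(sprintf("STL parse error in %s: expected vertex triplets, got %d vertex lines",
                 path, length(vert_lines)), call. = FALSE)
  }
  coords <- t(vapply(lines[vert_lines], function(l) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(v))) {
      stop(sprintf("STL parse error in %s at line: %s", path, l), call. = FALSE)
    }
    v
  }, numeric(3), USE.NAMES = FALSE))
  soup_to_mesh(coords)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  n_tri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (!length(n_tri) || is.na(n_tri) || n_tri < 0) {
    stop(sprintf("STL parse error in %s: bad triangle count", path), call. = FALSE)
  }
  expected <- 84 + n_tri * 50
  if (file.info(path)$size < expected) {
    stop(sprintf("STL parse error in %s: truncated (need %d bytes)", path, expected),
         call. = FALSE)
  }
  coords <- matrix(0, 3 * n_tri, 3)
  for (i in seq_len(n_tri)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", n = 2))
    coords[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  soup_to_mesh(coords)
}

# Deduplicate a triangle soup (3 rows per facet) into vertices + faces.
soup_to_mesh <- function(coords) {
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  new_mesh(coords[uniq, , drop = FALSE], matrix(idx, ncol = 3, byrow = TRUE))
}

#' @rdname write_mesh
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "pelvnav_mesh"))
  V <- mesh$vertices; FA <- mesh$faces
  normals <- t(vapply(seq_len(nrow(FA)), function(i) {
    tri <- V[FA[i, ], ]
    n <- vcross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    ln <- vnorm(n)
    if (ln < 1e-12) c(0, 0, 0) else n / ln
  }, numeric(3)))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid pelvnav", con)
    for (i in seq_len(nrow(FA))) {
      tri <- V[FA[i, ], ]
      writeLines(sprintf("  facet normal %g %g %g",
                         normals[i, 1], normals[i, 2], normals[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           tri[j, 1], tri[j, 2], tri[j, 3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid pelvnav", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "pelvnav binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(FA)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(FA))) {
      tri <- V[FA[i, ], ]
      writeBin(c(normals[i, ], t(tri)), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    stop(sprintf("OBJ parse error in %s: empty file", path), call. = FALSE)
  }
  verts <- list(); faces <- list()
  for (ln in seq_along(lines)) {
    l <- trimws(lines[ln])
    if (l == "" || startsWith(l, "#")) next
    parts <- strsplit(l, "\\s+")[[1]]
    if (parts[1] == "v") {
      v <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(v))) {
        stop(sprintf("OBJ parse error in %s at line %d: %s", path, ln, l),
             call. = FALSE)
      }
      verts[[length(verts) + 1]] <- v
    } else if (parts[1] == "f") {
      # keep only the vertex index of each v/vt/vn token; negative indices
      # are relative to the number of vertices seen so far
      raw_idx <- vapply(parts[-1], function(tok) {
        suppressWarnings(as.integer(strsplit(tok, "/", fixed = TRUE)[[1]][1]))
      }, integer(1), USE.NAMES = FALSE)
      if (any(is.na(raw_idx)) || length(raw_idx) < 3) {
        stop(sprintf("OBJ parse error in %s at line %d: %s", path, ln, l),
             call. = FALSE)
      }
      nv <- length(verts)
      idx <- ifelse(raw_idx < 0, nv + raw_idx + 1L, raw_idx)
      if (any(idx < 1 | idx > nv)) {
        stop(sprintf("OBJ parse error in %s at line %d: index out of range", path, ln),
             call. = FALSE)
      }
      # fan-triangulate polygons
      for (k in seq_len(length(idx) - 2)) {
        faces[[length(faces) + 1]] <- c(idx[1], idx[k + 1], idx[k + 2])
      }
    }
  }
  if (!length(verts) || !length(faces)) {
    stop(sprintf("OBJ parse error in %s: no geometry found", path), call. = FALSE)
  }
  new_mesh(do.call(rbind, verts), do.call(rbind, faces))
}

#' @rdname write_mesh
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "pelvnav_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pelvnav OBJ (geometry only, mm)", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

# ---- JSON documents ------------------------------------------------------

check_fields <- function(doc, required, allowed, what, path) {
  missing <- setdiff(required, names(doc))
  unknown <- setdiff(names(doc), allowed)
  if (length(missing)) {
    stop(sprintf("%s %s: missing field(s) %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(unknown)) {
    stop(sprintf("%s %s: unknown field(s) %s", what, path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

#' Write / read a landmark set as JSON
#'
#' Schema: `{"space": "model"|"world", "left_asis": [3], "right_asis": [3],
#' "symphysis": [3]}`, coordinates in mm. Unknown fields are rejected.
#'
#' @param landmarks A [landmark_set()].
#' @param path File path.
#' @param space Declared coordinate space.
#' @export
write_landmarks_json <- function(landmarks, path, space = "model") {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(
    list(space = space, left_asis = landmarks$left_asis,
         right_asis = landmarks$right_asis, symphysis = landmarks$symphysis),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_fields(doc, c("left_asis", "right_asis", "symphysis"),
               c("space", "left_asis", "right_asis", "symphysis"),
               "landmark JSON", path)
  landmark_set(doc$left_asis, doc$right_asis, doc$symphysis)
}

#' Write / read a similarity transform as JSON
#'
#' Schema: `{"rotation": [9 row-major floats], "translation": [3],
#' "scale": float, "fre_rms": float|null}`.
#'
#' @param transform A [similarity_transform()] or [fit_similarity()] result.
#' @param path File path.
#' @export
write_transform_json <- function(transform, path) {
  fre <- NULL
  if (inherits(transform, "registration_fit")) {
    fre <- transform$fre_rms
    transform <- transform$transform
  }
  stopifnot(inherits(transform, "similarity_transform"))
  jsonlite::write_json(
    list(rotation = as.numeric(t(transform$rotation)),
         translation = transform$translation,
         scale = transform$scale,
         fre_rms = fre),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_fields(doc, c("rotation", "translation", "scale"),
               c("rotation", "translation", "scale", "fre_rms"),
               "transform JSON", path)
  similarity_transform(matrix(doc$rotation, 3, 3, byrow = TRUE),
                       doc$translation, doc$scale)
}

#' Write / read a screw plan document as JSON
#'
#' Schema: `{"version": 1, "space": "model"|"world", "landmarks": {...},
#' "screws": [{"label", "entry" [3], "central_aim" [3], "diameter",
#' "depth"}]}`. Labels must be unique; unknown fields are rejected.
#'
#' @param trajectories Named list of [trajectory()] objects (names are the
#'   screw labels).
#' @param landmarks The [landmark_set()] of the same document space.
#' @param path File path.
#' @param space Declared coordinate space.
#' @export
write_plan <- function(trajectories, landmarks, path, space = "model") {
  stopifnot(inherits(landmarks, "landmark_set"))
  screws <- lapply(names(trajectories), function(label) {
    tr <- trajectories[[label]]
    list(label = label, entry = tr$entry, central_aim = tr$central_aim,
         diameter = tr$diameter, depth = tr$depth)
  })
  jsonlite::write_json(
    list(version = 1L, space = space,
         landmarks = list(left_asis = landmarks$left_asis,
                          right_asis = landmarks$right_asis,
                          symphysis = landmarks$symphysis),
         screws = screws),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_fields(doc, c("version", "space", "landmarks", "screws"),
               c("version", "space", "landmarks", "screws"), "plan JSON", path)
  lm <- doc$landmarks
  check_fields(lm, c("left_asis", "right_asis", "symphysis"),
               c("left_asis", "right_asis", "symphysis"), "plan JSON landmarks",
               path)
  labels <- vapply(doc$screws, function(s) s$label %||% NA_character_,
                   character(1))
  if (anyNA(labels) || anyDuplicated(labels)) {
    stop(sprintf("plan JSON %s: screw labels must be present and unique", path),
         call. = FALSE)
  }
  trajectories <- lapply(doc$screws, function(s) {
    check_fields(s, c("label", "entry", "central_aim", "diameter", "depth"),
                 c("label", "entry", "central_aim", "diameter", "depth"),
                 "plan JSON screw", path)
    trajectory(unlist(s$entry), unlist(s$central_aim), s$diameter, s$depth)
  })
  names(trajectories) <- labels
  list(
    space = doc$space,
    landmarks = landmark_set(unlist(lm$left_asis), unlist(lm$right_asis),
                             unlist(lm$symphysis)),
    trajectories = trajectories
  )
}

#' Write / read a phantom (landmarks + corridors + plan) as JSON
#'
#' Self-contained document for the `evaluate` pipeline stage: everything
#' needed to score drilled trajectories against a phantom.
#'
#' @param phantom A [make_phantom()] result.
#' @param path File path.
#' @export
write_phantom_json <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_pelvis"))
  corridors <- lapply(phantom$corridors, function(co) {
    list(label = co$label, axis_entry = co$axis_entry, axis_end = co$axis_end,
         radius = co$radius)
  })
  screws <- lapply(phantom$planned, function(tr) {
    list(entry = tr$entry, central_aim = tr$central_aim,
         diameter = tr$diameter, depth = tr$depth)
  })
  jsonlite::write_json(
    list(version = 1L, space = "model",
         landmarks = list(left_asis = phantom$landmarks$left_asis,
                          right_asis = phantom$landmarks$right_asis,
                          symphysis = phantom$landmarks$symphysis),
         corridors = corridors, screws = screws),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_fields(doc, c("version", "space", "landmarks", "corridors", "screws"),
               c("version", "space", "landmarks", "corridors", "screws"),
               "phantom JSON", path)
  lm <- doc$landmarks
  landmarks <- landmark_set(unlist(lm$left_asis), unlist(lm$right_asis),
                            unlist(lm$symphysis))
  corridors <- lapply(doc$corridors, function(co) {
    new_corridor(co$label, unlist(co$axis_entry), unlist(co$axis_end),
                 co$radius)
  })
  names(corridors) <- vapply(corridors, function(co) co$label, character(1))
  planned <- lapply(doc$screws, function(s) {
    trajectory(unlist(s$entry), unlist(s$central_aim), s$diameter, s$depth)
  })
  names(planned) <- names(doc$screws)
  if (is.null(names(planned)) || any(names(planned) == "")) {
    names(planned) <- names(corridors)
  }
  list(landmarks = landmarks, corridors = corridors, planned = planned,
       frame = build_frame(landmarks))
}

# ---- JSONL streams -------------------------------------------------------

#' Write / read a drill pose stream as JSONL
#'
#' One pose per line: `{"t": float, "tip": [3], "dir": [3]}`.
#'
#' @param poses Tibble with columns `t`, `tip_x`..`tip_z`, `dir_x`..`dir_z`.
#' @param path File path.
#' @export
write_pose_log <- function(poses, path) {
  lines <- vapply(seq_len(nrow(poses)), function(i) {
    jsonlite::toJSON(list(
      t = poses$t[i],
      tip = c(poses$tip_x[i], poses$tip_y[i], poses$tip_z[i]),
      dir = c(poses$dir_x[i], poses$dir_y[i], poses$dir_z[i])
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pose_log
#' @export
read_pose_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("pose log %s is empty", path), call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    doc <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) {
                      stop(sprintf("pose log parse error at %s line %d: %s",
                                   path, i, conditionMessage(e)), call. = FALSE)
                    })
    check_fields(doc, c("t", "tip", "dir"), c("t", "tip", "dir"),
                 "pose log", sprintf("%s:%d", path, i))
    tibble::tibble(t = doc$t,
                   tip_x = doc$tip[1], tip_y = doc$tip[2], tip_z = doc$tip[3],
                   dir_x = doc$dir[1], dir_y = doc$dir[2], dir_z = doc$dir[3])
  })
  dplyr::bind_rows(rows)
}

#' Write a guidance event log as JSONL
#'
#' One event per line: `{"t": float, "event": str, "screw": str}`.
#'
#' @param events Tibble with columns `t`, `event`, `screw`.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(list(t = events$t[i], event = events$event[i],
                          screw = events$screw[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- YAML config and CSV reports ----------------------------------------

#' Read a trial configuration from YAML
#'
#' Recognised top-level keys: `n_pelves`, `seed`, `noise` (keys of
#' [noise_model()]), `phantom` (keys of [phantom_params()]), `tolerances`
#' (keys of [guidance_tolerances()]). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [trial_config()].
#' @export
read_trial_config_yaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- yaml::read_yaml(path)
  check_fields(doc, character(0),
               c("n_pelves", "seed", "noise", "phantom", "tolerances"),
               "trial config YAML", path)
  noise <- do.call(noise_model, doc$noise %||% list())
  params <- do.call(phantom_params, doc$phantom %||% list())
  tol <- do.call(guidance_tolerances, doc$tolerances %||% list())
  trial_config(n_pelves = doc$n_pelves %||% 10, noise = noise, params = params,
               tolerances = tol, seed = doc$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a placement report CSV
#'
#' Stable column order `screw_label, mld_mm, mld_location, entry_dev_mm,
#' central_aim_dev_mm, angular_dev_deg, perforated, directions, correct`
#' (plus any extra columns such as `pelvis` appended after). A metadata
#' header of `#`-prefixed comment lines records the seed and provenance.
#'
#' @param screws Per-screw tibble (see [evaluate_placement()], [run_trial()]).
#' @param path Output CSV path.
#' @param seed Seed to record in the metadata header (may be `NA`).
#' @export
write_placement_csv <- function(screws, path, seed = NA) {
  front <- intersect(PLACEMENT_COLUMNS, names(screws))
  rest <- setdiff(names(screws), front)
  out <- screws[, c(front, rest), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pelvnav placement report"), con)
  writeLines(sprintf("# seed: %s", as.character(seed)), con)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_placement_csv
#' @export
read_placement_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tibble::as_tibble(read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE))
}
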
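# Monte-Carlo replication engine for the in-silico screw-placement trial
# and for the symphysis-tilt error-propagation experiment.

#' Configuration of an in-silico screw-placement trial
#'
#' Each pelvis is matched once (one landmark probing, one registration
#' shared by all four screws — no changes to the matching after the first
#' screw), then the four screws are drilled in the fixed order S1 right,
#' S1 left, S2 right, S2 left and evaluated geometrically.
#'
#' @param n_pelves Number of pelves (default 10, four screws each).
#' @param noise A [noise_model()].
#' @param params A [phantom_params()].
#' @param tolerances A [guidance_tolerances()] (carried for provenance; the
#'   trial drills against the displayed plan directly).
#' @param seed Integer seed; the whole trial is deterministic given it.
#' @export
trial_config <- function(n_pelves = 10, noise = noise_model(),
                         params = phantom_params(),
                         tolerances = guidance_tolerances(), seed = 1) {
  if (!is.numeric(n_pelves) || n_pelves < 1) {
    stop("n_pelves must be >= 1", call. = FALSE)
  }
  stopifnot(inherits(noise, "noise_model"), inherits(params, "phantom_params"))
  structure(list(n_pelves = as.integer(n_pelves), noise = noise,
                 params = params, tolerances = tolerances,
                 seed = as.integer(seed)),
            class = "trial_config")
}

#' Run the in-silico screw-placement trial
#'
#' For each pelvis: place the phantom at a random rigid pose on the table,
#' probe the three landmarks once under the noise model, fit the similarity
#' registration, derive the world-space guidance error (estimated map
#' composed with the inverse true map), then simulate and evaluate the four
#' drillings in the fixed order. The registration error is shared by all
#' four screws of a pelvis, so direction-concordant perforations within a
#' pelvis indicate matching error.
#'
#' @param config A [trial_config()].
#' @return Object of class `si_trial`: list with `screws` (tibble, one row
#'   per screw: pelvis, screw metrics, perforation columns, plus the
#'   pelvis-level registration FRE and guidance-error magnitude) and
#'   `config`.
#' @export
run_trial <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  with_seed(config$seed, run_trial_impl(config))
}

run_trial_impl <- function(config) {
  rows <- vector("list", config$n_pelves)
  for (i in seq_len(config$n_pelves)) {
    phantom <- make_phantom(config$params,
                            seed = if (config$params$anatomy_jitter_sigma > 0)
                              sample.int(2^31 - 1, 1) else NULL)
    # true pose of the pelvis on the table: random rigid motion
    T_true <- similarity_transform(
      rotation = random_rotation(),
      translation = runif(3, -200, 200),
      scale = 1
    )
    probed <- probe_landmarks(phantom, T_true, config$noise)
    reg <- fit_similarity(phantom$landmarks, probed, allow_scale = TRUE)
    guidance_error <- compose_transform(reg$transform, invert_transform(T_true))
    world_landmarks <- transform_landmarks(T_true, phantom$landmarks)
    world_frame <- build_frame(world_landmarks)
    screw_rows <- lapply(CORRIDOR_LABELS, function(label) {
      planned_world <- transform_trajectory(T_true, phantom$planned[[label]])
      corridor_world <- transform_corridor(T_true, phantom$corridors[[label]])
      drilled <- simulate_drilling(planned_world, guidance_error, config$noise)
      evaluate_placement(planned_world, drilled, corridor_world, world_frame,
                         screw_label = label)
    })
    pelvis_tbl <- dplyr::bind_rows(screw_rows)
    pelvis_tbl$pelvis <- i
    pelvis_tbl$fre_rms_mm <- reg$fre_rms
    pelvis_tbl$reg_rotation_deg <- rotation_angle_deg(guidance_error$rotation)
    rows[[i]] <- pelvis_tbl
  }
  screws <- dplyr::relocate(dplyr::bind_rows(rows), "pelvis")
  structure(list(screws = screws, config = config), class = "si_trial")
}

#' @export
print.si_trial <- function(x, ...) {
  cat(sprintf("<si_trial> %d pelves, %d screws\n",
              x$config$n_pelves, nrow(x$screws)))
  print(glance(x))
  invisible(x)
}

#' @rdname run_trial
#' @param x An `si_trial`.
#' @param ... Unused.
#' @export
tidy.si_trial <- function(x, ...) x$screws

#' @rdname run_trial
#' @export
glance.si_trial <- function(x, ...) {
  s <- x$screws
  tibble::tibble(
    n_pelves = x$config$n_pelves,
    n_screws = nrow(s),
    s1_correct_rate = mean(s$correct[s$screw_type == "S1"]),
    s2_correct_rate = mean(s$correct[s$screw_type == "S2"]),
    median_mld_mm = median(s$mld_mm),
    median_angular_dev_deg = median(s$angular_dev_deg)
  )
}

iqr_string <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  sprintf("%.1f-%.1f", q[1], q[2])
}

#' Summarise a per-screw trial table
#'
#' Produces, per screw type, the correct-placement rate and median + IQR of
#' each deviation metric; a perforation-direction histogram; a per-pelvis
#' shared-direction flag (all perforated screws of the pelvis share a
#' common direction component — the signature of matching error, since the
#' registration is shared within a pelvis); and descriptive two-group
#' comparisons between S1 and S2 (rank-based Mann-Whitney for MLD and the
#' point deviations, t-test for the angular deviation). The tests are
#' descriptive outputs only; nothing downstream is gated on them.
#'
#' @param screws A per-screw tibble as produced by [run_trial()] (or an
#'   `si_trial` object).
#' @return Object of class `si_trial_summary`: list of tibbles `by_type`,
#'   `direction_histogram`, `per_pelvis`, `comparisons`.
#' @export
summarize_trial <- function(screws) {
  if (inherits(screws, "si_trial")) screws <- screws$screws
  if (!is.data.frame(screws) || nrow(screws) == 0) {
    stop("empty per-screw table", call. = FALSE)
  }
  by_type <- screws |>
    dplyr::group_by(.data$screw_type) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_correct = sum(.data$correct),
      correct_rate = mean(.data$correct),
      mld_median_mm = median(.data$mld_mm),
      mld_iqr = iqr_string(.data$mld_mm),
      entry_median_mm = median(.data$entry_dev_mm),
      entry_iqr = iqr_string(.data$entry_dev_mm),
      central_aim_median_mm = median(.data$central_aim_dev_mm),
      central_aim_iqr = iqr_string(.data$central_aim_dev_mm),
      angular_median_deg = median(.data$angular_dev_deg),
      angular_iqr = iqr_string(.data$angular_dev_deg),
      mld_at_tip_rate = mean(.data$mld_location == "tip"),
      .groups = "drop"
    )
  perforated <- screws[screws$perforated, , drop = FALSE]
  direction_histogram <- if (nrow(perforated)) {
    perforated |>
      dplyr::count(.data$screw_type, .data$directions, name = "n_screws") |>
      dplyr::arrange(.data$screw_type, dplyr::desc(.data$n_screws))
  } else {
    tibble::tibble(screw_type = character(0), directions = character(0),
                   n_screws = integer(0))
  }
  per_pelvis <- if ("pelvis" %in% names(screws)) {
    screws |>
      dplyr::group_by(.data$pelvis) |>
      dplyr::summarise(
        n_perforated = sum(.data$perforated),
        shared_direction = shared_direction_flag(
          .data$directions[.data$perforated]),
        .groups = "drop"
      )
  } else {
    tibble::tibble(pelvis = integer(0), n_perforated = integer(0),
                   shared_direction = logical(0))
  }
  comparisons <- trial_comparisons(screws)
  structure(
    list(by_type = by_type, direction_histogram = direction_histogram,
         per_pelvis = per_pelvis, comparisons = comparisons),
    class = "si_trial_summary"
  )
}

# TRUE when >= 2 screws perforated and all share at least one common
# direction label (e.g. all have an anterior component).
shared_direction_flag <- function(direction_strings) {
  if (length(direction_strings) < 2) return(NA)
  sets <- strsplit(direction_strings, ",", fixed = TRUE)
  common <- Reduce(intersect, sets)
  length(common) > 0
}

trial_comparisons <- function(screws) {
  s1 <- screws[screws$screw_type == "S1", , drop = FALSE]
  s2 <- screws[screws$screw_type == "S2", , drop = FALSE]
  if (nrow(s1) < 2 || nrow(s2) < 2) {
    return(tibble::tibble(metric = character(0), test = character(0),
                          statistic = numeric(0), p_value = numeric(0)))
  }
  safe_test <- function(metric, test) {
    x <- s1[[metric]]; y <- s2[[metric]]
    res <- tryCatch({
      if (test == "mann_whitney") {
        w <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
        c(unname(w$statistic), w$p.value)
      } else {
        tt <- t.test(x, y)
        c(unname(tt$statistic), tt$p.value)
      }
    }, error = function(e) c(NA_real_, NA_real_))
    tibble::tibble(metric = metric, test = test,
                   statistic = res[1], p_value = res[2])
  }
  dplyr::bind_rows(
    safe_test("mld_mm", "mann_whitney"),
    safe_test("entry_dev_mm", "mann_whitney"),
    safe_test("central_aim_dev_mm", "mann_whitney"),
    safe_test("angular_dev_deg", "t_test")
  )
}

#' @export
print.si_trial_summary <- function(x, ...) {
  cat("<si_trial_summary>\n")
  print(x$by_type)
  if (nrow(x$direction_histogram)) {
    cat("perforation directions:\n")
    print(x$direction_histogram)
  }
  invisible(x)
}

#' Symphysis-tilt error-propagation experiment
#'
#' Sweeps a systematic anterior bias of the probed symphysis (all other
#' landmark noise as configured, typically zero or small) and reports, per
#' bias level: the fitted registration error's rotation angle and the angle
#' of its rotation axis to the world inter-ASIS axis (computed from a
#' deterministic, bias-only probing), plus Monte-Carlo estimates of the
#' correct-placement rate and the fraction of perforations carrying an
#' anterior component for each screw type.
#'
#' Because the symphysis sits much closer to the inter-ASIS axis than the
#' ASIS span, an anterior symphysis error tilts the registration plane
#' about that axis; the narrow S2 corridor then perforates — with an
#' anterior component — at a smaller bias than the wide S1 corridor.
#'
#' @param bias_grid Numeric vector of anterior symphysis biases (mm, >= 0).
#' @param config A [trial_config()]; its noise model's
#'   `symphysis_anterior_bias` is overridden by each grid value.
#' @return Object of class `si_tilt`: list with `sweep` (one tibble row per
#'   bias level) and `config`.
#' @export
symphysis_tilt_experiment <- function(bias_grid, config = trial_config()) {
  stopifnot(is.numeric(bias_grid), all(bias_grid >= 0))
  rows <- lapply(seq_along(bias_grid), function(k) {
    bias <- bias_grid[k]
    noise_k <- config$noise
    noise_k$symphysis_anterior_bias <- bias
    cfg <- trial_config(
      n_pelves = config$n_pelves, noise = noise_k, params = config$params,
      tolerances = config$tolerances, seed = config$seed + k
    )
    trial <- run_trial(cfg)
    s <- trial$screws
    # deterministic, bias-only registration to characterise the induced error
    det_err <- deterministic_tilt_error(config$params, bias)
    anterior_frac <- function(type) {
      perf <- s[s$screw_type == type & s$perforated, , drop = FALSE]
      if (!nrow(perf)) return(NA_real_)
      mean(vapply(strsplit(perf$directions, ",", fixed = TRUE),
                  function(d) "anterior" %in% d, logical(1)))
    }
    tibble::tibble(
      bias_mm = bias,
      rotation_deg = det_err$rotation_deg,
      axis_angle_to_interasis_deg = det_err$axis_angle_deg,
      s1_correct_rate = mean(s$correct[s$screw_type == "S1"]),
      s2_correct_rate = mean(s$correct[s$screw_type == "S2"]),
      s1_n_perforated = sum(s$perforated & s$screw_type == "S1"),
      s2_n_perforated = sum(s$perforated & s$screw_type == "S2"),
      s1_anterior_fraction = anterior_frac("S1"),
      s2_anterior_fraction = anterior_frac("S2")
    )
  })
  structure(list(sweep = dplyr::bind_rows(rows), config = config),
            class = "si_tilt")
}

# Fit the registration with ONLY the anterior symphysis bias (no random
# noise, identity true pose) and characterise the induced rotation.
deterministic_tilt_error <- function(params, bias) {
  phantom <- make_phantom(params)
  probed <- probe_landmarks(phantom, similarity_transform(),
                            noise_model(0, bias, 0, 0))
  reg <- fit_similarity(phantom$landmarks, probed)
  R <- reg$transform$rotation
  ang <- rotation_angle_deg(R)
  axis_angle <- if (ang < 1e-9) NA_real_ else {
    ax <- rotation_axis(R)
    lat <- build_frame(phantom$landmarks)$lateral_right
    cosang <- abs(sum(ax * lat))  # axis sign is arbitrary
    acos(min(max(cosang, -1), 1)) * RAD2DEG
  }
  list(rotation_deg = ang, axis_angle_deg = axis_angle)
}

#' @rdname symphysis_tilt_experiment
#' @param x An `si_tilt`.
#' @param ... Unused.
#' @export
tidy.si_tilt <- function(x, ...) x$sweep

#' @export
print.si_tilt <- function(x, ...) {
  cat("<si_tilt> symphysis anterior-bias sweep\n")
  print(x$sweep)
  invisible(x)
}
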
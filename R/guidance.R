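# Intraoperative guidance as a deterministic, replayable state machine:
# consume tracked drill poses, emit the alignment/feedback events the
# headset displayed (entry point turning green, then the drilling axis once
# the central aim is reached, then depth).

GUIDANCE_PHASES <- c("searching", "entry_captured", "aligned", "depth_reached",
                     "advanced", "complete")

#' Guidance tolerances
#'
#' The alignment criterion is an entry sphere plus an aim-point corridor:
#' the entry is "captured" when the drill tip is within `entry_mm` of the
#' planned entry, and the axis is "aligned" when, additionally, the drill
#' ray passes within `aim_mm` of the planned central aim point. Defaults of
#' 2 mm each are well below the corridor radii, so satisfied guidance
#' implies geometric safety in the default phantom. `stale_after_s` is the
#' tracking-loss timeout: a gap in the pose stream longer than this emits a
#' `tracking_stale` event (flags hold their last values until the next
#' pose).
#'
#' @param entry_mm Entry-capture tolerance (mm).
#' @param aim_mm Aim-corridor tolerance (mm).
#' @param stale_after_s Tracking staleness timeout (seconds).
#' @export
guidance_tolerances <- function(entry_mm = 2.0, aim_mm = 2.0,
                                stale_after_s = 1.0) {
  stopifnot(entry_mm > 0, aim_mm > 0, stale_after_s > 0)
  structure(list(entry_mm = entry_mm, aim_mm = aim_mm,
                 stale_after_s = stale_after_s),
            class = "guidance_tolerances")
}

#' A drill pose sample
#'
#' @param t Timestamp in seconds.
#' @param tip Drill tip position (mm).
#' @param direction Unit drilling direction (the "laser" ray overlaying the
#'   drill head).
#' @export
drill_pose <- function(t, tip, direction) {
  direction <- as_point3(direction, "direction")
  if (abs(vnorm(direction) - 1) > 1e-6) {
    stop("drill pose direction must be a unit vector", call. = FALSE)
  }
  structure(list(t = as.numeric(t), tip = as_point3(tip, "tip"),
                 direction = direction),
            class = "drill_pose")
}

#' Initial guidance state for a screw plan
#'
#' @param plan_order Character vector of screw labels in drilling order.
#'   The default is the fixed clinical order S1 right, S1 left, S2 right,
#'   S2 left.
#' @export
guidance_init <- function(plan_order = CORRIDOR_LABELS) {
  structure(
    list(active_index = 1L, active_screw = plan_order[1], plan_order = plan_order,
         entry_ok = FALSE, axis_ok = FALSE, depth_progress = 0,
         phase = "searching", last_t = NA_real_),
    class = "guidance_state"
  )
}

# Distance from the drill ray (tip, direction) to a point; the ray only
# extends forward, a target behind the tip is measured to the tip itself.
ray_point_distance <- function(tip, direction, target) {
  w <- target - tip
  proj <- sum(w * direction)
  if (proj <= 0) return(vnorm(w))
  vnorm(w - proj * direction)
}

#' Advance the guidance state machine by one drill pose
#'
#' Flags are pure functions of the current pose: `entry_ok` iff the tip is
#' within tolerance of the planned entry; `axis_ok` iff `entry_ok` and the
#' drill ray passes within tolerance of the planned central aim;
#' `depth_progress` is the projection of (tip - entry) on the planned
#' direction, clamped at 0. The phase records the furthest milestone
#' reached for the active screw; events are emitted on every flag/phase
#' transition and on tracking staleness gaps.
#'
#' @param state A `guidance_state` (see [guidance_init()]).
#' @param pose A [drill_pose()].
#' @param plan The active planned [trajectory()].
#' @param tolerances A [guidance_tolerances()].
#' @return List with `state` (updated) and `events` (tibble with columns
#'   `t`, `event`, `screw`; possibly zero rows).
#' @export
guidance_update <- function(state, pose, plan, tolerances = guidance_tolerances()) {
  stopifnot(inherits(state, "guidance_state"), inherits(plan, "trajectory"))
  if (!inherits(pose, "drill_pose")) {
    stop("pose must be a drill_pose with a unit direction", call. = FALSE)
  }
  if (state$phase %in% c("complete")) {
    return(list(state = state, events = empty_events()))
  }
  events <- list()
  emit <- function(t, ev) {
    events[[length(events) + 1]] <<- tibble::tibble(
      t = t, event = ev, screw = state$active_screw)
  }
  if (!is.na(state$last_t)) {
    if (pose$t < state$last_t) {
      stop("pose timestamps must be non-decreasing", call. = FALSE)
    }
    if (pose$t - state$last_t > tolerances$stale_after_s) {
      emit(pose$t, "tracking_stale")
    }
  }
  dir_p <- trajectory_direction(plan)
  phase_rank <- function(p) match(p, GUIDANCE_PHASES)
  # once aligned and advancing, the entry stays captured while the tip
  # remains within tolerance of the planned axis segment (the drill tip
  # necessarily leaves the entry sphere as it advances)
  drilling <- phase_rank(state$phase) >= phase_rank("aligned")
  entry_ok <- vnorm(pose$tip - plan$entry) <= tolerances$entry_mm ||
    (drilling &&
       point_segment_distance(pose$tip, plan$entry, trajectory_tip(plan)) <=
         tolerances$entry_mm)
  axis_ok <- entry_ok &&
    ray_point_distance(pose$tip, pose$direction, plan$central_aim) <=
      tolerances$aim_mm
  depth_progress <- max(0, sum((pose$tip - plan$entry) * dir_p))
  if (entry_ok && !state$entry_ok) emit(pose$t, "entry_captured")
  if (!entry_ok && state$entry_ok) emit(pose$t, "entry_lost")
  if (axis_ok && !state$axis_ok) emit(pose$t, "aligned")
  if (!axis_ok && state$axis_ok) emit(pose$t, "alignment_lost")
  phase <- state$phase
  # depth only counts once the axis has been aligned for this screw:
  # the phases follow the order searching -> entry_captured -> aligned ->
  # depth_reached, never skipping the alignment milestone
  was_aligned <- axis_ok || phase_rank(phase) >= phase_rank("aligned")
  candidate <- if (depth_progress >= plan$depth && was_aligned) {
    "depth_reached"
  } else if (axis_ok) {
    "aligned"
  } else if (entry_ok) {
    "entry_captured"
  } else {
    "searching"
  }
  # phase is monotone: it records the furthest milestone for this screw
  if (phase_rank(candidate) > phase_rank(phase)) {
    phase <- candidate
    if (phase == "depth_reached") emit(pose$t, "depth_reached")
  }
  state$entry_ok <- entry_ok
  state$axis_ok <- axis_ok
  state$depth_progress <- depth_progress
  state$phase <- phase
  state$last_t <- pose$t
  list(state = state,
       events = if (length(events)) dplyr::bind_rows(events) else empty_events())
}

empty_events <- function() {
  tibble::tibble(t = numeric(0), event = character(0), screw = character(0))
}

#' Advance to the next screw in the drilling order
#'
#' Only legal once the active screw has reached depth; after the last screw
#' the state becomes terminal (`complete`), which is a valid end state, not
#' an error.
#'
#' @param state A `guidance_state` in phase `depth_reached`.
#' @return The updated state (phase `searching` for the next screw, or
#'   `complete`).
#' @export
guidance_advance <- function(state) {
  stopifnot(inherits(state, "guidance_state"))
  if (state$phase != "depth_reached") {
    stop("cannot advance: active screw has not reached planned depth",
         call. = FALSE)
  }
  if (state$active_index >= length(state$plan_order)) {
    state$phase <- "complete"
    state$active_screw <- NA_character_
    return(state)
  }
  state$active_index <- state$active_index + 1L
  state$active_screw <- state$plan_order[state$active_index]
  state$entry_ok <- FALSE
  state$axis_ok <- FALSE
  state$depth_progress <- 0
  state$phase <- "searching"
  state
}

#' Replay a pose log through the guidance state machine
#'
#' Deterministically replays a stream of drill poses against a list of
#' planned trajectories in drilling order, auto-advancing to the next screw
#' (emitting an `advanced` event) whenever the active screw reaches depth.
#'
#' @param poses A data frame with columns `t`, `tip_x`, `tip_y`, `tip_z`,
#'   `dir_x`, `dir_y`, `dir_z` (as read by [read_pose_log()]), in time
#'   order.
#' @param plans Named list of planned [trajectory()] objects; names must
#'   cover the plan order.
#' @param tolerances A [guidance_tolerances()].
#' @param plan_order Drilling order (default S1 right, S1 left, S2 right,
#'   S2 left).
#' @return List with `events` (tibble `t`, `event`, `screw`) and `state`
#'   (final `guidance_state`).
#' @export
replay_pose_log <- function(poses, plans, tolerances = guidance_tolerances(),
                            plan_order = CORRIDOR_LABELS) {
  stopifnot(is.data.frame(poses), all(plan_order %in% names(plans)))
  state <- guidance_init(plan_order)
  all_events <- list()
  for (i in seq_len(nrow(poses))) {
    if (state$phase == "complete") break
    pose <- drill_pose(
      poses$t[i],
      c(poses$tip_x[i], poses$tip_y[i], poses$tip_z[i]),
      c(poses$dir_x[i], poses$dir_y[i], poses$dir_z[i])
    )
    upd <- guidance_update(state, pose, plans[[state$active_screw]], tolerances)
    state <- upd$state
    if (nrow(upd$events)) all_events[[length(all_events) + 1]] <- upd$events
    if (state$phase == "depth_reached") {
      finished <- state$active_screw
      state <- guidance_advance(state)
      all_events[[length(all_events) + 1]] <- tibble::tibble(
        t = pose$t, event = "advanced", screw = finished)
    }
  }
  list(events = if (length(all_events)) dplyr::bind_rows(all_events)
       else empty_events(),
       state = state)
}
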
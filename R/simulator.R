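#' Steering-agent profile for the trial simulator
#'
#' Parameters of the synthetic participant that steers the inert sphere.
#' The sphere is a damped point mass: each tick the agent accelerates
#' toward its current waypoint (with angular steering noise) and the
#' velocity decays, so motion must be anticipated, as in the real
#' steering-wheel interaction.  Impairment-style knobs (noise, detours,
#' dwell above the obstacle) let batches of trials mimic less efficient
#' execution; they are simulation conveniences, not fitted patient models.
#'
#' @param max_accel_px_s2 Maximum commanded acceleration (px/s^2).
#' @param damping_per_s Velocity damping rate (1/s); terminal speed is
#'   `max_accel_px_s2 / damping_per_s`.
#' @param steering_noise_sd_rad SD of the angular noise added to the
#'   commanded direction at every control tick (rad).
#' @param replan_interval_s Time between waypoint re-evaluations (s).
#' @param detour_prob Probability, per replan, of inserting a spurious
#'   detour waypoint before resuming the task.
#' @param dwell_above_s Extra loiter time spent above the obstacle after
#'   first crossing it (s).
#' @param route_order Optional character vector: fixed cube elimination
#'   order (subset/permutation of top/bottom/left/right).  Default `NULL`
#'   uses greedy nearest-cube routing.
#' @return An object of class `agent_profile`.
#' @export
agent_profile <- function(max_accel_px_s2 = 550, damping_per_s = 1.8,
                          steering_noise_sd_rad = 0.6,
                          replan_interval_s = 0.25, detour_prob = 0.05,
                          dwell_above_s = 0, route_order = NULL) {
  stopifnot(max_accel_px_s2 > 0, damping_per_s >= 0,
            steering_noise_sd_rad >= 0, replan_interval_s > 0,
            detour_prob >= 0, detour_prob <= 1, dwell_above_s >= 0)
  if (!is.null(route_order))
    stopifnot(all(route_order %in% c("top", "bottom", "left", "right")),
              !anyDuplicated(route_order))
  structure(list(max_accel_px_s2 = max_accel_px_s2,
                 damping_per_s = damping_per_s,
                 steering_noise_sd_rad = steering_noise_sd_rad,
                 replan_interval_s = replan_interval_s,
                 detour_prob = detour_prob, dwell_above_s = dwell_above_s,
                 route_order = route_order),
            class = "agent_profile")
}

#' Simulate one trial of the paradigm
#'
#' Runs the steering agent through the scene at the scene's sampling rate
#' and returns the resulting trajectory log, exactly as the tablet would
#' have recorded it: sphere centre positions at 60 Hz plus an elimination
#' event whenever the sphere touches a not-yet-eliminated cube (centre
#' distance at most `sphere_radius_px + cube_half_size_px`).  The obstacle
#' segment is impassable; the controller routes around its nearer end, and
#' any step that would carry the sphere through the inflated obstacle band
#' is stopped at the band boundary.  The trial ends at the fourth
#' elimination or at `T_max_s`, whichever comes first; a profile too weak
#' or too noisy to finish yields a valid incomplete log.
#'
#' With the same `seed`, profile and scene the returned log is
#' bit-identical across calls.
#'
#' @param profile An [agent_profile()].
#' @param scene A validated [scene_config()].
#' @param seed Integer seed for this trial's random stream.
#' @param participant_id Identifier stored in the log.
#' @return A validated `trajectory_log`.
#' @export
simulate_trial <- function(profile, scene = default_scene(), seed = 1L,
                           participant_id = sprintf("sim-%d", seed)) {
  stopifnot(inherits(profile, "agent_profile"))
  scene <- validate_scene(scene)
  set.seed(as.integer(seed))
  sr <- scene$sample_rate_hz
  dt <- 1 / sr
  nmax <- scene$count_max
  noise <- if (profile$steering_noise_sd_rad > 0)
    stats::rnorm(nmax, 0, profile$steering_noise_sd_rad) else numeric(nmax)
  replan_every <- max(1L, round(profile$replan_interval_s * sr))
  contact <- scene$sphere_radius_px + scene$cube_half_size_px
  r <- scene$sphere_radius_px
  oy <- scene$obstacle_y_px
  half_band <- scene$obstacle_thickness_px / 2 + r
  ox0 <- scene$obstacle_x_min_px - r
  ox1 <- scene$obstacle_x_max_px + r
  clear <- 3 * r                     # clearance past an obstacle end
  W <- scene$screen_width_px; H <- scene$screen_height_px

  cubes <- scene$cube_centers
  remaining <- if (is.null(profile$route_order))
    c("top", "bottom", "left", "right") else profile$route_order
  fixed_route <- !is.null(profile$route_order)

  x <- scene$sphere_start[1]; y <- scene$sphere_start[2]
  vx <- 0; vy <- 0
  xs <- numeric(nmax); ys <- numeric(nmax)
  xs[1] <- x; ys[1] <- y
  ev_cube <- character(0); ev_i <- integer(0)

  pick_target <- function(x, y) {
    if (!length(remaining)) return(NULL)
    if (fixed_route) return(remaining[1])
    d <- vapply(remaining, function(cb) {
      cc <- cubes[[cb]]; sqrt((cc[1] - x)^2 + (cc[2] - y)^2)
    }, numeric(1))
    remaining[which.min(d)]
  }

  # waypoint toward `goal`, detouring around the obstacle end if the
  # straight segment would pierce the blocked band
  route_waypoint <- function(x, y, goal) {
    gy <- goal[2]
    if ((y - oy) * (gy - oy) < 0) {      # segment crosses the midline
      tcross <- (oy - y) / (gy - y)
      xc <- x + tcross * (goal[1] - x)
      if (xc > ox0 && xc < ox1) {
        end_x <- if (abs(x - ox0) + abs(goal[1] - ox0) <=
                     abs(x - ox1) + abs(goal[1] - ox1))
          ox0 - clear else ox1 + clear
        return(c(end_x, oy))
      }
    }
    goal
  }

  target <- pick_target(x, y)
  detour <- NULL
  dwell_until <- -1
  dwell_done <- profile$dwell_above_s <= 0
  crossed <- FALSE
  waypoint <- route_waypoint(x, y, cubes[[target]])
  n_ev <- 0L
  i <- 1L                                  # next sample index to fill (0-based index i)
  while (i < nmax) {
    tick <- i %% replan_every == 0L
    if (tick) {
      if (!is.null(detour) &&
          sqrt((detour[1] - x)^2 + (detour[2] - y)^2) < 4 * r) detour <- NULL
      if (is.null(detour) && profile$detour_prob > 0 &&
          stats::runif(1) < profile$detour_prob)
        detour <- c(stats::runif(1, r, W - r), stats::runif(1, r, H - r))
    }
    t_now <- i * dt
    goal <- if (!dwell_done && crossed && t_now < dwell_until) {
      c(x, oy + 6 * r)                     # loiter above the obstacle
    } else if (!is.null(detour)) detour else cubes[[target]]
    if (tick || i == 1L) waypoint <- route_waypoint(x, y, goal)

    dx <- waypoint[1] - x; dy <- waypoint[2] - y
    th <- atan2(dy, dx) + noise[i]
    ax <- profile$max_accel_px_s2 * cos(th)
    ay <- profile$max_accel_px_s2 * sin(th)
    vx <- (1 - profile$damping_per_s * dt) * vx + ax * dt
    vy <- (1 - profile$damping_per_s * dt) * vy + ay * dt
    nx <- x + vx * dt; ny <- y + vy * dt
    # obstacle band collision (band inflated by the sphere radius)
    in_x <- nx > ox0 && nx < ox1
    if (in_x) {
      lo <- oy - half_band; hi <- oy + half_band
      if (y <= lo && ny > lo) { ny <- lo; vy <- 0 }
      else if (y >= hi && ny < hi) { ny <- hi; vy <- 0 }
      else if (ny > lo && ny < hi && (y <= lo || y >= hi)) { ny <- y; vy <- 0 }
    }
    # screen bounds
    if (nx < r) { nx <- r; vx <- 0 } else if (nx > W - r) { nx <- W - r; vx <- 0 }
    if (ny < r) { ny <- r; vy <- 0 } else if (ny > H - r) { ny <- H - r; vy <- 0 }
    x <- nx; y <- ny
    xs[i + 1L] <- x; ys[i + 1L] <- y
    if (!crossed && y > oy) {
      crossed <- TRUE
      if (!dwell_done) dwell_until <- i * dt + profile$dwell_above_s
    }
    # elimination on contact
    cc <- cubes[[target]]
    if (sqrt((cc[1] - x)^2 + (cc[2] - y)^2) <= contact) {
      n_ev <- n_ev + 1L
      ev_cube <- c(ev_cube, target); ev_i <- c(ev_i, i)
      remaining <- setdiff(remaining, target)
      if (n_ev == 4L) { i <- i + 1L; break }
      target <- pick_target(x, y)
      waypoint <- route_waypoint(x, y, cubes[[target]])
    }
    i <- i + 1L
  }
  n_samples <- if (n_ev == 4L) ev_i[4L] + 1L else min(i, nmax)
  trajectory_log(participant_id, scene,
                 data.frame(x = xs[seq_len(n_samples)], y = ys[seq_len(n_samples)]),
                 data.frame(cube_id = ev_cube, sample_index = ev_i))
}

#' Simulate a batch of trials
#'
#' Derives one sub-seed per trial from the master seed (`seed + i - 1` for
#' trial i) and runs [simulate_trial()] for each, optionally writing every
#' log as a JSONL file into a directory.
#'
#' @param n Number of trials.
#' @param profile An [agent_profile()] used for every trial.
#' @param scene A validated [scene_config()].
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, each log is written as
#'   `<participant_id>.jsonl` there.
#' @return Invisibly, the list of `trajectory_log` objects.
#' @export
simulate_trials <- function(n, profile, scene = default_scene(), seed = 1L,
                            out_dir = NULL) {
  logs <- lapply(seq_len(n), function(k)
    simulate_trial(profile, scene, seed = as.integer(seed) + k - 1L,
                   participant_id = sprintf("sim-%05d", k)))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (lg in logs)
      write_trajectory_log(lg, file.path(out_dir, paste0(lg$participant_id, ".jsonl")))
  }
  invisible(logs)
}
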
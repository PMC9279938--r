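## Deterministic 2D world: axis-aligned rectangular obstacles, a kinematic
## (unicycle) robot with two forward range sensors at +/-30 degrees, and
## the closed control loop coupling the world to the spiking controller.
## Units: cm for lengths, radians for headings, ms for simulated time.

#' Robot pose
#'
#' @param x,y Position, cm.
#' @param heading Heading, radians; wrapped to (-pi, pi].
#' @return An object of class `pose`.
#' @export
pose <- function(x = 0, y = 0, heading = 0) {
  stopifnot(is.finite(x), is.finite(y), is.finite(heading))
  structure(list(x = x, y = y, heading = wrap_angle(heading)), class = "pose")
}

wrap_angle <- function(a) {
  while (a > pi) a <- a - 2 * pi
  while (a <= -pi) a <- a + 2 * pi
  a
}

#' Rectangular world
#'
#' @param obstacles List of axis-aligned rectangles, each
#'   `c(xmin, xmax, ymin, ymax)` in cm.
#' @param bounds Outer rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param robot_radius Robot disc radius, cm (> 0).
#' @param goal_x Optional x coordinate: crossing it ends a trial with
#'   terminal cause `"goal"` (`NA` to disable).
#' @return An object of class `world`.
#' @export
world <- function(obstacles = list(), bounds = c(-50, 500, -250, 250),
                  robot_radius = 5, goal_x = NA_real_) {
  stopifnot(robot_radius > 0, length(bounds) == 4,
            bounds[1] < bounds[2], bounds[3] < bounds[4])
  for (ob in obstacles) {
    stopifnot(length(ob) == 4, ob[1] < ob[2], ob[3] < ob[4])
    if (ob[1] < bounds[1] || ob[2] > bounds[2] ||
        ob[3] < bounds[3] || ob[4] > bounds[4])
      stop("obstacle outside world bounds")
  }
  structure(list(obstacles = obstacles, bounds = bounds,
                 robot_radius = robot_radius, goal_x = goal_x),
            class = "world")
}

#' Two-beam ultrasonic sensor rig
#'
#' Two single-ray beams at +/-30 degrees from the heading (a 60 degree
#' total span); readings are clipped to `[min_reading, max_range]`.
#'
#' @param beam_offset Half-span, radians (default `pi/6`).
#' @param min_reading,max_range Clip range, cm (defaults 15 and 30, matching
#'   the encoder's `d_min`/`d_max`).
#' @return An object of class `sensor_rig`.
#' @export
sensor_rig <- function(beam_offset = pi / 6, min_reading = 15,
                       max_range = 30) {
  stopifnot(beam_offset > 0, beam_offset < pi / 2,
            min_reading > 0, min_reading < max_range)
  structure(list(beam_offset = beam_offset, min_reading = min_reading,
                 max_range = max_range),
            class = "sensor_rig")
}

## distance along a ray to the nearest obstacle face (Inf if none);
## standard slab intersection, exact for axis-aligned rectangles
ray_distance <- function(ox, oy, dx, dy, obstacles) {
  best <- Inf
  for (ob in obstacles) {
    if (abs(dx) < 1e-12) {
      if (ox < ob[1] || ox > ob[2]) next
      txlo <- -Inf; txhi <- Inf
    } else {
      t1 <- (ob[1] - ox) / dx; t2 <- (ob[2] - ox) / dx
      txlo <- min(t1, t2); txhi <- max(t1, t2)
    }
    if (abs(dy) < 1e-12) {
      if (oy < ob[3] || oy > ob[4]) next
      tylo <- -Inf; tyhi <- Inf
    } else {
      t1 <- (ob[3] - oy) / dy; t2 <- (ob[4] - oy) / dy
      tylo <- min(t1, t2); tyhi <- max(t1, t2)
    }
    tlo <- max(txlo, tylo); thi <- min(txhi, tyhi)
    if (thi < tlo || thi < 0) next
    t <- if (tlo >= 0) tlo else 0
    if (t < best) best <- t
  }
  best
}

#' Read both range sensors
#'
#' Each reading is the distance along that sensor's ray to the nearest
#' obstacle face, clipped to the rig's range; no hit yields `max_range`.
#'
#' @param w A [world()].
#' @param p A [pose()]; must lie inside the world bounds.
#' @param rig A [sensor_rig()].
#' @return Named vector `c(d_left =, d_right =)` in cm.
#' @export
sense <- function(w, p, rig = sensor_rig()) {
  b <- w$bounds
  if (p$x < b[1] || p$x > b[2] || p$y < b[3] || p$y > b[4])
    stop("pose outside world bounds")
  al <- p$heading + rig$beam_offset
  ar <- p$heading - rig$beam_offset
  dl <- ray_distance(p$x, p$y, cos(al), sin(al), w$obstacles)
  dr <- ray_distance(p$x, p$y, cos(ar), sin(ar), w$obstacles)
  clipd <- function(d) {
    if (!is.finite(d) || d > rig$max_range) return(rig$max_range)
    if (d < rig$min_reading) return(rig$min_reading)
    d
  }
  c(d_left = clipd(dl), d_right = clipd(dr))
}

#' Motion parameters
#'
#' Unicycle kinematics: turning happens while advancing. The drivetrain of
#' the original platform is unpublished; the defaults are chosen so that an
#' obstacle first sensed at 30 cm admits both a failed (late-deciding) and
#' a successful (early-deciding) avoidance.
#'
#' @param forward_speed cm/s (default 4).
#' @param turn_rate rad/s (default 1.5).
#' @param control_period ms between sense/act exchanges (default 100).
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(forward_speed = 4, turn_rate = 1.5,
                          control_period = 100) {
  stopifnot(forward_speed > 0, turn_rate > 0, control_period > 0)
  structure(list(forward_speed = forward_speed, turn_rate = turn_rate,
                 control_period = control_period),
            class = "motion_params")
}

#' Advance the robot by one control period
#'
#' `straight` advances along the heading; `left`/`right` additionally
#' rotate the heading by +/- `turn_rate * dt` while advancing; `stop`
#' leaves the pose unchanged.
#'
#' @param p A [pose()].
#' @param mp [motion_params()].
#' @param cmd One of `"straight"`, `"left"`, `"right"`, `"stop"`.
#' @param dt_control Control period, ms.
#' @return The new pose.
#' @export
robot_step <- function(p, mp, cmd, dt_control = mp$control_period) {
  cmd <- match.arg(cmd, c("straight", "left", "right", "stop"))
  if (cmd == "stop") return(p)
  dt_s <- dt_control / 1000
  h <- p$heading
  if (cmd == "left") h <- h + mp$turn_rate * dt_s
  if (cmd == "right") h <- h - mp$turn_rate * dt_s
  step_len <- mp$forward_speed * dt_s
  pose(p$x + step_len * cos(h), p$y + step_len * sin(h), h)
}

#' Does the robot disc intersect any obstacle?
#'
#' Closed-contact convention: tangent contact at exactly the robot radius
#' counts as a collision.
#'
#' @param w A [world()].
#' @param p A [pose()].
#' @return Logical.
#' @export
check_collision <- function(w, p) {
  for (ob in w$obstacles) {
    cx <- min(max(p$x, ob[1]), ob[2])
    cy <- min(max(p$y, ob[3]), ob[4])
    if ((p$x - cx)^2 + (p$y - cy)^2 <= w$robot_radius^2) return(TRUE)
  }
  FALSE
}

#' Deterministic scenario fixtures
#'
#' `single_left` / `single_right` place one carton-sized obstacle offset to
#' that side of the robot's path, overlapping it just enough that a
#' straight-driving robot collides while an early right/left turn clears
#' it. `single_right` is constructed as the exact reflection of
#' `single_left` about the x axis. `slalom5` places four alternating
#' single-width obstacles followed by one double-width obstacle that spans
#' both sensor rays (the terminal wall).
#'
#' @param name One of `"single_left"`, `"single_right"`, `"slalom5"`.
#' @return `list(world = <world>, start = <pose>)`.
#' @export
make_scenario <- function(name) {
  valid <- c("single_left", "single_right", "slalom5")
  if (!name %in% valid)
    stop("unknown scenario '", name, "'; valid scenarios: ",
         paste(valid, collapse = ", "))
  reflect_rect <- function(r) c(r[1], r[2], -r[4], -r[3])
  if (name == "single_left") {
    w <- world(obstacles = list(c(35, 65, 0, 40)),
               bounds = c(-60, 200, -150, 150),
               goal_x = 60)
    return(list(world = w, start = pose(0, 0, 0)))
  }
  if (name == "single_right") {
    w <- world(obstacles = list(reflect_rect(c(35, 65, 0, 40))),
               bounds = c(-60, 200, -150, 150),
               goal_x = 60)
    return(list(world = w, start = pose(0, 0, 0)))
  }
  ## slalom5: four alternating single cartons along the robot's zigzag,
  ## then a double carton spanning both sensor rays. The two terminal
  ## cartons are staggered so that, on the slightly oblique final leg,
  ## both rays cross the proximity threshold together and the brake
  ## conjunction fires before either single-side channel can decide.
  obs <- list(c(35, 65, 0, 40),            # 1: left of the path -> turn right
              c(45, 71, -90, -60),         # 2: right of the deflected leg -> left
              c(120, 150, -43, -3),        # 3: left again -> right
              c(135, 163, -150, -120),     # 4: right again -> left
              c(248, 278, -106, -76),      # 5a: terminal double carton...
              c(247.5, 277.5, -140, -106)) # 5b: ...staggered across the leg
  w <- world(obstacles = obs, bounds = c(-60, 700, -350, 350),
             goal_x = NA_real_)
  w$obstacle_group <- c(1, 2, 3, 4, 5, 5)
  list(world = w, start = pose(0, 0, 0))
}

#' Run the closed sensorimotor loop
#'
#' Alternates sensing (every control period), network simulation at the
#' spec's clock, action decoding and robot motion until a collision, a stop
#' command, goal crossing, leaving the world bounds, or `max_duration`.
#' The network is first given a settling interval (robot parked, commands
#' suppressed) so the sliding rate window is full before the first
#' decision. Fully deterministic; `seed` only matters when `sensor_noise`
#' is positive, in which case a uniform jitter of that half-width (cm) is
#' added to each reading.
#'
#' @param spec Calibrated `snn_spec`.
#' @param w A [world()].
#' @param start Starting [pose()].
#' @param mp [motion_params()].
#' @param max_duration Trial cap, seconds.
#' @param seed Integer seed (used only for optional sensor noise).
#' @param state Optional starting network state (to carry learning across
#'   trials); default fresh.
#' @param settle_ms Settling interval before motion, ms (default 1000).
#' @param sensor_noise Half-width of uniform reading jitter, cm (default 0).
#' @return A `trial_log`: list with `table` (one row per control period),
#'   `events` (first release, first turn, decision time, stop/collision
#'   times), `terminal` cause, and the final network `state`.
#' @export
run_closed_loop <- function(spec, w, start, mp = motion_params(),
                            max_duration = 15, seed = 1L, state = NULL,
                            settle_ms = 1000,
                            sensor_noise = 0) {
  stopifnot(inherits(spec, "snn_spec"), !is.null(spec$calib))
  rig <- sensor_rig(min_reading = spec$encoder$d_min,
                    max_range = spec$encoder$d_max)
  if (is.null(state)) state <- network_init(spec)
  cp <- mp$control_period
  steps_per_cp <- round(cp / spec$dt)
  n_window <- max(1L, round(spec$rate_window / cp))
  if (sensor_noise > 0) set.seed(as.integer(seed))
  read_sensors <- function(p) {
    d <- sense(w, p, rig)
    if (sensor_noise > 0) {
      d <- d + stats::runif(2, -sensor_noise, sensor_noise)
      d <- pmin(pmax(d, rig$min_reading), rig$max_range)
    }
    d
  }

  p <- start
  out_counts <- rep(NA_real_, n_window)   # rolling per-period Out counts
  widx <- 0L

  ## settling: hold the first reading, let the rate window fill
  n_settle <- max(0L, round(settle_ms / cp))
  d <- read_sensors(p)
  for (k in seq_len(n_settle)) {
    ch <- run_chunk(spec, state, d[["d_left"]], d[["d_right"]], steps_per_cp)
    state <- ch$state
    widx <- widx %% n_window + 1L
    out_counts[widx] <- ch$counts$out
  }
  t_net0 <- state$t   # network clock at the start of the motion phase

  n_periods <- ceiling(max_duration * 1000 / cp)
  log_rows <- vector("list", n_periods)
  terminal <- "timeout"
  first_release <- NA_real_
  first_turn <- NA_real_
  stop_time <- NA_real_
  collision_time <- NA_real_
  t_ctrl <- 0

  for (k in seq_len(n_periods)) {
    d <- read_sensors(p)
    ch <- run_chunk(spec, state, d[["d_left"]], d[["d_right"]], steps_per_cp)
    state <- ch$state
    t_ctrl <- t_ctrl + cp
    if (is.na(first_release) && !is.na(ch$first_release_time))
      first_release <- ch$first_release_time - t_net0
    widx <- widx %% n_window + 1L
    out_counts[widx] <- ch$counts$out
    filled <- !is.na(out_counts)
    out_rate <- 1000 * sum(out_counts[filled]) / (sum(filled) * cp)
    stop_active <- ch$counts$stop >= 1
    cmd <- decode_action(out_rate, stop_active, spec$bands)
    if (is.na(first_turn) && cmd %in% c("left", "right"))
      first_turn <- t_ctrl
    log_rows[[k]] <- list(
      t_ms = t_ctrl, d_left = d[["d_left"]], d_right = d[["d_right"]],
      w12 = state$w12, w34 = state$w34,
      gamma12 = state$g12, gamma34 = state$g34,
      r1 = state$r1, r2 = state$r2,
      out_rate = out_rate, stop_spikes = ch$counts$stop,
      releases1 = ch$counts$rel1, releases2 = ch$counts$rel2,
      command = cmd, x = p$x, y = p$y, heading = p$heading,
      collision = FALSE)
    if (cmd == "stop") {
      stop_time <- t_ctrl
      terminal <- "stop"
      break
    }
    p <- robot_step(p, mp, cmd, cp)
    if (check_collision(w, p)) {
      log_rows[[k]]$collision <- TRUE
      collision_time <- t_ctrl
      terminal <- "collision"
      break
    }
    if (!is.na(w$goal_x) && p$x > w$goal_x) {
      terminal <- "goal"
      break
    }
    b <- w$bounds
    if (p$x < b[1] || p$x > b[2] || p$y < b[3] || p$y > b[4]) {
      terminal <- "out_of_bounds"
      break
    }
  }

  tab <- do.call(rbind, lapply(log_rows[!vapply(log_rows, is.null, TRUE)],
                               function(r) as.data.frame(r)))
  decision_time <- if (!is.na(first_release) && !is.na(first_turn))
    (first_turn - first_release) / 1000 else NA_real_
  structure(list(
    table = tab,
    events = list(first_release_ms = first_release,
                  first_turn_ms = first_turn,
                  decision_time_s = decision_time,
                  stop_time_ms = stop_time,
                  collision_time_ms = collision_time),
    terminal = terminal,
    state = state),
    class = "trial_log")
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("<trial_log> %d control periods, terminal: %s\n",
              nrow(x$table), x$terminal))
  ev <- x$events
  if (!is.na(ev$decision_time_s))
    cat(sprintf("  decision time: %.2f s (release %.0f ms -> turn %.0f ms)\n",
                ev$decision_time_s, ev$first_release_ms, ev$first_turn_ms))
  invisible(x)
}
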
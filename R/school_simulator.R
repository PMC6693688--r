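#' Define a vision region for a social force
#'
#' Each social force perceives neighbours only within a sphere of given
#' radius, minus up to two blind cones centred on the focal fish's heading:
#' one pointing forward (along the velocity) and one backward. Angles are
#' full apex angles in degrees, so `blind_behind_deg = 90` excludes the
#' 90-degree cone directly behind the fish. A fish at rest has no heading
#' and its blind cones are ignored for that frame.
#'
#' @param radius perception radius in body-length units; must be positive.
#' @param blind_behind_deg,blind_front_deg full apex angles of the excluded
#'   cones, in `[0, 360)`; 0 disables the cone.
#' @return an object of class `vision_region`.
#' @export
vision_region <- function(radius, blind_behind_deg = 0, blind_front_deg = 0) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0,
            blind_behind_deg >= 0, blind_behind_deg < 360,
            blind_front_deg >= 0, blind_front_deg < 360)
  structure(list(radius = radius,
                 blind_behind_deg = blind_behind_deg,
                 blind_front_deg = blind_front_deg),
            class = "vision_region")
}

#' Simulation configuration for a flashing fish school
#'
#' Holds every parameter of the agent-based model: the social-force
#' weights (cohesion, alignment, separation), the internal friction and
#' speed-control weights, the flash probability `P` (per frame, natural
#' value 0.5), the dark-fish probability `D` (a fish drawn dark at
#' initialization never flashes), per-force vision regions, and the
#' integration step. Mass is fixed at 1 so acceleration equals the total
#' force.
#'
#' Default vision radii preserve the required ordering (cohesion reaches
#' furthest, separation shortest, alignment intermediate): 25, 3 and 1
#' body lengths with blind cones of 90 degrees behind (cohesion),
#' 60 degrees front and behind (alignment), and 60 degrees behind
#' (separation). The cohesion radius exceeds the diameter of the
#' initialization cube: if cohesion cannot reach across the school,
#' subgroups that drift out of perception range separate irreversibly,
#' which contradicts the premise that a handful of flashing fish can
#' hold the whole school together.
#'
#' @param n_fish number of agents, at least 1.
#' @param w_c,w_a,w_s cohesion/alignment/separation weights (defaults
#'   7, 6, 9).
#' @param w_f,w_v friction and speed-control weights (defaults 1.05, 5).
#' @param v_max maximum speed, body lengths per second.
#' @param v_cruise preferred speed targeted by the speed-control force.
#' @param dt integration step in seconds (default 1/30, matching 30 fps).
#' @param P per-frame flash probability in `[0, 1]`.
#' @param D probability that a fish is dark (never flashes).
#' @param cohesion_region,alignment_region,separation_region
#'   [vision_region()] objects.
#' @param init_half_width half-width of the initialization cube; fish start
#'   at rest, uniformly placed in `[-init_half_width, init_half_width]^3`.
#' @param flash_mode `"bernoulli"` (independent per-frame draws with
#'   probability `P`) or `"square_wave"` (deterministic on/off schedule with
#'   per-fish random phase).
#' @param flash_on_s,flash_off_s on and off durations of the square wave,
#'   seconds.
#' @param flash_gates_all_forces if `TRUE` (default) non-flashing fish are
#'   invisible to all three social forces; if `FALSE` only cohesion
#'   (vision-mediated) is gated, leaving the lateral-line-mediated
#'   alignment and separation ungated, for sensitivity analysis.
#' @param seed optional integer seed; [run_simulation()] sets it before
#'   initialization so runs are reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_fish,
                       w_c = 7, w_a = 6, w_s = 9,
                       w_f = 1.05, w_v = 5,
                       v_max = 2, v_cruise = 0.8 * v_max,
                       dt = 1 / 30,
                       P = 0.5, D = 0,
                       cohesion_region = vision_region(25, blind_behind_deg = 90),
                       alignment_region = vision_region(3, blind_behind_deg = 60,
                                                        blind_front_deg = 60),
                       separation_region = vision_region(1, blind_behind_deg = 60),
                       init_half_width = 10,
                       flash_mode = c("bernoulli", "square_wave"),
                       flash_on_s = 0.166, flash_off_s = 0.168,
                       flash_gates_all_forces = TRUE,
                       seed = NULL) {
  flash_mode <- match.arg(flash_mode)
  if (!is.numeric(n_fish) || length(n_fish) != 1L || n_fish < 1)
    stop("invalid config: n_fish must be >= 1")
  stopifnot(w_c >= 0, w_a >= 0, w_s >= 0, w_f >= 0, w_v >= 0,
            P >= 0, P <= 1, D >= 0, D <= 1,
            dt > 0, v_max > 0, v_cruise >= 0,
            inherits(cohesion_region, "vision_region"),
            inherits(alignment_region, "vision_region"),
            inherits(separation_region, "vision_region"),
            init_half_width > 0, flash_on_s > 0, flash_off_s > 0)
  structure(list(n_fish = as.integer(n_fish),
                 w_c = w_c, w_a = w_a, w_s = w_s, w_f = w_f, w_v = w_v,
                 v_max = v_max, v_cruise = v_cruise, dt = dt, P = P, D = D,
                 cohesion_region = cohesion_region,
                 alignment_region = alignment_region,
                 separation_region = separation_region,
                 init_half_width = init_half_width,
                 flash_mode = flash_mode,
                 flash_on_s = flash_on_s, flash_off_s = flash_off_s,
                 flash_gates_all_forces = isTRUE(flash_gates_all_forces),
                 seed = seed),
            class = "sim_config")
}

square_wave_frames <- function(config) {
  on <- max(1L, as.integer(round(config$flash_on_s / config$dt)))
  off <- max(1L, as.integer(round(config$flash_off_s / config$dt)))
  c(on = on, period = on + off)
}

#' Initialize a school at rest
#'
#' Places each fish uniformly at random inside a cube of side
#' `2 * init_half_width` centred on the origin, with zero velocity and
#' acceleration. Each fish is permanently dark when its uniform draw `R`
#' falls below `D`. Initial flashing states are drawn by the same rule
#' used at every later frame.
#'
#' @param config a [sim_config()].
#' @return a `school_state`: list with `position` and `velocity`
#'   (`n_fish` x 3 matrices), logical `dark`, `flashing`, `motivated`,
#'   per-fish motivated velocity rows `mot_vel`, square-wave `phase`
#'   (frames), and the current `frame` index (0).
#' @export
init_school <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_fish
  position <- matrix(stats::runif(3 * n, -config$init_half_width,
                                  config$init_half_width),
                     nrow = n, ncol = 3)
  dark <- stats::runif(n) < config$D
  sw <- square_wave_frames(config)
  phase <- if (config$flash_mode == "square_wave")
    sample.int(sw[["period"]], n, replace = TRUE) - 1L
  else
    integer(n)
  state <- list(position = position,
                velocity = matrix(0, n, 3),
                dark = dark,
                flashing = rep(FALSE, n),
                motivated = rep(FALSE, n),
                mot_vel = matrix(0, n, 3),
                phase = phase,
                frame = 0L)
  state$flashing <- draw_flashing(state, config)
  structure(state, class = "school_state")
}

# flash redraw rule shared by init and step; consumes n uniforms in agent
# order in bernoulli mode
draw_flashing <- function(state, config) {
  n <- config$n_fish
  if (config$flash_mode == "bernoulli") {
    stats::runif(n) < config$P & !state$dark
  } else {
    sw <- square_wave_frames(config)
    ph <- (state$frame + state$phase) %% sw[["period"]]
    ph < sw[["on"]] & !state$dark
  }
}

region_spec <- function(region)
  c(region$radius, region$blind_front_deg, region$blind_behind_deg)

#' Neighbours visible to a focal fish for one social force
#'
#' Returns the indices of school members within the region's radius whose
#' bearing from the focal fish's heading lies outside both blind cones.
#' When `flash_gated` is `TRUE`, fish not flashing on this frame are
#' invisible. A focal fish at rest has no heading, so blind cones are not
#' applied. The focal fish never sees itself.
#'
#' @param i focal fish index (1-based).
#' @param state a `school_state`.
#' @param region a [vision_region()].
#' @param flash_gated exclude non-flashing neighbours?
#' @return integer vector of visible neighbour indices.
#' @export
visible_neighbors <- function(i, state, region, flash_gated = TRUE) {
  pos <- state$position
  n <- nrow(pos)
  disp <- sweep(pos, 2, pos[i, ])
  d2 <- rowSums(disp^2)
  ok <- d2 <= region$radius^2
  ok[i] <- FALSE
  if (flash_gated) ok <- ok & state$flashing
  v <- state$velocity[i, ]
  sp <- sqrt(sum(v^2))
  if (sp > 0 && any(ok)) {
    dot <- (disp %*% (v / sp))[, 1] / sqrt(pmax(d2, .Machine$double.xmin))
    if (region$blind_front_deg > 0)
      ok <- ok & !(dot > cos(region$blind_front_deg / 2 * pi / 180))
    if (region$blind_behind_deg > 0)
      ok <- ok & !(dot < -cos(region$blind_behind_deg / 2 * pi / 180))
  }
  which(ok)
}

unit_or_zero <- function(x) {
  nm <- sqrt(sum(x^2))
  if (nm > 0) x / nm else c(0, 0, 0)
}

#' Social and internal force components
#'
#' Unweighted force laws of the model. Each social force steers toward a
#' target direction at the maximum speed: `f = unit(s) * v_max - v`, where
#' `s` is, respectively, the displacement to the centroid of visible
#' neighbours (cohesion), the mean neighbour velocity (alignment), or the
#' mean of inverse-square repulsion vectors `(r - r_k) / |r - r_k|^2`
#' (separation). An empty visible set, or a zero `s`-vector, contributes
#' the zero vector so that undefined directions never brake the fish.
#'
#' @param pos,vel focal position and velocity, length-3 numerics.
#' @param nbr_pos,nbr_vel matrices (one row per visible neighbour).
#' @param v_max maximum speed.
#' @return a length-3 force vector (pre-weighting).
#' @export
cohesion_force <- function(pos, vel, nbr_pos, v_max) {
  if (is.null(nbr_pos) || nrow(nbr_pos) == 0L) return(c(0, 0, 0))
  s <- colMeans(nbr_pos) - pos
  u <- unit_or_zero(s)
  if (all(u == 0)) return(c(0, 0, 0))
  u * v_max - vel
}

#' @rdname cohesion_force
#' @export
alignment_force <- function(vel, nbr_vel, v_max) {
  if (is.null(nbr_vel) || nrow(nbr_vel) == 0L) return(c(0, 0, 0))
  u <- unit_or_zero(colMeans(nbr_vel))
  if (all(u == 0)) return(c(0, 0, 0))
  u * v_max - vel
}

#' @rdname cohesion_force
#' @export
separation_force <- function(pos, vel, nbr_pos, v_max) {
  if (is.null(nbr_pos) || nrow(nbr_pos) == 0L) return(c(0, 0, 0))
  disp <- sweep(nbr_pos, 2, pos)          # r_k - r
  d2 <- rowSums(disp^2)
  if (any(d2 == 0)) stop("degenerate geometry: coincident agents")
  u <- unit_or_zero(colMeans(-disp / d2))
  if (all(u == 0)) return(c(0, 0, 0))
  u * v_max - vel
}

#' Internal friction and speed-control forces
#'
#' Friction is linear drag `-v` (pre-weight). Speed control pushes the
#' speed toward the preferred cruise speed along the current heading:
#' `unit(v) * (v_cruise - |v|)`; a fish at rest has no heading and feels
#' neither force.
#'
#' @param vel focal velocity, length 3.
#' @param v_cruise preferred speed.
#' @return list with components `friction` and `speed_control`.
#' @export
internal_forces <- function(vel, v_cruise) {
  sp <- sqrt(sum(vel^2))
  if (sp == 0) return(list(friction = c(0, 0, 0), speed_control = c(0, 0, 0)))
  list(friction = -vel,
       speed_control = vel / sp * (v_cruise - sp))
}

#' Advance the school one frame (reference implementation)
#'
#' Synchronous explicit Euler update: every fish's forces are evaluated on
#' the previous frame's positions, velocities and flashing states, then
#' `v <- clamp(v + f_tot * dt, v_max)` and `r <- r + v * dt`, and finally
#' the flashing flags are redrawn. Motivated fish ignore all forces and
#' move at their fixed velocity. This pure-R step is the executable
#' definition of the model; [run_simulation()] uses a compiled
#' equivalent that consumes the identical RNG stream.
#'
#' @param state a `school_state`.
#' @param config the [sim_config()].
#' @return the next `school_state`.
#' @export
step_school <- function(state, config) {
  n <- config$n_fish
  gate_all <- config$flash_gates_all_forces
  # coincident agents are degenerate only when they can perceive each
  # other; mutually invisible dark fish may legitimately overlap
  dup <- which(duplicated(state$position) |
                 duplicated(state$position, fromLast = TRUE))
  if (length(dup) > 1) {
    key <- apply(state$position[dup, , drop = FALSE], 1, paste,
                 collapse = ",")
    for (g in split(dup, key)) {
      if (length(g) > 1 && (!gate_all || any(state$flashing[g])))
        stop("degenerate geometry: coincident agents")
    }
  }
  new_vel <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (state$motivated[i]) {
      new_vel[i, ] <- state$mot_vel[i, ]
      next
    }
    vi <- state$velocity[i, ]
    nc <- visible_neighbors(i, state, config$cohesion_region, TRUE)
    na <- visible_neighbors(i, state, config$alignment_region, gate_all)
    ns <- visible_neighbors(i, state, config$separation_region, gate_all)
    fi <- internal_forces(vi, config$v_cruise)
    f <- config$w_c * cohesion_force(state$position[i, ], vi,
                                     state$position[nc, , drop = FALSE],
                                     config$v_max) +
      config$w_a * alignment_force(vi,
                                   state$velocity[na, , drop = FALSE],
                                   config$v_max) +
      config$w_s * separation_force(state$position[i, ], vi,
                                    state$position[ns, , drop = FALSE],
                                    config$v_max) +
      config$w_f * fi$friction +
      config$w_v * fi$speed_control
    v <- vi + f * config$dt
    sp <- sqrt(sum(v^2))
    if (sp > config$v_max) v <- v * config$v_max / sp
    if (!all(is.finite(v))) stop("numeric failure: non-finite velocity")
    new_vel[i, ] <- v
  }
  state$velocity <- new_vel
  state$position <- state$position + new_vel * config$dt
  state$frame <- state$frame + 1L
  state$flashing <- draw_flashing(state, config)
  state
}

#' Flag fish as motivated leaders
#'
#' Motivated fish thereafter ignore all social and internal forces and
#' swim at `direction * min(speed_factor * v_cruise, v_max)`. They must
#' not be dark: invisible leaders cannot be followed.
#'
#' @param state a `school_state`.
#' @param agent_ids indices of the fish to motivate (non-empty).
#' @param direction length-3 direction (normalized internally).
#' @param speed_factor multiple of `v_cruise` at which leaders swim;
#'   capped at `v_max`.
#' @param config the [sim_config()] (for `v_cruise` and `v_max`).
#' @return the modified state.
#' @export
set_motivated <- function(state, agent_ids, direction, speed_factor, config) {
  n <- nrow(state$position)
  if (length(agent_ids) == 0L) stop("agent_ids must be non-empty")
  if (any(agent_ids < 1 | agent_ids > n)) stop("unknown agent id")
  if (any(state$dark[agent_ids]))
    stop("motivated fish must not be dark")
  u <- unit_or_zero(direction)
  if (all(u == 0)) stop("direction must be non-zero")
  speed <- min(speed_factor * config$v_cruise, config$v_max)
  state$motivated[agent_ids] <- TRUE
  state$mot_vel[agent_ids, ] <- matrix(u * speed, length(agent_ids), 3,
                                       byrow = TRUE)
  state
}

#' Run the school simulation
#'
#' Drives the compiled step kernel (or the pure-R reference step) for
#' `n_frames` frames, recording every frame. Interventions are applied to
#' the state immediately before the force evaluation of their frame; each
#' is a list with a `frame` index (1-based step number) and a function
#' `fn(state, config)` returning the modified state (for instance a
#' [set_motivated()] call, or a redraw of dark flags to sweep `D` in
#' time).
#'
#' @param config a [sim_config()]; when `config$seed` is set the RNG is
#'   seeded first, making the trajectory fully reproducible.
#' @param n_frames number of update steps, at least 1.
#' @param interventions optional list of `list(frame =, fn =)` entries.
#' @param state optional starting `school_state`; defaults to
#'   [init_school()].
#' @param engine `"cpp"` (default) or `"r"`; both produce identical
#'   trajectories for identical seeds.
#' @return a `school_trajectory`: arrays `position` and `velocity` with
#'   dimensions `n_fish` x 3 x (n_frames + 1), a `flashing` matrix
#'   `n_fish` x (n_frames + 1), vectors `dark` and `motivated`, and `dt`.
#'   Frame indices are 0-based: slice `[, , t + 1]` is frame `t`.
#' @export
run_simulation <- function(config, n_frames, interventions = NULL,
                           state = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "sim_config"), n_frames >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(state)) state <- init_school(config)

  breaks <- integer(0)
  if (!is.null(interventions)) {
    frames <- vapply(interventions, `[[`, integer(1) + 0, "frame")
    stopifnot(all(frames >= 1), all(frames <= n_frames))
    breaks <- sort(unique(frames))
  }

  n <- config$n_fish
  T_total <- n_frames + 1L
  pos <- array(NA_real_, c(n, 3, T_total))
  vel <- array(NA_real_, c(n, 3, T_total))
  fla <- matrix(NA, n, T_total)

  record <- function(seg, at) {
    len <- dim(seg$position)[3]
    idx <- at + seq_len(len) - 1L
    pos[, , idx] <<- seg$position
    vel[, , idx] <<- seg$velocity
    fla[, idx] <<- seg$flashing
  }

  run_segment <- function(state, k) {
    if (k == 0L)
      return(list(position = array(state$position, c(n, 3, 1)),
                  velocity = array(state$velocity, c(n, 3, 1)),
                  flashing = matrix(state$flashing, n, 1),
                  state = state))
    if (engine == "cpp") {
      sw <- square_wave_frames(config)
      out <- sim_run_cpp(state$position, state$velocity, state$dark,
                         state$flashing, state$motivated, state$mot_vel,
                         state$phase, sw[["on"]], sw[["period"]],
                         if (config$flash_mode == "bernoulli") 0L else 1L,
                         config$P,
                         config$w_c, config$w_a, config$w_s,
                         config$w_f, config$w_v,
                         config$v_max, config$v_cruise, config$dt,
                         region_spec(config$cohesion_region),
                         region_spec(config$alignment_region),
                         region_spec(config$separation_region),
                         config$flash_gates_all_forces, k, state$frame)
      last <- dim(out$position)[3]
      state$position <- out$position[, , last, drop = FALSE][, , 1]
      state$velocity <- out$velocity[, , last, drop = FALSE][, , 1]
      if (n == 1L) {
        state$position <- matrix(out$position[, , last], 1, 3)
        state$velocity <- matrix(out$velocity[, , last], 1, 3)
      }
      state$flashing <- as.logical(out$flashing[, last])
      state$frame <- state$frame + k
      list(position = out$position, velocity = out$velocity,
           flashing = out$flashing, state = state)
    } else {
      p <- array(NA_real_, c(n, 3, k + 1L))
      v <- array(NA_real_, c(n, 3, k + 1L))
      f <- matrix(NA, n, k + 1L)
      p[, , 1] <- state$position; v[, , 1] <- state$velocity
      f[, 1] <- state$flashing
      for (s in seq_len(k)) {
        state <- step_school(state, config)
        p[, , s + 1L] <- state$position
        v[, , s + 1L] <- state$velocity
        f[, s + 1L] <- state$flashing
      }
      list(position = p, velocity = v, flashing = f, state = state)
    }
  }

  done <- 0L
  pos[, , 1] <- state$position
  vel[, , 1] <- state$velocity
  fla[, 1] <- state$flashing
  for (b in c(breaks, n_frames + 1L)) {
    k <- min(b - 1L, n_frames) - done
    if (k > 0) {
      seg <- run_segment(state, k)
      record(list(position = seg$position[, , -1, drop = FALSE],
                  velocity = seg$velocity[, , -1, drop = FALSE],
                  flashing = seg$flashing[, -1, drop = FALSE]),
             done + 2L)
      state <- seg$state
      done <- done + k
    }
    if (b <= n_frames) {
      for (iv in interventions)
        if (iv$frame == b) state <- iv$fn(state, config)
    }
  }

  structure(list(position = pos, velocity = vel, flashing = fla,
                 dark = state$dark, motivated = state$motivated,
                 dt = config$dt, n_frames = as.integer(n_frames)),
            class = "school_trajectory")
}

#' @export
print.school_trajectory <- function(x, ...) {
  cat(sprintf(
    "school_trajectory: %d fish, %d frames (dt = %.4g s), %d dark, %d motivated\n",
    dim(x$position)[1], dim(x$position)[3], sum(x$dark), sum(x$motivated)))
  invisible(x)
}

#' Flatten a trajectory to a long table
#'
#' One row per agent-frame with columns `frame` (0-based), `agent_id`,
#' `x, y, z`, `vx, vy, vz`, and 0/1 `flashing`, `dark`, `motivated` —
#' the on-disk CSV schema shared with tracked video.
#'
#' @param x a `school_trajectory`.
#' @param ... unused.
#' @return a `data.frame`.
#' @export
as.data.frame.school_trajectory <- function(x, ...) {
  n <- dim(x$position)[1]
  T_total <- dim(x$position)[3]
  frame <- rep(seq_len(T_total) - 1L, each = n)
  data.frame(frame = frame,
             agent_id = rep(seq_len(n), T_total),
             x = as.vector(x$position[, 1, ]),
             y = as.vector(x$position[, 2, ]),
             z = as.vector(x$position[, 3, ]),
             vx = as.vector(x$velocity[, 1, ]),
             vy = as.vector(x$velocity[, 2, ]),
             vz = as.vector(x$velocity[, 3, ]),
             flashing = as.integer(as.vector(x$flashing)),
             dark = rep(as.integer(x$dark), T_total),
             motivated = rep(as.integer(x$motivated), T_total))
}
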
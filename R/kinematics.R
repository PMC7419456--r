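# Shared-control simulation of the flexible actuated fetoscope. The
# instrument enters the cavity through a fulcrum (the entry port removes
# two degrees of freedom), carries a rigid shaft ending at frame {E} and a
# steerable flexible distal tip with two actuated joints: R1, the roll of
# the shaft about its own axis, and R2, the bending of the distal segment
# (constant-curvature model). The camera sits at the tip, its optical axis
# tangent to the bent segment. In shared control the operator commands the
# gross handle motion while R1/R2 are servoed autonomously so that the
# camera stays perpendicular to the placental surface.

#' Distal tip kinematic parameters
#'
#' @param segment_length_mm length of the flexible bending segment.
#' @param camera_offset_mm camera position offset along the tip tangent.
#' @param r2_range_deg mechanical range of the bending joint, degrees.
#' @return A `tip_kinematics` list.
#' @export
tip_kinematics <- function(segment_length_mm = 10, camera_offset_mm = 0,
                           r2_range_deg = c(0, 90)) {
  stopifnot(segment_length_mm > 0)
  structure(list(segment_length_mm = segment_length_mm,
                 camera_offset_mm = camera_offset_mm,
                 r2_range_deg = r2_range_deg),
            class = "tip_kinematics")
}

#' Instrument state
#'
#' The instrument is parameterized by the direction of the shaft through
#' the fulcrum (a unit vector), the insertion depth of the shaft end past
#' the fulcrum, and the two distal joints. The fulcrum constraint is
#' satisfied by construction: the shaft axis always passes through the
#' fulcrum point.
#'
#' @param shaft_dir unit vector of the shaft axis, pointing into the
#'   cavity (world frame).
#' @param insertion_mm distance from the fulcrum to the shaft end {E}.
#' @param r1_deg,r2_deg distal joint values, degrees.
#' @param fulcrum world position of the entry port (mm).
#' @param kin a [tip_kinematics()].
#' @return An `instrument_state` list.
#' @export
instrument_state <- function(shaft_dir = c(0, 0, 1), insertion_mm = 30,
                             r1_deg = 0, r2_deg = 0,
                             fulcrum = c(0, 0, 0), kin = tip_kinematics()) {
  r2_deg <- min(max(r2_deg, kin$r2_range_deg[1]), kin$r2_range_deg[2])
  structure(list(shaft_dir = normalize_vec(shaft_dir),
                 insertion_mm = insertion_mm,
                 r1_deg = r1_deg, r2_deg = r2_deg,
                 fulcrum = fulcrum, kin = kin),
            class = "instrument_state")
}

# Orientation of the shaft-end frame {E}: z along the shaft, x/y completed
# from a fixed reference axis. The reference must stay fixed across the
# instrument workspace (shaft directions point into the cavity, near +z):
# switching references mid-sweep would discontinuously roll {E} and with
# it the R1 target.
shaft_frame <- function(shaft_dir) {
  z <- normalize_vec(shaft_dir)
  a <- if (abs(z[1]) < 0.99) c(1, 0, 0) else c(0, 1, 0)
  x <- normalize_vec(a - sum(a * z) * z)
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

# Constant-curvature bend of angle r2 (degrees) about the local x-axis for
# a segment of length L: returns the 4x4 transform from the segment base to
# the tip, tangent included. r2 = 0 degenerates to a straight segment.
bend_transform <- function(r2_deg, L) {
  th <- deg2rad(r2_deg)
  if (abs(th) < 1e-9) {
    return(rigid_transform(diag(3), c(0, 0, L)))
  }
  rho <- L / th
  # bending about +x curves the tip towards -y while advancing along +z
  pos <- c(0, -rho * (1 - cos(th)), rho * sin(th))
  rigid_transform(rot_x(r2_deg), pos)
}

#' Forward kinematics of the instrument
#'
#' Composes the fulcrum-constrained shaft placement with the distal roll
#' (R1, about the shaft axis) and the constant-curvature bend (R2) to give
#' the shaft-end pose `^W T_E` and the camera pose `^W T_C`. With R2 = 0
#' the camera axis is collinear with the shaft axis.
#'
#' @param state an [instrument_state()].
#' @return List with `T_E` and `T_C` (4x4 transforms).
#' @export
forward_kinematics <- function(state) {
  Re <- shaft_frame(state$shaft_dir)
  pe <- state$fulcrum + state$insertion_mm * state$shaft_dir
  T_E <- rigid_transform(Re, pe)
  T_tip <- T_E %*% rigid_transform(rot_z(state$r1_deg)) %*%
    bend_transform(state$r2_deg, state$kin$segment_length_mm)
  if (state$kin$camera_offset_mm != 0) {
    T_tip <- T_tip %*% rigid_transform(diag(3), c(0, 0, state$kin$camera_offset_mm))
  }
  list(T_E = T_E, T_C = T_tip)
}

#' Inverse kinematics from inclination errors to joint targets
#'
#' Given the measured label `(x_m, y_m)` (so errors `(x_e, y_e) = -(x_m,
#' y_m)` for a perpendicular set-point) and the current state, computes the
#' absolute joint targets `(R1_d, R2_d)` that zero the label: the bending
#' magnitude follows the arcsine of the misalignment and the roll aligns
#' the bending plane with the error direction. With a truthful label and
#' rigid joints a single application achieves perpendicularity.
#'
#' @param measured_label measured inclination components `(x_m, y_m)`.
#' @param state an [instrument_state()].
#' @return List with `r1_deg`, `r2_deg` (absolute targets, R2 clamped to
#'   its mechanical range) and `reachable`.
#' @export
inverse_kinematics <- function(measured_label, state) {
  m <- as.numeric(measured_label)
  r <- sqrt(sum(m^2))
  if (r > 1) {
    warning("measured label outside the unit disc; clamped")
    m <- m / r; r <- 1
  }
  fk <- forward_kinematics(state)
  # desired camera z in the {E} frame: current ^E R_C applied to the
  # placenta axis measured in the camera frame
  R_EC <- crossprod(fk$T_E[1:3, 1:3], fk$T_C[1:3, 1:3])
  z_des <- drop(R_EC %*% label_to_axis(m))
  z_des <- z_des / sqrt(sum(z_des^2))
  # joint solution of z_C^E(R1, R2) = Rz(R1) Bend_x(R2) e_z
  #   = (sin R2 sin R1, -sin R2 cos R1, cos R2)
  r2 <- rad2deg(acos(min(1, max(-1, z_des[3]))))
  r1 <- if (r2 < 1e-9) state$r1_deg else rad2deg(atan2(z_des[1], -z_des[2]))
  lim <- state$kin$r2_range_deg
  reachable <- r2 >= lim[1] - 1e-9 && r2 <= lim[2] + 1e-9
  list(r1_deg = r1, r2_deg = min(max(r2, lim[1]), lim[2]),
       reachable = reachable)
}

#' PID gains and limits
#'
#' @param kp,ki,kd non-negative gains (per joint, identical for both).
#' @param output_limit command saturation (deg/s).
#' @param rate_hz control loop rate.
#' @param meas_alpha weight of the newest measurement in the exponential
#'   low-pass filter applied to the measured inclination before the
#'   inverse kinematics (1 disables filtering). Noisy per-frame estimates
#'   otherwise jitter the joint targets.
#' @return A `pid_gains` list.
#' @export
pid_gains <- function(kp = 20, ki = 0.5, kd = 0.05, output_limit = 720,
                      rate_hz = 40, meas_alpha = 0.6) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, rate_hz > 0,
            meas_alpha > 0, meas_alpha <= 1)
  structure(list(kp = kp, ki = ki, kd = kd, output_limit = output_limit,
                 rate_hz = rate_hz, meas_alpha = meas_alpha),
            class = "pid_gains")
}

pid_state <- function() list(integral = c(0, 0), prev_error = c(0, 0))

# One discrete PID step with clamping anti-windup; errors and commands are
# length-2 (R1, R2). With kp = 1, ki = kd = 0 the command equals the error.
pid_step <- function(gains, error, state, dt) {
  d <- if (all(is.finite(state$prev_error))) (error - state$prev_error) / dt
       else c(0, 0)
  candidate <- state$integral + error * dt
  cmd_raw <- gains$kp * error + gains$ki * candidate + gains$kd * d
  cmd <- pmin(pmax(cmd_raw, -gains$output_limit), gains$output_limit)
  # anti-windup: only integrate when not pushing further into saturation
  grow <- (cmd_raw == cmd) | (sign(error) != sign(cmd_raw))
  state$integral <- ifelse(grow, candidate, state$integral)
  state$prev_error <- error
  list(command = cmd, state = state)
}

# wrap an angular difference to (-180, 180]
wrap_angle <- function(a) ((a + 180) %% 360) - 180

#' One tick of the shared-control loop
#'
#' Renders (or queries the oracle for) the current view, obtains the
#' measured inclination, runs the inverse kinematics and the PID, applies
#' rate-limited joint dynamics and advances one control period. When the
#' surface leaves the field of view the last commands are held and the
#' tick is flagged.
#'
#' @param scene list with `surface` (a [placenta_surface()]), `light`,
#'   `cfg` (render configuration used when a model is in the loop).
#' @param state an [instrument_state()].
#' @param estimator either the string `"oracle"` (feedback is the exact
#'   scene label) or a `trained_model` whose predictions close the loop.
#' @param gains a [pid_gains()].
#' @param loop internal loop memory (PID state, joint rates); pass the
#'   value returned by the previous tick or NULL to start.
#' @param label_noise_sd optional Gaussian noise added to oracle labels.
#' @return List with `state` (advanced), `loop`, and `row` (one log
#'   record).
#' @export
closed_loop_step <- function(scene, state, estimator = "oracle",
                             gains = pid_gains(), loop = NULL,
                             label_noise_sd = 0) {
  if (is.null(loop)) {
    loop <- list(pid = pid_state(), targets = c(state$r1_deg, state$r2_deg),
                 tick = 0L)
  }
  dt <- 1 / gains$rate_hz
  fk <- forward_kinematics(state)
  z_c <- fk$T_C[1:3, 3]
  z_p <- -scene$surface$normal
  err_deg <- combined_error(z_c, z_p)

  measured <- tryCatch({
    if (identical(estimator, "oracle")) {
      lab <- label_from_scene(fk$T_C, scene$surface$normal)
      if (label_noise_sd > 0) lab <- lab + rnorm(2, 0, label_noise_sd)
      clamp_label(lab)
    } else {
      rv <- render_view(scene$surface, fk$T_C, scene$light, scene$cfg)
      predict(estimator, rv$image)
    }
  }, error = function(e) NULL)

  visible <- !is.null(measured)
  if (visible) {
    # exponential low-pass on the measurement stream before the IK
    if (gains$meas_alpha < 1 && !is.null(loop$filtered)) {
      measured <- clamp_label(gains$meas_alpha * measured +
                                (1 - gains$meas_alpha) * loop$filtered)
    }
    loop$filtered <- measured
    ik <- inverse_kinematics(measured, state)
    loop$targets <- c(ik$r1_deg, ik$r2_deg)
    # when the bending plane must swing far (the required bend direction
    # flips as the shaft crosses the surface-perpendicular ray), retract
    # the bend while the roll swings: rolling a deployed tip through a
    # large arc drags the camera far off target, while bending through
    # zero re-orients with a bounded excursion
    r1_err_now <- abs(wrap_angle(ik$r1_deg - state$r1_deg))
    if (r1_err_now > 90) loop$targets[2] <- 0
  }
  joint_now <- c(state$r1_deg, state$r2_deg)
  joint_err <- c(wrap_angle(loop$targets[1] - joint_now[1]),
                 loop$targets[2] - joint_now[2])
  ps <- pid_step(gains, joint_err, loop$pid, dt)
  loop$pid <- ps$state
  new_joints <- joint_now + ps$command * dt   # commands are joint rates
  lim <- state$kin$r2_range_deg
  state$r1_deg <- new_joints[1]
  state$r2_deg <- min(max(new_joints[2], lim[1]), lim[2])
  loop$tick <- loop$tick + 1L

  # tip projection onto the surface plane (for heatmaps)
  su <- scene$surface
  denom <- sum(z_c * su$normal)
  tip_uv <- c(NA_real_, NA_real_)
  if (abs(denom) > 1e-9) {
    tt <- sum((su$center - fk$T_C[1:3, 4]) * su$normal) / denom
    if (is.finite(tt) && tt > 0) {
      h <- fk$T_C[1:3, 4] + tt * z_c
      tip_uv <- c(sum((h - su$center) * su$u), sum((h - su$center) * su$v))
    }
  }

  row <- data.frame(
    tick = loop$tick, time_s = loop$tick * dt,
    r1_deg = state$r1_deg, r2_deg = state$r2_deg,
    r1_target = loop$targets[1], r2_target = loop$targets[2],
    r1_cmd = ps$command[1], r2_cmd = ps$command[2],
    x_m = if (visible) measured[[1]] else NA_real_,
    y_m = if (visible) measured[[2]] else NA_real_,
    combined_error_deg = err_deg,
    tip_u_mm = tip_uv[1], tip_v_mm = tip_uv[2],
    surface_visible = visible)
  list(state = state, loop = loop, row = row)
}

#' Scripted landmark-visiting episode
#'
#' Replaces the human operator with scripted gross motion: the handle is
#' steered so that the shaft axis sweeps smoothly from landmark to landmark
#' on the placental surface, holding the tip at a 10-20 mm stand-off, with
#' optional seeded jitter emulating hand tremor. The distal tip behaves per
#' configuration: `"straight"` locks R2 at 0 (rigid straight scope),
#' `"fixed"` locks R2 at a constant curve (curved rigid scope),
#' `"autonomous"` closes the loop through the estimator.
#'
#' @param scene list with `surface`, `light`, `cfg` (see
#'   [closed_loop_step()]).
#' @param landmarks matrix of in-plane landmark coordinates (mm, one row
#'   per landmark, columns u and v), or NULL for a default letter grid
#'   spread over the surface.
#' @param config `"straight"`, `"fixed"` or `"autonomous"`.
#' @param estimator `"oracle"` or a `trained_model` (autonomous config).
#' @param fulcrum world position of the entry port.
#' @param kin a [tip_kinematics()].
#' @param gains a [pid_gains()].
#' @param fixed_r2_deg locked bending angle for the `"fixed"` config.
#' @param standoff_mm target tip-to-surface distance (within 10-20 mm).
#' @param travel_s,dwell_s seconds of travel between landmarks and of hold
#'   at each landmark.
#' @param jitter_sd_deg seeded angular jitter of the scripted shaft
#'   direction (0 disables).
#' @param seed seed for jitter and any oracle label noise.
#' @param label_noise_sd Gaussian noise on oracle labels.
#' @return A `trajectory_log` data frame (one row per tick at the loop
#'   rate) with the episode configuration attached as attributes.
#' @export
run_episode <- function(scene, landmarks = NULL,
                        config = c("autonomous", "straight", "fixed"),
                        estimator = "oracle",
                        fulcrum = c(0, 0, 0), kin = tip_kinematics(),
                        gains = pid_gains(), fixed_r2_deg = 30,
                        standoff_mm = 15, travel_s = 1.0, dwell_s = 0.75,
                        jitter_sd_deg = 0, seed = 1L, label_noise_sd = 0) {
  config <- match.arg(config)
  su <- scene$surface
  if (is.null(landmarks)) {
    g <- su$extent_mm * 0.3
    landmarks <- as.matrix(expand.grid(u = c(-g, 0, g), v = c(-g, 0, g)))
  }
  if (nrow(landmarks) < 1) stop("landmark list is empty")
  targets_w <- t(apply(landmarks, 1, function(lm)
    su$center + lm[1] * su$u + lm[2] * su$v))

  dt <- 1 / gains$rate_hz
  n_travel <- max(1L, round(travel_s / dt))
  n_dwell <- max(1L, round(dwell_s / dt))

  # scripted shaft directions: from the fulcrum towards each landmark
  dirs <- t(apply(targets_w, 1, function(p) normalize_vec(p - fulcrum)))
  # per-tick scripted direction: slerp between successive landmark aims
  script <- list()
  for (k in seq_len(nrow(dirs))) {
    from <- if (k == 1) dirs[1, ] else dirs[k - 1, ]
    to <- dirs[k, ]
    if (k > 1) {
      for (s in seq_len(n_travel)) {
        f <- s / n_travel
        script[[length(script) + 1]] <- list(dir = slerp(from, to, f), lm = k)
      }
    }
    for (s in seq_len(n_dwell)) {
      script[[length(script) + 1]] <- list(dir = to, lm = k)
    }
  }

  jit <- if (jitter_sd_deg > 0) {
    with_preserved_seed(seed, matrix(rnorm(2 * length(script), 0,
                                           deg2rad(jitter_sd_deg)),
                                     ncol = 2))
  } else matrix(0, length(script), 2)

  r2_init <- switch(config, straight = 0, fixed = fixed_r2_deg, autonomous = 0)
  state <- instrument_state(shaft_dir = dirs[1, ], insertion_mm = 1,
                            r1_deg = 0, r2_deg = r2_init,
                            fulcrum = fulcrum, kin = kin)
  if (config == "autonomous") {
    # the episode starts with the tip already deployed and aligned on the
    # first landmark (the instrument is steered into position before the
    # task begins); the log measures task performance, not deployment
    hit1 <- ray_plane_distance(fulcrum, dirs[1, ], su)
    state$insertion_mm <- max(5, hit1 - standoff_mm - kin$segment_length_mm)
    # settle alignment and stand-off jointly before the task begins
    for (it in 1:40) {
      fk1 <- forward_kinematics(state)
      lab1 <- tryCatch(label_from_scene(fk1$T_C, su$normal),
                       error = function(e) NULL)
      if (!is.null(lab1)) {
        ik1 <- inverse_kinematics(lab1, state)
        state$r1_deg <- ik1$r1_deg
        state$r2_deg <- ik1$r2_deg
      }
      d1 <- ray_plane_distance(fk1$T_C[1:3, 4], fk1$T_C[1:3, 3], su)
      if (is.finite(d1)) {
        state$insertion_mm <- min(max(5, state$insertion_mm +
                                        min(1, max(-1, 0.4 * (d1 - standoff_mm)))),
                                  max(5, hit1 - 5))
      }
    }
  }
  loop <- NULL
  rows <- vector("list", length(script))
  noise_seq <- if (label_noise_sd > 0) {
    with_preserved_seed(seed + 1L, matrix(rnorm(2 * length(script), 0,
                                                label_noise_sd), ncol = 2))
  }
  for (i in seq_along(script)) {
    dir_i <- script[[i]]$dir
    if (jitter_sd_deg > 0) {
      dir_i <- normalize_vec(dir_i + jit[i, 1] * orthonormal_of(dir_i)$a +
                               jit[i, 2] * orthonormal_of(dir_i)$b)
    }
    state$shaft_dir <- dir_i
    hit <- ray_plane_distance(fulcrum, dir_i, su)
    if (config == "straight") {
      # camera axis is the shaft axis: the stand-off is exact analytically
      state$insertion_mm <- max(5, hit - standoff_mm -
                                  state$kin$segment_length_mm)
    } else {
      # bent tip: the camera looks off-shaft, so maintain the scripted
      # 10-20 mm stand-off on the actual camera-to-surface distance (the
      # operator does this visually); rate-limited insertion adjustments
      fk_now <- forward_kinematics(state)
      d_cam <- ray_plane_distance(fk_now$T_C[1:3, 4], fk_now$T_C[1:3, 3], su)
      if (is.finite(d_cam)) {
        adj <- min(1, max(-1, 0.4 * (d_cam - standoff_mm)))
        state$insertion_mm <- min(max(5, state$insertion_mm + adj),
                                  max(5, hit - 5))
      }
    }

    if (config == "autonomous") {
      noise_i <- 0
      if (!is.null(noise_seq)) {
        # per-tick noise drawn from a pre-generated seeded stream
        noise_i <- noise_seq[i, ]
      }
      step <- closed_loop_step_with_noise(scene, state, estimator, gains,
                                          loop, noise_i)
      state <- step$state; loop <- step$loop
      rows[[i]] <- cbind(step$row, landmark = script[[i]]$lm)
    } else {
      fk <- forward_kinematics(state)
      err <- combined_error(fk$T_C[1:3, 3], -su$normal)
      tip_uv <- tip_projection(fk, su)
      rows[[i]] <- data.frame(
        tick = i, time_s = i * dt, r1_deg = state$r1_deg,
        r2_deg = state$r2_deg, r1_target = state$r1_deg,
        r2_target = state$r2_deg, r1_cmd = 0, r2_cmd = 0,
        x_m = NA_real_, y_m = NA_real_, combined_error_deg = err,
        tip_u_mm = tip_uv[1], tip_v_mm = tip_uv[2],
        surface_visible = TRUE, landmark = script[[i]]$lm)
    }
  }
  log <- do.call(rbind, rows)
  log$tick <- seq_len(nrow(log))
  log$time_s <- log$tick * dt
  attr(log, "config") <- config
  attr(log, "rate_hz") <- gains$rate_hz
  attr(log, "seed") <- seed
  class(log) <- c("trajectory_log", class(log))
  log
}

closed_loop_step_with_noise <- function(scene, state, estimator, gains,
                                        loop, noise_i) {
  if (identical(estimator, "oracle") && any(noise_i != 0)) {
    # inject pre-drawn noise by temporarily perturbing the oracle label:
    # re-implemented inline to keep closed_loop_step deterministic
    step <- closed_loop_step(scene, state, "oracle", gains, loop,
                             label_noise_sd = 0)
    # recompute controller action with the noisy measurement
    if (!is.na(step$row$x_m)) {
      noisy <- clamp_label(c(step$row$x_m, step$row$y_m) + noise_i)
      ik <- inverse_kinematics(noisy, state)
      step$loop$targets <- c(ik$r1_deg, ik$r2_deg)
      step$row$x_m <- noisy[[1]]; step$row$y_m <- noisy[[2]]
    }
    return(step)
  }
  closed_loop_step(scene, state, estimator, gains, loop)
}

tip_projection <- function(fk, su) {
  z_c <- fk$T_C[1:3, 3]
  denom <- sum(z_c * su$normal)
  if (abs(denom) < 1e-9) return(c(NA_real_, NA_real_))
  tt <- sum((su$center - fk$T_C[1:3, 4]) * su$normal) / denom
  if (!is.finite(tt) || tt <= 0) return(c(NA_real_, NA_real_))
  h <- fk$T_C[1:3, 4] + tt * z_c
  c(sum((h - su$center) * su$u), sum((h - su$center) * su$v))
}

ray_plane_distance <- function(origin, dir, su) {
  denom <- sum(dir * su$normal)
  if (abs(denom) < 1e-9) return(Inf)
  tt <- sum((su$center - origin) * su$normal) / denom
  if (tt <= 0) Inf else tt
}

orthonormal_of <- function(z) {
  a <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- normalize_vec(a - sum(a * z) * z)
  v <- c(z[2] * u[3] - z[3] * u[2],
         z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  list(a = u, b = v)
}

#' A 45-degree placental scene for control experiments
#'
#' The placenta plane is placed at 45 degrees with respect to the entry
#' axis (+z from the fulcrum at the origin), at a working depth typical of
#' fetoscopy.
#'
#' @param texture surface texture (default procedural, seed 1).
#' @param depth_mm distance from the fulcrum to the plane center along +z.
#' @param extent_mm textured patch side.
#' @param resolution_px render resolution for model-in-the-loop runs.
#' @return List with `surface`, `light`, `cfg` as used by [run_episode()].
#' @export
tilted_scene <- function(texture = NULL, depth_mm = 60, extent_mm = 80,
                         resolution_px = 200L) {
  if (is.null(texture)) texture <- generate_texture(1L, 512L)
  normal <- normalize_vec(c(0, sin(pi / 4), -cos(pi / 4)))  # 45 deg to +z
  surface <- placenta_surface(texture, extent_mm = extent_mm,
                              center = c(0, 0, depth_mm),
                              normal_into_cavity = normal)
  list(surface = surface, light = light_model(),
       cfg = render_config(resolution = resolution_px))
}

slerp <- function(a, b, f) {
  d <- min(1, max(-1, sum(a * b)))
  th <- acos(d)
  if (th < 1e-9) return(a)
  (sin((1 - f) * th) * a + sin(f * th) * b) / sin(th)
}
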
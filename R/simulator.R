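# Episode execution on the planar walker: state initialisation from the
# reference, control-rate stepping of the C++ core, fall and heel-strike
# detection, and full trajectory logging.

#' Assemble a simulator state vector
#'
#' State layout: generalized coordinates q, velocities, per-muscle
#' activations, per-muscle fiber lengths, time. Fiber lengths initialise at
#' the optimal fiber length and fiber velocities at zero.
#'
#' @param model a `walker_model`.
#' @param ref optional `reference_motion`; when given, q and velocities are
#'   taken from the reference at `phase`.
#' @param phase initial gait phase in `[0, 1)`.
#' @param activations initial per-muscle activations (scalar recycled).
#' @param fiber `"equilibrium"` (default) solves each fiber to quasi-static
#'   equilibrium at the initial pose, avoiding force transients;
#'   `"optimal"` starts every fiber at its optimal length (in the standing
#'   pose the two coincide by construction of the bundled model).
#' @return numeric state vector.
#' @export
sim_state_init <- function(model, ref = NULL, phase = 0, activations = 0.02,
                           fiber = c("equilibrium", "optimal"),
                           q = NULL, qd = NULL) {
  fiber <- match.arg(fiber)
  nj <- length(joint_names(model))
  nm <- length(model$muscles)
  if (is.null(q)) {
    if (is.null(ref)) {
      q <- default_q(model)
      qd <- numeric(3 + nj)
    } else {
      fr <- ref_lookup(ref, phase * ref$cycle_duration)
      q <- c(0, fr$base[2], fr$base[3], fr$theta)
      qd <- c(fr$base_dot[1], fr$base_dot[2], fr$base_dot[3], fr$theta_dot)
    }
  } else if (is.null(qd)) qd <- numeric(3 + nj)
  if (length(activations) == 1) activations <- rep(activations, nm)
  activations <- pmin(1, pmax(0, activations))
  lfib <- if (fiber == "optimal") {
    vapply(model$muscles, function(m) m$params$l_opt, numeric(1))
  } else {
    core <- model_core(model)
    L <- cpp_muscle_geometry(core, unname(as.numeric(q)))$L
    cc <- model$options$curve_constants
    vapply(seq_len(nm), function(i)
      solve_mtu_equilibrium(model$muscles[[i]]$params, L[i], 0,
                            activations[i], cc,
                            name = names(model$muscles)[i])$fiber_length,
      numeric(1))
  }
  unname(c(q, qd, activations, lfib, 0))
}

state_parts <- function(model, state) {
  nd <- 3 + length(joint_names(model))
  nm <- length(model$muscles)
  state <- unname(state)
  list(q = state[1:nd], qd = state[nd + 1:nd],
       act = state[2 * nd + 1:nm], lfib = state[2 * nd + nm + 1:nm],
       t = state[2 * nd + 2 * nm + 1])
}

#' Advance the simulation by one control step
#'
#' Integrates `n_substeps` physics substeps of size `dt` under constant
#' muscle excitations: activation dynamics, fiber-tendon dynamics, muscle
#' joint torques, ground contact and semi-implicit Euler integration of the
#' rigid-body tree.
#'
#' @param core flattened model (from the internal model builder) or a
#'   `walker_model`.
#' @param terrain a `walker_terrain` or its flattened form.
#' @param state state vector from [sim_state_init()] or a previous step.
#' @param excitations per-muscle excitations; values outside `[0, 1]` are
#'   clipped (count returned as attribute `clipped`).
#' @param n_substeps physics substeps per control step (default 10, i.e.
#'   100 Hz control over a 1 kHz physics step).
#' @param dt physics substep (s, default 1/1000).
#' @return list: new `state`, per-foot ground reaction forces `grf_r` /
#'   `grf_l` (tangential, normal), per-foot centre of pressure x `cop_x`,
#'   calcaneus-sphere vertical forces `heel_fz`, `com`, `comv`, end-effector
#'   positions `eff`, per-muscle `mtu_force`, per-sphere contact log
#'   `spheres`, and `clipped`.
#' @export
sim_step <- function(core, terrain, state, excitations, n_substeps = 10,
                     dt = 1e-3) {
  if (inherits(core, "walker_model")) core <- model_core(core)
  if (inherits(terrain, "walker_terrain")) terrain <- terrain_core(terrain)
  clipped <- sum(excitations < 0 | excitations > 1)
  u <- pmin(1, pmax(0, excitations))
  out <- cpp_step(core, terrain, state, u, as.integer(n_substeps), dt)
  out$clipped <- clipped
  out
}

#' Per-sphere contact forces at a state
#'
#' Evaluates the penalty contact model without integrating: normal force
#' (zero without penetration), regularised Coulomb friction (capped at
#' mu * N), contact point and penetration per sphere, plus the force-weighted
#' centre of pressure per foot.
#'
#' @param state simulator state vector.
#' @param terrain a `walker_terrain`.
#' @param model a `walker_model`.
#' @return list with `spheres` (data frame) and `cop` (per-foot COP x, `NA`
#'   when the foot is unloaded).
#' @export
contact_forces <- function(state, terrain, model) {
  core <- model_core(model)
  p <- state_parts(model, state)
  m <- cpp_contact(core, terrain_core(terrain), p$q, p$qd)
  cs <- model$contact_spheres
  df <- data.frame(segment = cs$segment, foot = cs$foot, heel = cs$heel,
                   normal = m[, 1], friction = m[, 2],
                   contact_x = m[, 3], contact_y = m[, 4],
                   penetration = m[, 5], mu = m[, 6],
                   stringsAsFactors = FALSE)
  cop <- vapply(c(right = "right", left = "left"), function(f) {
    sel <- df$foot == f & df$normal > 0
    if (!any(sel)) return(NA_real_)
    sum(df$contact_x[sel] * df$normal[sel]) / sum(df$normal[sel])
  }, numeric(1))
  list(spheres = df, cop = cop)
}

#' Observation vector of the walker state
#'
#' Planar reduction of the full-body dynamic state: pelvis height, trunk
#' pitch, base and pitch velocities, joint angles and velocities, per-foot
#' ground reaction force (normalised by body weight) and centre of pressure
#' relative to the pelvis (exactly zero without contact), and the gait phase
#' encoded as sine/cosine. The layout is versioned via
#' [observation_layout()]; absolute forward position is excluded so the
#' observation is invariant to forward translation.
#'
#' @param model a `walker_model`.
#' @param terrain a `walker_terrain` (for contact forces).
#' @param state simulator state.
#' @param phase gait phase in `[0, 1)`.
#' @param contact optional precomputed grf/cop list (from a step output) with
#'   `grf_r`, `grf_l`, `cop_x` to avoid recomputing contact.
#' @return named numeric observation vector.
#' @export
build_observation <- function(model, terrain, state, phase = 0,
                              contact = NULL) {
  p <- state_parts(model, state)
  if (any(!is.finite(state))) stop("non-finite simulator state")
  W <- sum(model$segments$mass) * model$options$gravity
  if (is.null(contact)) {
    cf <- contact_forces(state, terrain, model)
    s <- cf$spheres
    grf_r <- c(sum(s$friction[s$foot == "right"]), sum(s$normal[s$foot == "right"]))
    grf_l <- c(sum(s$friction[s$foot == "left"]), sum(s$normal[s$foot == "left"]))
    cop <- cf$cop
  } else {
    grf_r <- contact$grf_r; grf_l <- contact$grf_l
    cop <- c(right = if (contact$grf_r[2] > 0) contact$cop_x[1] else NA,
             left = if (contact$grf_l[2] > 0) contact$cop_x[2] else NA)
  }
  copdx <- ifelse(is.na(cop), 0, cop - p$q[1])
  nj <- length(joint_names(model))
  obs <- c(pelvis_h = p$q[2], pitch = p$q[3],
           vx = p$qd[1], vy = p$qd[2], pitch_rate = p$qd[3],
           setNames(p$q[3 + 1:nj], paste0("ang_", joint_names(model))),
           setNames(p$qd[3 + 1:nj], paste0("vel_", joint_names(model))),
           grf_r_x = grf_r[1] / W, grf_r_y = grf_r[2] / W,
           cop_dx_r = unname(copdx[1]),
           grf_l_x = grf_l[1] / W, grf_l_y = grf_l[2] / W,
           cop_dx_l = unname(copdx[2]),
           phase_sin = sin(2 * pi * phase), phase_cos = cos(2 * pi * phase))
  obs
}

#' Observation layout descriptor
#' @param model a `walker_model`.
#' @return list with `version`, `names`, `length`.
#' @export
observation_layout <- function(model) {
  nms <- names(build_observation(model, make_terrain("flat"),
                                 sim_state_init(model), 0))
  list(version = 1L, names = nms, length = length(nms))
}

#' Run one walking episode
#'
#' Steps the walker under a policy at 100 Hz control over 1 kHz physics until
#' the duration elapses or a fall is detected (pelvis below 60 % of standing
#' height or trunk pitch beyond 60 degrees). Heel strikes are detected from
#' the calcaneus-sphere vertical force rising through 5 % body weight with a
#' 100 ms refractory period per foot.
#'
#' @param policy an object with a [policy_action()] method (or a plain
#'   function of the observation returning excitations).
#' @param model a `walker_model`.
#' @param terrain a `walker_terrain`.
#' @param ref a `reference_motion` (initial state and phase bookkeeping).
#' @param duration trial length (s, default 20).
#' @param seed integer seed (stochastic policies and random initial phase).
#' @param init_phase `"random"` or a phase in `[0, 1)`.
#' @param init_state optional explicit initial state vector overriding the
#'   reference-based initialisation (e.g. a standing pose).
#' @param stochastic logical, sample exploration noise from the policy.
#' @param control_hz control frequency (default 100).
#' @param dt physics substep (s).
#' @param record logical, keep full trajectories.
#' @return object of class `episode_record`.
#' @export
simulate_episode <- function(policy, model, terrain, ref, duration = 20,
                             seed = NULL, init_phase = 0, stochastic = FALSE,
                             control_hz = 100, dt = 1e-3, record = TRUE,
                             init_state = NULL) {
  core <- model_core(model)
  tcore <- terrain_core(terrain)
  nj <- length(joint_names(model))
  nm <- length(model$muscles)
  n_sub <- round(1 / (control_hz * dt))
  n_tick <- round(duration * control_hz)
  W <- sum(model$segments$mass) * model$options$gravity
  standing <- model$standing_height

  run <- function() {
    phase0 <- if (identical(init_phase, "random")) runif(1) else init_phase
    state <- if (is.null(init_state)) sim_state_init(model, ref, phase0) else
      init_state
    # initial activations from the policy, as in controller-driven resets
    obs0 <- build_observation(model, terrain, state, phase0)
    u <- policy_action(policy, obs0, stochastic = stochastic)
    np <- state_parts(model, state)
    state[2 * (3 + nj) + 1:nm] <- pmin(1, pmax(0, u))

    logs <- if (record) list(
      q = matrix(NA_real_, n_tick, 3 + nj), qd = matrix(NA_real_, n_tick, 3 + nj),
      act = matrix(NA_real_, n_tick, nm), exc = matrix(NA_real_, n_tick, nm),
      grf = matrix(NA_real_, n_tick, 4), cop = matrix(NA_real_, n_tick, 2),
      heel = matrix(NA_real_, n_tick, 2), com = matrix(NA_real_, n_tick, 2)) else NULL
    events <- data.frame(time = numeric(0), foot = character(0),
                         com_x = numeric(0), cop_x = numeric(0),
                         foot_angle_deg = numeric(0))
    last_strike <- c(right = -Inf, left = -Inf)
    prev_heel <- c(0, 0)
    fell <- FALSE; fall_time <- NA_real_; clipped <- 0L
    out <- NULL
    for (k in seq_len(n_tick)) {
      t_k <- (k - 1) / control_hz
      phase <- (phase0 + t_k / ref$cycle_duration) %% 1
      obs <- if (k == 1) obs0 else
        build_observation(model, terrain, state, phase,
                          contact = list(grf_r = out$grf_r, grf_l = out$grf_l,
                                         cop_x = out$cop_x))
      u <- policy_action(policy, obs, stochastic = stochastic)
      out <- sim_step(core, tcore, state, u, n_sub, dt)
      state <- out$state
      clipped <- clipped + out$clipped
      p_q <- state[1:(3 + nj)]
      t_now <- k / control_hz
      # heel strikes: rising edge of calcaneus vertical force through 5% BW
      for (f in 1:2) {
        fz <- out$heel_fz[f]
        nm_f <- c("right", "left")[f]
        if (fz > 0.05 * W && prev_heel[f] <= 0.05 * W &&
            t_now - last_strike[nm_f] > 0.1) {
          last_strike[nm_f] <- t_now
          w_foot <- foot_world_angle(model, p_q, nm_f)
          events <- rbind(events, data.frame(
            time = t_now, foot = nm_f, com_x = out$com[1],
            cop_x = out$cop_x[f], foot_angle_deg = w_foot * 180 / pi))
        }
        prev_heel[f] <- fz
      }
      if (record) {
        logs$q[k, ] <- p_q
        logs$qd[k, ] <- state[(3 + nj) + 1:(3 + nj)]
        logs$act[k, ] <- state[2 * (3 + nj) + 1:nm]
        logs$exc[k, ] <- pmin(1, pmax(0, u))
        logs$grf[k, ] <- c(out$grf_r, out$grf_l)
        logs$cop[k, ] <- out$cop_x
        logs$heel[k, ] <- out$heel_fz
        logs$com[k, ] <- out$com
      }
      if (p_q[2] < 0.6 * standing || abs(p_q[3]) > pi / 3) {
        fell <- TRUE; fall_time <- t_now
        if (record) logs <- lapply(logs, function(m) m[seq_len(k), , drop = FALSE])
        break
      }
    }
    n_done <- if (fell) round(fall_time * control_hz) else n_tick
    rec <- list(time = (seq_len(n_done)) / control_hz,
                fell = fell, fall_time = fall_time,
                survived = !fell, duration = duration,
                heel_strikes = events, clipped = clipped,
                phase0 = phase0, control_hz = control_hz,
                final_x = state[1])
    if (record) {
      colnames(logs$q) <- c("base_x", "base_y", "pitch", joint_names(model))
      colnames(logs$act) <- colnames(logs$exc) <- names(model$muscles)
      rec <- c(rec, logs)
    }
    structure(rec, class = "episode_record")
  }
  if (is.null(seed)) run() else with_seed(seed, run)
}

# World angle of a foot segment (rad; positive = toes above heel).
foot_world_angle <- function(model, q, foot = c("right", "left")) {
  foot <- match.arg(foot)
  jn <- joint_names(model)
  idx <- if (foot == "right") match(c("hip_r", "knee_r", "ankle_r"), jn)
  else match(c("hip_l", "knee_l", "ankle_l"), jn)
  sg <- model$joints$sign[model$joints$type == "revolute"][idx]
  q[3] + sum(sg * q[3 + idx])
}

#' Activation and joint-angle tables of an episode
#'
#' Converts a recorded episode to the columnar tables the analysis functions
#' consume.
#'
#' @param episode an `episode_record` (recorded).
#' @return list with `motion` (time + joint angles, rad) and `activations`
#'   (time + per-muscle activation).
#' @export
episode_tables <- function(episode) {
  if (is.null(episode$q)) stop("episode was not recorded")
  jn <- setdiff(colnames(episode$q), c("base_x", "base_y", "pitch"))
  list(motion = data.frame(time = episode$time,
                           episode$q[, jn, drop = FALSE]),
       activations = data.frame(time = episode$time, episode$act))
}
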
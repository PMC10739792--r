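# Gait controllers: a Gaussian multilayer-perceptron policy (the trainable
# controller) and scripted policies used as fixtures (constant excitation and
# a reference-tracking muscle PD controller).

#' Policy network specification
#'
#' @param n_obs observation length.
#' @param n_act number of muscles (output length).
#' @param hidden hidden layer sizes (default desk-scale 64/32; the full-scale
#'   counterpart would be 512/256).
#' @return list of class `policy_spec`.
#' @export
policy_spec <- function(n_obs, n_act, hidden = c(64, 32)) {
  if (any(hidden < 1) || n_obs < 1 || n_act < 1) stop("invalid layer sizes")
  structure(list(n_obs = n_obs, n_act = n_act, hidden = hidden),
            class = "policy_spec")
}

mlp_init <- function(sizes, seed = NULL, out_scale = 0.01) {
  with_seed(seed, function() {
    L <- list()
    for (i in seq_len(length(sizes) - 1)) {
      fan_in <- sizes[i]
      sc <- if (i == length(sizes) - 1) out_scale else sqrt(2 / fan_in)
      L[[i]] <- list(W = matrix(rnorm(fan_in * sizes[i + 1], 0, sc), fan_in),
                     b = numeric(sizes[i + 1]))
    }
    L
  })
}

mlp_forward <- function(layers, X) {
  X <- if (is.matrix(X)) X else matrix(X, 1)
  acts <- list(X)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- acts[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2, layers[[i]]$b, "+")
    acts[[i + 1]] <- if (i < nl) tanh(Z) else Z
  }
  list(out = acts[[nl + 1]], acts = acts)
}

# Backpropagate dL/d(out) through the MLP; returns per-layer gradients and
# (optionally unused) input gradient.
mlp_backward <- function(layers, fw, d_out) {
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- d_out
  for (i in nl:1) {
    A <- fw$acts[[i]]
    grads[[i]] <- list(W = crossprod(A, delta), b = colSums(delta))
    if (i > 1) {
      delta <- delta %*% t(layers[[i]]$W)
      delta <- delta * (1 - fw$acts[[i]]^2)
    }
  }
  grads
}

#' Create a Gaussian MLP gait controller
#'
#' Two tanh hidden layers; the mean head is squashed to `[0, 1]` with a
#' logistic, exploration is Gaussian in the squashed space with a learnable
#' state-independent log standard deviation.
#'
#' @param spec a [policy_spec()].
#' @param seed integer seed for weight initialisation.
#' @param obs_center,obs_scale optional fixed observation standardisation
#'   applied before the network (defaults: identity).
#' @return object of class `walker_policy`.
#' @export
mlp_policy <- function(spec, seed = NULL, obs_center = NULL, obs_scale = NULL) {
  sizes <- c(spec$n_obs, spec$hidden, spec$n_act)
  net <- mlp_init(sizes, seed)
  # start near-quiet: mean excitation ~0.1 rather than 0.5
  net[[length(net)]]$b <- rep(-2.2, spec$n_act)
  structure(list(spec = spec,
                 net = net,
                 value = mlp_init(c(spec$n_obs, spec$hidden, 1),
                                  if (is.null(seed)) NULL else seed + 1,
                                  out_scale = 0.1),
                 log_std = rep(-1.6, spec$n_act),
                 obs_center = obs_center %||% numeric(spec$n_obs),
                 obs_scale = obs_scale %||% rep(1, spec$n_obs),
                 obs_names = NULL),
            class = "walker_policy")
}

# Fixed observation standardisation for the walker layout: typical centre and
# spread of each observation block (pelvis height, angles, velocities,
# body-weight-normalised GRF, phase encoding).
walker_obs_norm <- function(model) {
  nms <- observation_layout(model)$names
  center <- setNames(numeric(length(nms)), nms)
  scale <- setNames(rep(1, length(nms)), nms)
  center["pelvis_h"] <- 0.9
  scale["pelvis_h"] <- 0.1
  scale[grepl("^(vx|vy|pitch_rate)$", nms)] <- 2
  scale[grepl("^ang_", nms)] <- 0.5
  scale[grepl("^vel_", nms)] <- 5
  center["vx"] <- 1.3
  list(center = unname(center), scale = unname(scale))
}

policy_mean <- function(policy, obs_mat) {
  X <- sweep(sweep(obs_mat, 2, policy$obs_center), 2, policy$obs_scale, "/")
  fw <- mlp_forward(policy$net, X)
  list(mean = 1 / (1 + exp(-fw$out)), fw = fw)
}

policy_value <- function(policy, obs_mat) {
  X <- sweep(sweep(obs_mat, 2, policy$obs_center), 2, policy$obs_scale, "/")
  mlp_forward(policy$value, X)
}

#' Evaluate a policy
#'
#' Deterministic mode is a pure function of the observation; stochastic mode
#' adds Gaussian exploration noise (seed the caller's RNG or pass `seed`),
#' with the result clipped to `[0, 1]` by the simulator boundary.
#'
#' @param policy a policy object.
#' @param obs observation vector (layout must match the policy's input size).
#' @param stochastic logical.
#' @param seed optional integer seed for the noise draw.
#' @param ... method-specific arguments.
#' @return excitation vector.
#' @export
policy_action <- function(policy, obs, stochastic = FALSE, seed = NULL, ...) {
  UseMethod("policy_action")
}

#' @export
policy_action.walker_policy <- function(policy, obs, stochastic = FALSE,
                                        seed = NULL, ...) {
  if (length(obs) != policy$spec$n_obs)
    stop("observation length ", length(obs), " does not match policy input ",
         policy$spec$n_obs)
  mu <- policy_mean(policy, matrix(obs, 1))$mean[1, ]
  if (!stochastic) return(mu)
  draw <- function() mu + exp(policy$log_std) * rnorm(length(mu))
  if (is.null(seed)) draw() else with_seed(seed, draw)
}

#' @export
policy_action.function <- function(policy, obs, stochastic = FALSE,
                                   seed = NULL, ...) {
  policy(obs)
}

#' Constant-excitation policy
#' @param u scalar or per-muscle excitation.
#' @param n number of muscles (needed when `u` is scalar).
#' @return policy object.
#' @export
constant_policy <- function(u = 0, n = 18) {
  structure(list(u = if (length(u) > 1) u else rep(u, n)),
            class = "constant_policy")
}

#' @export
policy_action.constant_policy <- function(policy, obs, ...) {
  policy$u
}

#' Reference-tracking muscle PD controller
#'
#' A scripted, non-learned controller used as a reproducible walking fixture:
#' per-joint PD torques toward the reference angles (plus a trunk-righting
#' term blended into the stance hip) are distributed over the muscles in
#' proportion to their moment arm and strength, with an optional tonic
#' co-excitation floor.
#'
#' @param model a `walker_model`.
#' @param ref a `reference_motion`.
#' @param kp,kd per-joint PD gains (Nm/rad, Nm s/rad; scalars recycled).
#' @param trunk_kp,trunk_kd trunk-righting gains.
#' @param co tonic co-excitation added to every muscle.
#' @param gain torque-to-excitation scale.
#' @param fp_gain Raibert-style foot-placement gain: the swing hip target is
#'   shifted by `fp_gain * (vx - v_ref)` to capture forward-speed errors.
#' @return policy object of class `tracking_policy`.
#' @export
tracking_policy <- function(model, ref, kp = c(220, 260, 180), kd = c(14, 16, 10),
                            trunk_kp = 420, trunk_kd = 60, co = 0.02,
                            gain = 1.0, fp_gain = 0.25) {
  core <- model_core(model)
  q0 <- default_q(model)
  geo <- cpp_muscle_geometry(core, q0)
  F0 <- vapply(model$muscles, function(m) m$params$F0, numeric(1))
  if (length(kp) == 3) kp <- rep(kp, 2)
  if (length(kd) == 3) kd <- rep(kd, 2)
  structure(list(model = model, core = core, ref = ref, kp = kp, kd = kd,
                 trunk_kp = trunk_kp, trunk_kd = trunk_kd, co = co,
                 gain = gain, fp_gain = fp_gain, F0 = F0),
            class = "tracking_policy")
}

#' @export
policy_action.tracking_policy <- function(policy, obs, ...) {
  m <- policy$model
  jn <- joint_names(m)
  nj <- length(jn)
  phase <- atan2(obs[["phase_sin"]], obs[["phase_cos"]]) / (2 * pi)
  phase <- phase %% 1
  fr <- ref_lookup(policy$ref, phase * policy$ref$cycle_duration)
  ang <- obs[paste0("ang_", jn)]
  vel <- obs[paste0("vel_", jn)]
  theta_des <- fr$theta
  # foot placement: shift the swing hip target with the forward-speed error
  wr0 <- obs[["grf_r_y"]]; wl0 <- obs[["grf_l_y"]]
  dv <- obs[["vx"]] - policy$ref$speed
  swing <- if (wr0 < wl0) "hip_r" else "hip_l"
  theta_des[match(swing, jn)] <- theta_des[match(swing, jn)] +
    policy$fp_gain * dv
  tau <- policy$kp * (theta_des - ang) + policy$kd * (fr$theta_dot - vel)
  # trunk righting through the hips, weighted by each leg's vertical load
  tau_trunk <- policy$trunk_kp * (fr$base[3] - obs[["pitch"]]) -
    policy$trunk_kd * obs[["pitch_rate"]]
  wr <- obs[["grf_r_y"]]; wl <- obs[["grf_l_y"]]
  tot <- wr + wl
  if (tot > 1e-6) {
    tau[match("hip_r", jn)] <- tau[match("hip_r", jn)] - tau_trunk * wr / tot
    tau[match("hip_l", jn)] <- tau[match("hip_l", jn)] - tau_trunk * wl / tot
  }
  # distribute joint torques over muscles: muscle torque per unit excitation
  # is approximately -r * F0; agonists of each desired torque share the load
  q_now <- c(0, obs[["pelvis_h"]], obs[["pitch"]], ang)
  R <- cpp_muscle_geometry(policy$core, q_now)$R
  cap <- -R * policy$F0  # nm x nj: torque each muscle can add per excitation
  u <- rep(policy$co, length(policy$F0))
  for (j in seq_len(nj)) {
    ag <- which(cap[, j] * tau[j] > 0)
    if (!length(ag)) next
    u[ag] <- u[ag] +
      policy$gain * abs(tau[j]) * abs(cap[ag, j]) / sum(cap[ag, j]^2)
  }
  pmin(1, pmax(0, u))
}

#' Static-optimization muscle tonus for a posture
#'
#' Solves for constant excitations whose joint torques cancel the
#' gravitational joint torques at a given pose: a projected-gradient least
#' squares on the linearised torque capacity of each muscle (active
#' force-length scaling at the equilibrium fiber length), with passive muscle
#' torques subtracted, bounded between the co-contraction floor `co` and
#' `a_max`. The floor sets the co-contraction level and hence the posture's
#' intrinsic joint stiffness.
#'
#' @param model a `walker_model`.
#' @param q full generalized coordinates of the posture.
#' @param co co-contraction floor (minimum excitation).
#' @param bias extra per-joint torque demand (Nm, model joint order), e.g. to
#'   press the knees into their hyperextension stops while standing.
#' @param a_max upper excitation bound.
#' @return list with `u` (per-muscle excitations) and `residual` (unmet
#'   torque per joint, Nm).
#' @export
static_tonus <- function(model, q, co = 0.1, bias = NULL, a_max = 0.9) {
  core <- model_core(model)
  q <- full_coords(model, q)
  nj <- length(joint_names(model))
  if (is.null(bias)) bias <- numeric(nj)
  sol <- solve_all_mtus(model, q, rep(0, length(model$muscles)), core)
  Fp <- vapply(sol$mtus, `[[`, numeric(1), "force")
  R <- sol$geom$R
  tau_pass <- -as.numeric(t(R) %*% Fp)
  F0 <- vapply(model$muscles, function(m) m$params$F0, numeric(1))
  flA <- vapply(seq_along(model$muscles), function(i)
    evaluate_curves("active_fl",
                    sol$mtus[[i]]$fiber_length / model$muscles[[i]]$params$l_opt,
                    model$options$curve_constants), numeric(1))
  cap <- -R * (F0 * flA)
  tau_req <- gravity_joint_torques(model, q) - tau_pass + bias
  u <- rep(co, length(F0))
  for (it in 1:200) {
    resid <- tau_req - as.numeric(t(cap) %*% u)
    du <- cap %*% solve(crossprod(cap) + diag(1e-4, nj), resid)
    u <- pmin(a_max, pmax(co, u + 0.3 * as.numeric(du)))
  }
  list(u = u, residual = tau_req - as.numeric(t(cap) %*% u))
}

#' Gravitational joint torques at a pose
#'
#' The torque each revolute joint must produce to cancel gravity, computed
#' from the gradient of the whole-body potential energy with respect to the
#' joint angles.
#'
#' @param model a `walker_model`.
#' @param q full generalized coordinates.
#' @return numeric vector, Nm, in model joint order.
#' @export
gravity_joint_torques <- function(model, q) {
  core <- model_core(model)
  q <- full_coords(model, q)
  Mg <- sum(model$segments$mass) * model$options$gravity
  nj <- length(joint_names(model))
  vapply(seq_len(nj), function(j) {
    h <- 1e-6
    qp <- q; qp[3 + j] <- q[3 + j] + h
    qm <- q; qm[3 + j] <- q[3 + j] - h
    zero <- numeric(length(q))
    (cpp_com(core, qp, zero)$com[2] - cpp_com(core, qm, zero)$com[2]) /
      (2 * h) * Mg
  }, numeric(1))
}

#' Balanced standing posture and state for the planar walker
#'
#' Knees rest against their hyperextension stops (skeleton bears the load),
#' the trunk pitch is trimmed so the whole-body centre of mass sits a small
#' offset ahead of the ankles, and the pelvis height puts the foot spheres
#' just into contact.
#'
#' @param model a `walker_model`.
#' @param com_offset COM position ahead of the ankles (m).
#' @param ankle initial dorsiflexion (rad).
#' @return list with `q` (full coordinates) and `ankle_x` (world ankle x).
#' @export
standing_pose <- function(model, com_offset = 0.05, ankle = 0.03) {
  core <- model_core(model)
  q_ref <- c(0.04, 0, ankle, 0.04, 0, ankle)
  segmap <- setNames(seq_len(nrow(model$segments)) - 1L, model$segments$name)
  shank_len <- -model$joints$anchor_y[model$joints$name == "ankle_r"]
  ank_pt <- matrix(c(0, -shank_len), 2)
  f <- function(p0) {
    q0 <- c(0, 0.9, p0, q_ref)
    cpp_com(core, q0, numeric(9))$com[1] -
      cpp_points_world(core, q0, as.integer(segmap["shank_r"]), ank_pt)[1] -
      com_offset
  }
  p0 <- stats::uniroot(f, c(-0.5, 0.5))$root
  q0 <- c(0, 0, p0, q_ref)
  cs <- model$contact_spheres
  pts <- cpp_points_world(core, q0, as.integer(segmap[cs$segment]),
                          rbind(cs$x, cs$y))
  q0[2] <- -min(pts[2, ] - cs$radius) - 0.003
  list(q = q0,
       ankle_x = cpp_points_world(core, q0, as.integer(segmap["shank_r"]),
                                  ank_pt)[1])
}

#' Standing-balance fixture policy
#'
#' A scripted stance controller: static-optimization tonus (see
#' [static_tonus()]) holds the posture with the knees pressed against their
#' stops, and a low-pass-filtered COM-position/velocity feedback modulates
#' the plantarflexor/dorsiflexor excitations (ankle strategy). Established at
#' build time as the package's standing regression fixture: it keeps the
#' walker upright for at least two seconds.
#'
#' @param model a `walker_model`.
#' @param co co-contraction floor.
#' @param knee_bias knee extension-stop preload torque (Nm).
#' @param kp COM feedback gain (excitation per metre of COM error).
#' @param vel_weight COM-velocity weight in the error (s).
#' @param filt low-pass coefficient per control step in `(0, 1]`.
#' @return policy object of class `stand_policy`; its `init_state(model)`
#'   entry supplies the matching initial state.
#' @export
stand_policy <- function(model, co = 0.15, knee_bias = 20, kp = 5,
                         vel_weight = 0.25, filt = 0.4) {
  pose <- standing_pose(model, com_offset = 0.05)
  nj <- length(joint_names(model))
  tonus <- static_tonus(model, pose$q, co = co,
                        bias = -knee_bias * (joint_names(model) %in%
                                               c("knee_r", "knee_l")))
  core <- model_core(model)
  # hold the COM slightly ahead of the trim pose: the forward COP margin is
  # much larger than the backward one
  com0 <- cpp_com(core, pose$q, numeric(3 + nj))$com[1] - pose$q[1] + 0.02
  env <- new.env(parent = emptyenv())
  env$e_f <- 0
  mn <- names(model$muscles)
  structure(list(model = model, core = core, q0 = pose$q, u0 = tonus$u,
                 com0 = com0, kp = kp, vel_weight = vel_weight, filt = filt,
                 sol = which(mn %in% c("soleus_r", "soleus_l")),
                 gas = which(mn %in% c("gastroc_r", "gastroc_l")),
                 ta = which(mn %in% c("tibant_r", "tibant_l")),
                 env = env),
            class = "stand_policy")
}

#' @export
policy_action.stand_policy <- function(policy, obs, ...) {
  nj <- length(joint_names(policy$model))
  q <- c(0, obs[["pelvis_h"]], obs[["pitch"]],
         obs[paste0("ang_", joint_names(policy$model))])
  qd <- c(obs[["vx"]], obs[["vy"]], obs[["pitch_rate"]],
          obs[paste0("vel_", joint_names(policy$model))])
  cm <- cpp_com(policy$core, unname(q), unname(qd))
  e <- (cm$com[1] - q[1]) - policy$com0 + policy$vel_weight * cm$comv[1]
  policy$env$e_f <- (1 - policy$filt) * policy$env$e_f + policy$filt * e
  adj <- policy$kp * policy$env$e_f
  u <- policy$u0
  u[policy$sol] <- u[policy$sol] + adj
  u[policy$gas] <- u[policy$gas] + 0.5 * adj
  u[policy$ta] <- u[policy$ta] - 0.8 * adj
  pmin(0.95, pmax(0.01, u))
}
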
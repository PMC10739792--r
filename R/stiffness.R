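# Analytic joint stiffness from muscle moment arms and series MTU stiffness.
#
# With the moment arm defined as r = dL/dtheta (L the MTU path length), a
# muscle of tension F applies the joint moment -r * F, so the restoring joint
# stiffness contributed by one muscle is
#     K = dr/dtheta * F + K_MTU * r^2,
# the derivative of r * F with the MTU force differentiated through the
# re-equilibrated fiber-tendon series (dF/dtheta = K_MTU * r).

joint_dof_index <- function(model, joint) {
  jn <- joint_names(model)
  i <- match(joint, jn)
  if (is.na(i)) stop("joint '", joint, "' not in model (", paste(jn, collapse = ", "), ")")
  i
}

#' MTU length and moment arms at a configuration
#'
#' The MTU length is the summed Euclidean distance along the muscle's path
#' points; the moment arm about each joint is the analytic partial derivative
#' of that length with respect to the joint angle (positive when the MTU
#' lengthens with increasing angle).
#'
#' @param model a `walker_model`.
#' @param muscle muscle name or index.
#' @param q full generalized coordinates (base x, y, pitch, joint angles), or
#'   a vector of joint angles only (base taken from the standing pose).
#' @return list with `L` (m) and `r` (named vector, m/rad, one per joint).
#' @export
mtu_length_and_moment_arm <- function(model, muscle, q) {
  core <- model_core(model)
  q <- full_coords(model, q)
  i <- if (is.character(muscle)) match(muscle, names(model$muscles)) else muscle
  if (is.na(i) || i < 1 || i > length(model$muscles))
    stop("unknown muscle '", muscle, "'")
  g <- cpp_muscle_geometry(core, q)
  list(L = g$L[i], r = setNames(g$R[i, ], joint_names(model)))
}

full_coords <- function(model, q) {
  nj <- length(joint_names(model))
  if (length(q) == nj) q <- c(default_q(model)[1:3], q)
  if (length(q) != 3 + nj) stop("q must have ", nj, " or ", 3 + nj, " entries")
  as.numeric(q)
}

# Solve all muscles to quasi-static equilibrium at configuration q with the
# given activations; returns per-muscle force and stiffness decomposition.
solve_all_mtus <- function(model, q, activations, core = model_core(model)) {
  q <- full_coords(model, q)
  g <- cpp_muscle_geometry(core, q)
  nm <- length(model$muscles)
  if (length(activations) == 1) activations <- rep(activations, nm)
  if (length(activations) != nm) stop("need one activation per muscle")
  cc <- model$options$curve_constants
  out <- vector("list", nm)
  for (i in seq_len(nm)) {
    p <- model$muscles[[i]]$params
    eq <- solve_mtu_equilibrium(p, g$L[i], 0, activations[i], cc,
                                name = names(model$muscles)[i])
    ks <- mtu_stiffness(p, list(fiber_length = eq$fiber_length,
                                activation = activations[i],
                                mtu_length = g$L[i], fiber_velocity = 0), cc)
    out[[i]] <- c(list(force = eq$force, fiber_length = eq$fiber_length), ks)
  }
  list(geom = g, mtus = out)
}

#' Analytic joint stiffness with per-muscle breakdown
#'
#' Computes the quasi-static stiffness of one joint: every muscle is solved to
#' fiber-tendon equilibrium at the supplied configuration and activations
#' (velocities zero), and the per-muscle contributions
#' `dr/dtheta * F + K_MTU * r^2` are summed. The moment-arm derivative is
#' taken by central differencing of the analytic moment arm.
#'
#' @param model a `walker_model`.
#' @param q configuration (see [mtu_length_and_moment_arm()]).
#' @param activations per-muscle activations in `[0, 1]` (scalar recycled).
#' @param joint joint name, e.g. `"knee_r"`.
#' @return list of class `stiffness_breakdown` with `K_nm_per_rad`,
#'   `K_nm_per_deg` and a per-muscle `breakdown` data frame (moment arm,
#'   moment-arm derivative, MTU force, fiber/tendon/series stiffness,
#'   contribution).
#' @export
joint_stiffness <- function(model, q, activations, joint) {
  core <- model_core(model)
  q <- full_coords(model, q)
  j <- joint_dof_index(model, joint)
  sol <- solve_all_mtus(model, q, activations, core)
  dlt <- 1e-5
  qp <- q; qp[3 + j] <- q[3 + j] + dlt
  qm <- q; qm[3 + j] <- q[3 + j] - dlt
  rp <- cpp_muscle_geometry(core, qp)$R[, j]
  rm <- cpp_muscle_geometry(core, qm)$R[, j]
  drdth <- (rp - rm) / (2 * dlt)
  r <- sol$geom$R[, j]
  F <- vapply(sol$mtus, `[[`, numeric(1), "force")
  K_MTU <- vapply(sol$mtus, `[[`, numeric(1), "K_MTU")
  contrib <- drdth * F + K_MTU * r^2
  br <- data.frame(
    muscle = names(model$muscles),
    moment_arm = r, d_moment_arm_d_angle = drdth, mtu_force = F,
    fiber_stiffness = vapply(sol$mtus, `[[`, numeric(1), "K_M"),
    tendon_stiffness = vapply(sol$mtus, `[[`, numeric(1), "K_T"),
    mtu_stiffness = K_MTU,
    negative_fiber_stiffness =
      vapply(sol$mtus, `[[`, logical(1), "negative_fiber_stiffness"),
    contribution = contrib,
    row.names = NULL, stringsAsFactors = FALSE)
  K <- sum(contrib)
  structure(list(joint = joint, K_nm_per_rad = K,
                 K_nm_per_deg = K * pi / 180, breakdown = br),
            class = "stiffness_breakdown")
}

#' Net quasi-static muscle moment measure used by the stiffness identity
#'
#' Returns `sum_m r_m * F_m` about a joint with all muscles re-solved to
#' equilibrium at `q` (activations frozen, velocities zero). Its derivative
#' with respect to the joint angle equals the analytic joint stiffness; the
#' physical joint moment applied by the muscles is the negative of this value.
#'
#' @inheritParams joint_stiffness
#' @return scalar, Nm.
#' @export
net_muscle_moment <- function(model, q, activations, joint) {
  j <- joint_dof_index(model, joint)
  sol <- solve_all_mtus(model, q, activations)
  sum(sol$geom$R[, j] * vapply(sol$mtus, `[[`, numeric(1), "force"))
}

#' Cycle-average joint stiffness along a motion
#'
#' Evaluates the instantaneous analytic joint stiffness at every frame of a
#' joint-angle table with matching per-muscle activations, and averages over
#' frames (stance + swing by default).
#'
#' @param model a `walker_model`.
#' @param motion data frame with `time` and one column per model joint (rad).
#' @param activations data frame with `time` and one column per muscle.
#' @param joints joints to report (default all).
#' @return list with `per_frame` (data frame of instantaneous K, Nm/rad) and
#'   `average` (data frame: joint, K_nm_per_rad, K_nm_per_deg).
#' @export
analyze_trial_stiffness <- function(model, motion, activations,
                                    joints = joint_names(model)) {
  core <- model_core(model)
  jn <- joint_names(model)
  mn <- names(model$muscles)
  missing_j <- setdiff(jn, names(motion))
  if (length(missing_j)) stop("motion lacks joint column(s): ",
                              paste(missing_j, collapse = ", "))
  missing_m <- setdiff(mn, names(activations))
  if (length(missing_m)) stop("activation table lacks muscle column(s): ",
                              paste(missing_m, collapse = ", "))
  n <- nrow(motion)
  K <- matrix(NA_real_, n, length(jn), dimnames = list(NULL, jn))
  lopt <- vapply(model$muscles, function(m) m$params$l_opt, numeric(1))
  cc <- model$options$curve_constants
  for (i in seq_len(n)) {
    q <- full_coords(model, as.numeric(motion[i, jn]))
    a <- pmin(1, pmax(0, as.numeric(activations[i, mn])))
    g <- cpp_muscle_geometry(core, q)
    lf <- vapply(seq_along(mn), function(m) {
      solve_mtu_equilibrium(model$muscles[[m]]$params, g$L[m], 0, a[m], cc,
                            name = mn[m])$fiber_length
    }, numeric(1))
    K[i, ] <- cpp_joint_stiffness_inst(core, q, a, lf)
  }
  avg <- data.frame(joint = jn, K_nm_per_rad = colMeans(K),
                    K_nm_per_deg = colMeans(K) * pi / 180, row.names = NULL)
  list(per_frame = data.frame(time = motion$time, K),
       average = avg[avg$joint %in% joints, ])
}
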
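# Shared fixtures, built once per test run.

walker <- build_planar_model()
walker_ref <- synthetic_reference_gait(walker)
flat_terrain <- make_terrain("flat")

# A single-segment pendulum expressed in the generic model structure: fixed
# base, one revolute joint, a force-free dummy muscle (both path points on the
# same segment so it spans no joint), no contact spheres.
pendulum_model <- function(mass = 2, length = 0.5, com_frac = 0.5,
                           rog_frac = 0.3, joint_damp = 0) {
  seg <- data.frame(
    name = c("base_seg", "rod"),
    mass = c(1e3, mass),
    inertia = c(1e3, mass * (rog_frac * length)^2),
    com_x = c(0, 0), com_y = c(0, -com_frac * length),
    stringsAsFactors = FALSE)
  jt <- data.frame(
    name = c("base", "pivot"),
    type = c("planar-free-base", "revolute"),
    parent = c("world", "base_seg"), child = c("base_seg", "rod"),
    sign = c(NA, 1), anchor_x = c(NA, 0), anchor_y = c(NA, 0),
    limit_lo = c(NA, -10), limit_hi = c(NA, 10),
    stringsAsFactors = FALSE)
  mus <- list(dummy = list(
    name = "dummy", group = "other",
    params = mtu_params(F0 = 1, l_opt = 0.05, l_slack = 0.05),
    path = data.frame(segment = c("rod", "rod"), x = c(0, 0),
                      y = c(-0.1, -0.2), stringsAsFactors = FALSE)))
  spheres <- data.frame(segment = character(0), x = numeric(0), y = numeric(0),
                        radius = numeric(0), foot = character(0),
                        heel = logical(0), stringsAsFactors = FALSE)
  eff <- data.frame(name = "tip", segment = "rod", x = 0, y = -length,
                    stringsAsFactors = FALSE)
  opts <- default_model_options()
  opts$fixed_base <- TRUE
  opts$joint_damp <- joint_damp
  structure(list(format_version = 1L, segments = seg, joints = jt,
                 muscles = mus, contact_spheres = spheres, effectors = eff,
                 options = opts, standing_height = length),
            class = "walker_model")
}

# One free segment carrying a single contact sphere: a block resting on the
# ground through one sphere, for static/sliding contact oracles.
block_model <- function(mass = 5, radius = 0.05) {
  seg <- data.frame(name = "block", mass = mass, inertia = mass * 0.01,
                    com_x = 0, com_y = 0, stringsAsFactors = FALSE)
  jt <- data.frame(name = "base", type = "planar-free-base", parent = "world",
                   child = "block", sign = NA, anchor_x = NA, anchor_y = NA,
                   limit_lo = NA, limit_hi = NA, stringsAsFactors = FALSE)
  mus <- list(dummy = list(
    name = "dummy", group = "other",
    params = mtu_params(F0 = 1, l_opt = 0.05, l_slack = 0.05),
    path = data.frame(segment = c("block", "block"), x = c(0, 0.1),
                      y = c(0, 0), stringsAsFactors = FALSE)))
  spheres <- data.frame(segment = "block", x = 0, y = -0.1, radius = radius,
                        foot = "right", heel = TRUE, stringsAsFactors = FALSE)
  eff <- data.frame(name = "c", segment = "block", x = 0, y = 0,
                    stringsAsFactors = FALSE)
  structure(list(format_version = 1L, segments = seg, joints = jt,
                 muscles = mus, contact_spheres = spheres, effectors = eff,
                 options = default_model_options(), standing_height = 0.2),
            class = "walker_model")
}

# A minimal planar knee: fixed base ("femur" fused to base), one revolute
# joint driving a "tibia", with two antagonist muscles whose geometry can be
# randomised; used by the stiffness finite-difference oracles.
knee_model <- function(org_ext = c(0.03, -0.15), via_ext = c(0.05, -0.38),
                       ins_ext = c(0.04, -0.06),
                       org_flx = c(-0.03, -0.12), ins_flx = c(-0.03, -0.05),
                       F0 = c(3000, 2000), ffrac = c(0.4, 0.45)) {
  seg <- data.frame(
    name = c("femur", "tibia"),
    mass = c(10, 3), inertia = c(0.5, 0.05),
    com_x = c(0, 0), com_y = c(-0.2, -0.2), stringsAsFactors = FALSE)
  jt <- data.frame(
    name = c("base", "knee"),
    type = c("planar-free-base", "revolute"),
    parent = c("world", "femur"), child = c("femur", "tibia"),
    sign = c(NA, -1), anchor_x = c(NA, 0), anchor_y = c(NA, -0.42),
    limit_lo = c(NA, -0.2), limit_hi = c(NA, 2.4), stringsAsFactors = FALSE)
  mk <- function(nm, grp, pts, F0i, ff) {
    path <- data.frame(segment = c("femur", rep("tibia", nrow(pts) - 1)),
                       x = pts[, 1], y = pts[, 2], stringsAsFactors = FALSE)
    if (nrow(pts) == 3) path$segment <- c("femur", "femur", "tibia")
    list(name = nm, group = grp, params = NULL, path = path,
         F0i = F0i, ff = ff)
  }
  mus <- list(
    ext = mk("ext", "vastus", rbind(org_ext, via_ext, ins_ext), F0[1], ffrac[1]),
    flx = mk("flx", "biceps_femoris", rbind(org_flx, ins_flx), F0[2], ffrac[2]))
  spheres <- data.frame(segment = character(0), x = numeric(0), y = numeric(0),
                        radius = numeric(0), foot = character(0),
                        heel = logical(0), stringsAsFactors = FALSE)
  eff <- data.frame(name = "tip", segment = "tibia", x = 0, y = -0.4,
                    stringsAsFactors = FALSE)
  opts <- default_model_options()
  opts$fixed_base <- TRUE
  model <- structure(list(format_version = 1L, segments = seg, joints = jt,
                          muscles = mus, contact_spheres = spheres,
                          effectors = eff, options = opts,
                          standing_height = 0.9),
                     class = "walker_model")
  # size MTUs at the straight-knee pose, as for the walker
  geom <- planargait:::cpp_muscle_geometry(
    planargait:::model_core(model, skip_params = TRUE),
    c(0, 0.9, 0, 0))
  for (i in seq_along(model$muscles)) {
    L0 <- geom$L[i]
    ff <- model$muscles[[i]]$ff
    model$muscles[[i]]$params <- mtu_params(
      F0 = model$muscles[[i]]$F0i, l_opt = ff * L0, l_slack = (1 - ff) * L0)
    model$muscles[[i]]$F0i <- NULL
    model$muscles[[i]]$ff <- NULL
  }
  model
}

# Independent brute-force trapezoid coactivation index (oracle).
brute_ci <- function(a, b) {
  tz <- function(y) sum((y[-1] + y[-length(y)]) / 2)
  100 * 2 * tz(pmin(a, b)) / (tz(a) + tz(b))
}
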
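# Planar walker model definition: rigid segments, revolute joints, Hill-type
# muscle-tendon units with polyline path points, and foot contact spheres.
#
# Coordinates: x forward, y up, rotations about +z (right-hand rule), radians.
# Each segment has a local frame with its origin at the proximal joint; the
# trunk (root) frame sits at the pelvis and is carried by the planar free base
# (base x, base y, trunk pitch). Joint angles are stored in anatomical
# convention (hip flexion +, knee flexion +, ankle dorsiflexion +) and mapped
# to rotations through each joint's axis sign.

#' Default Hill curve constants
#'
#' Shape constants of the muscle and tendon curves: active force-length
#' Gaussian width `gamma`; passive-fiber strain `e0_pass` at which passive
#' force reaches the maximum isometric force, with exponential shape `kpe`;
#' Hill hyperbola curvature `a_hill` and eccentric plateau `fv_plateau` of the
#' force-velocity curve; nominal tendon strain `eps0` at the maximum isometric
#' force and the toe-region fraction `toe_frac` of the tendon curve.
#'
#' @param ... named overrides of individual constants.
#' @return named numeric vector of the seven curve constants.
#' @export
hill_curve_constants <- function(...) {
  cc <- c(gamma = 0.45, e0_pass = 0.6, kpe = 4, a_hill = 0.25,
          fv_plateau = 1.4, eps0 = 0.049, toe_frac = 0.4)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cc))
    if (length(bad)) stop("unknown curve constant(s): ", paste(bad, collapse = ", "))
    cc[names(ov)] <- unlist(ov)
  }
  cc
}

#' Muscle-tendon unit parameters
#'
#' @param F0 maximum isometric force (N).
#' @param l_opt optimal fiber length (m).
#' @param l_slack tendon slack length (m).
#' @param pennation optimal-length pennation angle (rad), in `[0, pi/3)`.
#' @param v_max maximum shortening velocity (optimal fiber lengths per second).
#' @param tau_act,tau_deact activation / deactivation time constants (s).
#' @return a validated list of class `mtu_params`.
#' @export
mtu_params <- function(F0, l_opt, l_slack, pennation = 0, v_max = 10,
                       tau_act = 0.01, tau_deact = 0.04) {
  p <- list(F0 = F0, l_opt = l_opt, l_slack = l_slack, pennation = pennation,
            v_max = v_max, tau_act = tau_act, tau_deact = tau_deact)
  num <- unlist(p)
  if (any(!is.finite(num))) stop("non-finite MTU parameter")
  if (any(num[c("F0", "l_opt", "l_slack", "v_max", "tau_act", "tau_deact")] <= 0))
    stop("MTU parameters must be strictly positive")
  if (pennation < 0 || pennation >= pi / 3)
    stop("pennation must lie in [0, pi/3)")
  structure(p, class = "mtu_params")
}

#' Validate a walker model definition
#'
#' Checks the structural invariants: positive masses, inertias and sphere
#' radii; every muscle path point and contact sphere referencing an existing
#' segment; at least two path points per muscle; and a joint graph that is a
#' tree rooted at the floating base segment.
#'
#' @param model a `walker_model` object.
#' @return the model, invisibly, if valid; otherwise an error naming the
#'   offending entry.
#' @export
validate_model <- function(model) {
  seg <- model$segments
  if (any(seg$mass <= 0))
    stop("non-positive mass for segment ", seg$name[which(seg$mass <= 0)[1]])
  if (any(seg$inertia <= 0))
    stop("non-positive inertia for segment ", seg$name[which(seg$inertia <= 0)[1]])
  jt <- model$joints
  if (sum(jt$type == "planar-free-base") != 1)
    stop("model must have exactly one planar-free-base joint")
  root <- jt$child[jt$type == "planar-free-base"]
  rev <- jt[jt$type == "revolute", , drop = FALSE]
  for (nm in c(rev$parent, rev$child))
    if (!nm %in% seg$name) stop("joint references unknown segment ", nm)
  # tree check: every non-root segment is the child of exactly one joint,
  # and walking parents terminates at the root
  for (s in seg$name) {
    if (s == root) next
    k <- sum(rev$child == s)
    if (k != 1)
      stop("segment ", s, " must be the child of exactly one revolute joint")
  }
  for (s in seg$name) {
    seen <- character()
    cur <- s
    while (cur != root) {
      if (cur %in% seen) stop("joint graph has a cycle at segment ", cur)
      seen <- c(seen, cur)
      i <- which(rev$child == cur)
      if (!length(i)) stop("segment ", cur, " is not connected to the base")
      cur <- rev$parent[i]
    }
  }
  for (m in model$muscles) {
    if (nrow(m$path) < 2)
      stop("muscle ", m$name, " needs at least 2 path points")
    bad <- setdiff(m$path$segment, seg$name)
    if (length(bad))
      stop("muscle ", m$name, " references unknown segment ", bad[1])
    same <- m$path$segment[-1] == m$path$segment[-nrow(m$path)]
    d <- sqrt(diff(m$path$x)^2 + diff(m$path$y)^2)
    if (any(same & d < 1e-9))
      stop("muscle ", m$name, " has coincident adjacent path points")
  }
  cs <- model$contact_spheres
  if (nrow(cs)) {
    bad <- setdiff(cs$segment, seg$name)
    if (length(bad)) stop("contact sphere references unknown segment ", bad[1])
    if (any(cs$radius <= 0)) stop("non-positive contact sphere radius")
  }
  invisible(model)
}

default_model_options <- function() {
  list(gravity = 9.81,
       contact_kn = 1.5e5, contact_cn = 1.0, contact_veps = 0.005,
       jlim_k = 300, jlim_c = 5, joint_damp = 0.5,
       act_min = 0.01, mus_beta = 0.1,
       curve_constants = hill_curve_constants(),
       fixed_base = FALSE)
}

#' Build the reduced planar walker
#'
#' Constructs the seven-segment sagittal walker: trunk (head-arms-trunk lump),
#' two thighs, two shanks and two feet, joined by a planar free base and six
#' revolute joints (hips, knees, ankles), actuated by nine muscles per leg and
#' supported by three contact spheres per foot (one calcaneus, two toe).
#' Segment masses and lengths follow standard anthropometric fractions scaled
#' to the configured body mass and height.
#'
#' @param config named list of overrides: `body_mass` (kg, default 65.4),
#'   `height` (m, default 1.712), plus any entry of the model option block
#'   (gravity, contact and joint-limit constants, `curve_constants`,
#'   `fixed_base`).
#' @return a validated `walker_model`.
#' @export
build_planar_model <- function(config = list()) {
  body_mass <- config$body_mass %||% 65.4
  height <- config$height %||% 1.712
  if (body_mass <= 0 || height <= 0) stop("non-positive body mass or height")

  l_thigh <- 0.245 * height
  l_shank <- 0.246 * height
  l_foot <- 0.152 * height
  ankle_h <- 0.06

  m_hat <- 0.678 * body_mass
  m_thigh <- 0.100 * body_mass
  m_shank <- 0.0465 * body_mass
  m_foot <- 0.0145 * body_mass

  segments <- data.frame(
    name = c("trunk", "thigh_r", "shank_r", "foot_r",
             "thigh_l", "shank_l", "foot_l"),
    mass = c(m_hat, m_thigh, m_shank, m_foot, m_thigh, m_shank, m_foot),
    inertia = c(m_hat * 0.40^2,
                rep(c(m_thigh * (0.323 * l_thigh)^2,
                      m_shank * (0.302 * l_shank)^2,
                      m_foot * (0.25 * l_foot)^2), 2)),
    com_x = c(0, 0, 0, 0.05, 0, 0, 0.05),
    com_y = c(0.35, -0.433 * l_thigh, -0.433 * l_shank, -0.03,
              -0.433 * l_thigh, -0.433 * l_shank, -0.03),
    stringsAsFactors = FALSE)

  joints <- data.frame(
    name = c("base", "hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l"),
    type = c("planar-free-base", rep("revolute", 6)),
    parent = c("world", "trunk", "thigh_r", "shank_r", "trunk", "thigh_l", "shank_l"),
    child = c("trunk", "thigh_r", "shank_r", "foot_r", "thigh_l", "shank_l", "foot_l"),
    sign = c(NA, 1, -1, 1, 1, -1, 1),
    anchor_x = c(NA, 0, 0, 0, 0, 0, 0),
    anchor_y = c(NA, 0, -l_thigh, -l_shank, 0, -l_thigh, -l_shank),
    limit_lo = c(NA, -0.6, -0.1, -0.9, -0.6, -0.1, -0.9),
    limit_hi = c(NA, 1.6, 2.4, 0.8, 1.6, 2.4, 0.8),
    stringsAsFactors = FALSE)

  # muscle path geometry per leg (local frames); proportions follow common
  # sagittal lines of action so moment arms land in the 2-6 cm range
  leg_paths <- function(side) {
    th <- paste0("thigh_", side); sh <- paste0("shank_", side)
    ft <- paste0("foot_", side)
    list(
      iliopsoas = list(group = "other", F0 = 1500, ffrac = 0.5,
        path = data.frame(segment = c("trunk", th),
                          x = c(0.06, 0.015), y = c(0.08, -0.10))),
      glutmax = list(group = "other", F0 = 2200, ffrac = 0.5,
        path = data.frame(segment = c("trunk", th),
                          x = c(-0.08, -0.02), y = c(0.05, -0.12))),
      # knee-crossing paths carry a via point just distal to the joint so the
      # moment arm stays near-constant over the motion range (the polyline
      # stand-in for patellar/retinacular routing)
      vastus = list(group = "vastus", F0 = 5000, ffrac = 0.35,
        path = data.frame(segment = c(th, th, sh, sh),
                          x = c(0.025, 0.05, 0.045, 0.04),
                          y = c(-0.15, -l_thigh + 0.02, -0.015, -0.09))),
      rectfem = list(group = "other", F0 = 1200, ffrac = 0.35,
        path = data.frame(segment = c("trunk", th, sh, sh),
                          x = c(0.05, 0.05, 0.045, 0.04),
                          y = c(-0.02, -l_thigh + 0.02, -0.015, -0.09))),
      bifemlh = list(group = "biceps_femoris", F0 = 1800, ffrac = 0.45,
        path = data.frame(segment = c("trunk", sh, sh),
                          x = c(-0.07, -0.035, -0.03),
                          y = c(0.0, -0.02, -0.07))),
      semiten = list(group = "semitendinosus", F0 = 1300, ffrac = 0.45,
        path = data.frame(segment = c("trunk", th, sh, sh),
                          x = c(-0.06, -0.035, -0.032, -0.025),
                          y = c(0.02, -l_thigh + 0.02, -0.02, -0.09))),
      tibant = list(group = "tibialis_anterior", F0 = 1200, ffrac = 0.3,
        path = data.frame(segment = c(sh, sh, ft, ft),
                          x = c(0.025, 0.035, 0.04, 0.10),
                          y = c(-0.18, -l_shank + 0.02, 0.0, -0.02))),
      soleus = list(group = "soleus", F0 = 3600, ffrac = 0.25,
        path = data.frame(segment = c(sh, ft, ft),
                          x = c(-0.025, -0.045, -0.055),
                          y = c(-0.15, -0.005, -0.035))),
      gastroc = list(group = "gastrocnemius", F0 = 2500, ffrac = 0.25,
        path = data.frame(segment = c(th, ft, ft),
                          x = c(-0.025, -0.045, -0.055),
                          y = c(-l_thigh + 0.04, -0.005, -0.035))))
  }

  muscles <- list()
  for (side in c("r", "l")) {
    for (nm in names(lp <- leg_paths(side))) {
      mu <- lp[[nm]]
      muscles[[paste0(nm, "_", side)]] <-
        list(name = paste0(nm, "_", side), group = mu$group,
             params = NULL, ffrac = mu$ffrac, F0 = mu$F0, path = mu$path)
    }
  }

  spheres <- do.call(rbind, lapply(c("r", "l"), function(side) {
    data.frame(segment = paste0("foot_", side),
               x = c(-0.045, 0.55 * l_foot, 0.72 * l_foot),
               y = c(-0.035, -0.04, -0.04),
               radius = c(0.025, 0.02, 0.02),
               foot = if (side == "r") "right" else "left",
               heel = c(TRUE, FALSE, FALSE),
               stringsAsFactors = FALSE)
  }))

  effectors <- data.frame(
    name = c("head", "foot_r", "foot_l"),
    segment = c("trunk", "foot_r", "foot_l"),
    x = c(0, 0.08, 0.08), y = c(0.62, -0.04, -0.04),
    stringsAsFactors = FALSE)

  opts <- default_model_options()
  keep <- intersect(names(config), names(opts))
  opts[keep] <- config[keep]

  model <- structure(
    list(format_version = 1L, segments = segments, joints = joints,
         muscles = muscles, contact_spheres = spheres, effectors = effectors,
         options = opts,
         standing_height = l_thigh + l_shank + ankle_h),
    class = "walker_model")

  # size each MTU against the standing pose: the tendon is exactly slack and
  # the fiber sits at 0.85 of its optimal length, i.e. on the ascending limb
  # of the active force-length curve (gait muscles operate mostly below
  # optimal length; this also gives the fibers a positive length-feedback
  # stiffness around the working range). Zero pennation throughout keeps the
  # series-stiffness identity exact; see the methods vignette.
  geom <- cpp_muscle_geometry(model_core(model, skip_params = TRUE),
                              default_q(model))
  for (i in seq_along(model$muscles)) {
    L0 <- geom$L[i]
    ff <- model$muscles[[i]]$ffrac
    model$muscles[[i]]$params <- mtu_params(
      F0 = model$muscles[[i]]$F0, l_opt = ff * L0 / 0.85,
      l_slack = (1 - ff) * L0)
    model$muscles[[i]]$ffrac <- NULL
    model$muscles[[i]]$F0 <- NULL
  }
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default (standing) generalized coordinates of a model
#'
#' Base at x = 0 with the pelvis at standing height, trunk vertical, all
#' joint angles zero.
#'
#' @param model a `walker_model`.
#' @return numeric vector of generalized coordinates.
#' @export
default_q <- function(model) {
  c(0, model$standing_height, rep(0, 1 + nrow(model$joints) - 1))[
    seq_len(3 + sum(model$joints$type == "revolute"))]
}

#' Names of the revolute joints, in dof order
#' @param model a `walker_model`.
#' @return character vector.
#' @export
joint_names <- function(model) {
  model$joints$name[model$joints$type == "revolute"]
}

#' Muscle names and their agonist/antagonist group tags
#' @param model a `walker_model`.
#' @return named character vector mapping muscle name to group tag.
#' @export
muscle_groups <- function(model) {
  vapply(model$muscles, function(m) m$group, character(1))
}

# Flatten a model to the numeric arrays the C++ core consumes. Cached on the
# model object by simulate/analyze entry points.
model_core <- function(model, skip_params = FALSE) {
  seg <- model$segments
  segmap <- setNames(seq_len(nrow(seg)) - 1L, seg$name)
  rev <- model$joints[model$joints$type == "revolute", , drop = FALSE]
  ndof <- 3L + nrow(rev)

  seg_parent <- rep(-1L, nrow(seg))
  seg_dof <- rep(-1L, nrow(seg))
  seg_sign <- rep(0, nrow(seg))
  anchor <- matrix(0, 2, nrow(seg))
  for (i in seq_len(nrow(rev))) {
    ci <- segmap[rev$child[i]] + 1L
    seg_parent[ci] <- segmap[rev$parent[i]]
    seg_dof[ci] <- 2L + i  # 0-based dof index: base is 0..2
    seg_sign[ci] <- rev$sign[i]
    anchor[, ci] <- c(rev$anchor_x[i], rev$anchor_y[i])
  }
  if (any(seg_parent[-1] >= seq_len(nrow(seg) - 1)))
    stop("segments must be ordered parents-first")

  mus <- model$muscles
  npts <- vapply(mus, function(m) nrow(m$path), integer(1))
  mus_ptr <- c(0L, cumsum(npts))
  mus_seg <- unlist(lapply(mus, function(m) unname(segmap[m$path$segment])))
  mus_xy <- t(do.call(rbind, lapply(mus, function(m) cbind(m$path$x, m$path$y))))
  getp <- function(field, default) {
    vapply(mus, function(m) {
      if (skip_params || is.null(m$params)) default else m$params[[field]]
    }, numeric(1))
  }

  cs <- model$contact_spheres
  eff <- model$effectors
  opt <- model$options
  dof_free <- rep(1L, ndof)
  if (isTRUE(opt$fixed_base)) dof_free[1:3] <- 0L

  list(seg_parent = as.integer(seg_parent), seg_dof = as.integer(seg_dof),
       seg_sign = seg_sign, mass = seg$mass, inertia = seg$inertia,
       anchor = anchor, com = rbind(seg$com_x, seg$com_y),
       mus_ptr = as.integer(mus_ptr), mus_seg = as.integer(mus_seg),
       mus_xy = mus_xy,
       F0 = getp("F0", 1), lopt = getp("l_opt", 0.1),
       lslack = getp("l_slack", 0.1), penn = getp("pennation", 0),
       vmax = getp("v_max", 10),
       tau_act = getp("tau_act", 0.01), tau_deact = getp("tau_deact", 0.04),
       sph_seg = as.integer(unname(segmap[cs$segment])),
       sph_foot = as.integer(cs$foot == "left"),
       sph_heel = as.integer(cs$heel),
       sph_xy = rbind(cs$x, cs$y), sph_r = cs$radius,
       jlim_lo = rev$limit_lo, jlim_hi = rev$limit_hi,
       jlim_k = opt$jlim_k, jlim_c = opt$jlim_c, joint_damp = opt$joint_damp,
       contact_kn = opt$contact_kn, contact_cn = opt$contact_cn,
       contact_veps = opt$contact_veps, gravity = opt$gravity,
       act_min = opt$act_min, mus_beta = opt$mus_beta, dof_free = dof_free,
       curve_constants = unname(opt$curve_constants),
       eff_seg = as.integer(unname(segmap[eff$segment])),
       eff_xy = rbind(eff$x, eff$y))
}
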
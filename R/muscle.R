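# Hill-type muscle-tendon unit: dimensionless curves, first-order activation
# dynamics, and the fiber-tendon force equilibrium solve.

curve_kind_code <- function(kind) {
  switch(kind,
         active_fl = 1L, passive_fl = 2L, force_velocity = 3L, tendon_fl = 4L,
         stop("unknown curve kind '", kind, "'"))
}

#' Evaluate a normalized Hill curve
#'
#' Dimensionless muscle and tendon curves (force in units of the maximum
#' isometric force F0). `active_fl` and `passive_fl` take fiber length /
#' optimal fiber length; `force_velocity` takes fiber velocity normalized by
#' the maximum shortening velocity (negative = shortening); `tendon_fl` takes
#' tendon strain.
#'
#' @param kind one of `"active_fl"`, `"passive_fl"`, `"force_velocity"`,
#'   `"tendon_fl"`.
#' @param x numeric vector of normalized inputs.
#' @param constants curve constants, see [hill_curve_constants()].
#' @return numeric vector of normalized forces.
#' @export
evaluate_curves <- function(kind, x, constants = hill_curve_constants()) {
  if (any(!is.finite(x))) stop("non-finite curve input")
  cpp_curve(curve_kind_code(kind), as.numeric(x), unname(constants))
}

# Analytic slope of the length-type curves (per unit normalized input).
curve_slope <- function(kind, x, constants = hill_curve_constants()) {
  cpp_curve_d(curve_kind_code(kind), as.numeric(x), unname(constants))
}

#' One step of first-order activation dynamics
#'
#' Integrates `da/dt = (u - a) / tau(u, a)` with the activation-scaled time
#' constants `tau_act * (0.5 + 1.5 a)` during excitation rise and
#' `tau_deact / (0.5 + 1.5 a)` during decay. The step is split into substeps
#' no longer than a fifth of the smaller time constant so that long control
#' steps remain accurate.
#'
#' @param u excitation in `[0, 1]`.
#' @param a current activation in `[0, 1]`.
#' @param dt time step (s), > 0.
#' @param params an [mtu_params()] object (uses `tau_act`, `tau_deact`).
#' @return the new activation, in `[0, 1]`.
#' @export
activation_step <- function(u, a, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  if (any(u < 0 | u > 1) || any(a < 0 | a > 1))
    stop("u and a must lie in [0, 1]")
  n_sub <- max(1L, ceiling(dt / (0.2 * min(params$tau_act, params$tau_deact))))
  h <- dt / n_sub
  for (i in seq_len(n_sub)) {
    tau <- ifelse(u > a, params$tau_act * (0.5 + 1.5 * a),
                  params$tau_deact / (0.5 + 1.5 * a))
    # exponential integrator with tau frozen over the substep
    a <- u + (a - u) * exp(-h / tau)
    a <- pmin(1, pmax(0, a))
  }
  a
}

# Pennation under the constant-thickness model: sin(alpha) * l_fiber conserved.
pennation_cos <- function(params, fiber_length) {
  sina <- min(0.99, sin(params$pennation) * params$l_opt / max(fiber_length, 1e-9))
  sqrt(1 - sina^2)
}

#' Solve the fiber-tendon equilibrium of a muscle-tendon unit
#'
#' Finds the fiber length at which the tendon force balances the along-tendon
#' fiber force (active + passive, times the pennation cosine) for a given MTU
#' length, MTU lengthening velocity and activation. The fiber velocity is
#' taken as the MTU velocity divided by the pennation cosine (the tendon is
#' treated as inextensible at the velocity level for this static solve). The
#' root is found with damped Newton iteration on the fiber length, falling
#' back to bisection on the bracket `[0.2, 1.8] * l_opt`.
#'
#' With `rigid_tendon = TRUE` the fiber length follows directly from the
#' geometry (`l_fiber * cos(pennation) = mtu_length - l_slack`) and no solve
#' is needed.
#'
#' @param params an [mtu_params()] object.
#' @param mtu_length MTU path length (m), > 0.
#' @param mtu_velocity MTU lengthening velocity (m/s).
#' @param a activation in `[0, 1]`.
#' @param constants curve constants.
#' @param rigid_tendon logical; use the rigid-tendon shortcut.
#' @param name muscle name used in error messages.
#' @return list with `force` (tendon force, N), `fiber_length` (m),
#'   `fiber_velocity` (m/s), and the equilibrium `residual` (N).
#' @export
solve_mtu_equilibrium <- function(params, mtu_length, mtu_velocity = 0, a = 0,
                                  constants = hill_curve_constants(),
                                  rigid_tendon = FALSE, name = "mtu") {
  if (mtu_length <= 0) stop("mtu_length must be > 0")
  if (a < 0 || a > 1) stop("activation must lie in [0, 1]")
  cc <- unname(constants)
  vtilde <- mtu_velocity / (params$v_max * params$l_opt)

  if (rigid_tendon) {
    h <- params$l_opt * sin(params$pennation)
    proj <- max(mtu_length - params$l_slack, 1e-9)
    lf <- sqrt(proj^2 + h^2)
    cosa <- proj / lf
    lt <- lf / params$l_opt
    fl <- cpp_curve(1L, lt, cc) * cpp_curve(3L, vtilde / cosa, cc) * a +
      cpp_curve(2L, lt, cc)
    force <- params$F0 * fl * cosa
    return(list(force = max(force, 0), fiber_length = lf,
                fiber_velocity = mtu_velocity / cosa, residual = 0))
  }

  resid <- function(lf) {
    cosa <- pennation_cos(params, lf)
    eps <- (mtu_length - lf * cosa) / params$l_slack - 1
    lt <- lf / params$l_opt
    fT <- cpp_curve(4L, eps, cc)
    fM <- (a * cpp_curve(1L, lt, cc) * cpp_curve(3L, vtilde / cosa, cc) +
             cpp_curve(2L, lt, cc)) * cosa
    fT - fM
  }

  lo <- 0.2 * params$l_opt
  hi <- 1.8 * params$l_opt
  flo <- resid(lo); fhi <- resid(hi)
  if (flo * fhi > 0) {
    # no sign change: either fully slack (both fiber and tendon force-free)
    # or a genuine failure
    if (abs(flo) < 1e-9 && abs(fhi) < 1e-9) {
      lf <- min(params$l_opt,
                max(lo, (mtu_length - params$l_slack) /
                      pennation_cos(params, params$l_opt)))
      return(list(force = 0, fiber_length = lf, fiber_velocity = mtu_velocity,
                  residual = 0))
    }
    stop("no equilibrium root for ", name, " at mtu_length = ", mtu_length,
         ", a = ", a)
  }

  lf <- 0.5 * (lo + hi)
  for (it in 1:100) {
    f <- resid(lf)
    if (abs(f) < 1e-10) break
    if (f * flo < 0) { hi <- lf; fhi <- f } else { lo <- lf; flo <- f }
    h <- 1e-7 * params$l_opt
    df <- (resid(lf + h) - resid(lf - h)) / (2 * h)
    step_ok <- is.finite(df) && abs(df) > 1e-12
    lf_new <- if (step_ok) lf - f / df else NA_real_
    if (!step_ok || is.na(lf_new) || lf_new <= lo || lf_new >= hi)
      lf_new <- 0.5 * (lo + hi)  # bisection fallback
    lf <- lf_new
  }
  cosa <- pennation_cos(params, lf)
  eps <- (mtu_length - lf * cosa) / params$l_slack - 1
  force <- params$F0 * cpp_curve(4L, eps, cc)
  list(force = max(force, 0), fiber_length = lf,
       fiber_velocity = mtu_velocity / cosa,
       residual = params$F0 * resid(lf))
}

#' Fiber, tendon and series MTU stiffness
#'
#' Fiber stiffness is the slope of the along-tendon fiber force with respect
#' to fiber length at fixed activation (active + passive slopes summed, the
#' force-velocity multiplier evaluated at the state's velocity but not
#' differentiated); tendon stiffness is the slope of the tendon force-strain
#' curve over the slack length; the series MTU stiffness combines the two as
#' `(1/K_M + 1/K_T)^-1`, with the convention that a slack (zero-stiffness)
#' element makes the series stiffness zero.
#'
#' @param params an [mtu_params()] object.
#' @param state list with `fiber_length` (m), `activation`, `mtu_length` (m)
#'   and optionally `fiber_velocity` (m/s, default 0).
#' @param constants curve constants.
#' @return list with `K_M`, `K_T`, `K_MTU` in N/m (fiber stiffness may be
#'   negative on the descending limb of the active force-length curve;
#'   `negative_fiber_stiffness` flags this).
#' @export
mtu_stiffness <- function(params, state, constants = hill_curve_constants()) {
  cc <- unname(constants)
  lf <- state$fiber_length
  a <- state$activation
  vf <- state$fiber_velocity %||% 0
  cosa <- pennation_cos(params, lf)
  lt <- lf / params$l_opt
  eps <- (state$mtu_length - lf * cosa) / params$l_slack - 1
  fv <- cpp_curve(3L, vf / (params$v_max * params$l_opt), cc)
  K_M <- params$F0 / params$l_opt *
    (a * cpp_curve_d(1L, lt, cc) * fv + cpp_curve_d(2L, lt, cc)) * cosa^2
  K_T <- params$F0 / params$l_slack * cpp_curve_d(4L, eps, cc)
  den <- K_M + K_T
  K_MTU <- if (abs(den) < 1e-9) 0 else K_M * K_T / den
  list(K_M = K_M, K_T = K_T, K_MTU = K_MTU,
       negative_fiber_stiffness = K_M < 0)
}
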
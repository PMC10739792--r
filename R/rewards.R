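# Imitation-tracking reward and its shaping variants.
#
# The tracking reward is a weighted sum of exponential kernels over squared
# tracking errors (joint angles in radians, velocities in rad/s, end-effector
# and center-of-mass positions in meters):
#   r_track = 0.65 exp(-0.4 SSE_pos) + 0.1 exp(-0.000625 SSE_vel)
#           + 0.15 exp(-1.25 SSE_end) + 0.1 exp(-0.5 SSE_com).
# Fine-tuning adds an activation-minimisation kernel r_A = exp(-sum a_i^2)
# and a joint-stiffness-target kernel
#   r_S = exp(-sum_j (S_target_j - S_j)^2), j in {hip, knee, ankle}.

kernel_coefs <- c(pos = 0.4, vel = 0.000625, end = 1.25, com = 0.5)
track_weights <- c(pos = 0.65, vel = 0.1, end = 0.15, com = 0.1)

variant_table <- function() {
  data.frame(
    variant = c("STANDARD", "ACT", "STIF0", "STIF1", "STIF2", "STIF3",
                "ACT_RANDOM"),
    w_track = c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9),
    w_A = c(0.0, 0.1, 0.05, 0.05, 0.05, 0.05, 0.1),
    w_S = c(0.0, 0.0, 0.05, 0.05, 0.05, 0.05, 0.0),
    s_target = c(NA, NA, 0.0, 5.0, 7.5, 10.0, NA),
    stringsAsFactors = FALSE)
}

#' Reward specification for a controller variant
#'
#' Named variants reproduce the study's objective table exactly: STANDARD
#' tracks only (weights 1/0/0); ACT adds activation minimisation (0.9/0.1/0);
#' STIF0-STIF3 add a joint-stiffness target kernel (0.9/0.05/0.05) with the
#' same target at hip, knee and ankle (0, 5.0, 7.5, 10.0 in the configured
#' stiffness unit); ACT_RANDOM shares ACT's objective but trains with a
#' per-episode random ground friction in `[0.2, 0.8]`.
#'
#' @param variant one of the named variants, or `"CUSTOM"`.
#' @param w_track,w_A,w_S component weights (CUSTOM only), all >= 0.
#' @param s_target named stiffness targets `c(hip=, knee=, ankle=)` (CUSTOM).
#' @param stiffness_unit `"Nm/deg"` (default) or `"Nm/rad"` for targets and
#'   measured stiffness entering `r_S`.
#' @param normalize_activation logical: rescale the activation exponent by
#'   `92 / n_muscles` to keep its magnitude comparable to the full-body
#'   muscle set; off by default.
#' @return object of class `reward_spec`.
#' @export
reward_spec <- function(variant = "STANDARD", w_track = NULL, w_A = NULL,
                        w_S = NULL, s_target = NULL,
                        stiffness_unit = c("Nm/deg", "Nm/rad"),
                        normalize_activation = FALSE) {
  stiffness_unit <- match.arg(stiffness_unit)
  tb <- variant_table()
  if (variant %in% tb$variant) {
    row <- tb[tb$variant == variant, ]
    w <- c(track = row$w_track, A = row$w_A, S = row$w_S)
    st <- if (is.na(row$s_target)) NULL else
      c(hip = row$s_target, knee = row$s_target, ankle = row$s_target)
  } else if (variant == "CUSTOM") {
    w <- c(track = w_track %||% 1, A = w_A %||% 0, S = w_S %||% 0)
    st <- s_target
  } else stop("unknown reward variant '", variant, "'")
  if (any(w < 0)) stop("reward weights must be non-negative")
  if (w[["S"]] > 0 && is.null(st))
    stop("stiffness targets required when w_S > 0")
  stopifnot(abs(sum(track_weights) - 1) < 1e-12)
  structure(list(variant = variant, weights = w, s_target = st,
                 kernel_coefs = kernel_coefs, track_weights = track_weights,
                 stiffness_unit = stiffness_unit,
                 normalize_activation = normalize_activation,
                 mu_random = if (variant == "ACT_RANDOM") c(0.2, 0.8) else NULL),
            class = "reward_spec")
}

#' Tracking sub-reward kernel
#'
#' `exp(-c * SSE)` with the kind-specific coefficient: 0.4 for joint-angle
#' errors (rad), 0.000625 for joint-velocity errors (rad/s), 1.25 for
#' end-effector position errors (m), 0.5 for the center-of-mass position
#' error (m).
#'
#' @param kind one of `"pos"`, `"vel"`, `"end"`, `"com"`.
#' @param errors list of tracking errors: `ang` (per-joint angle errors),
#'   `vel` (per-joint velocity errors), `end` (2 x n matrix of end-effector
#'   position errors), `com` (length-2 position error).
#' @return kernel value in `(0, 1]`.
#' @export
tracking_subreward <- function(kind, errors) {
  kind <- match.arg(kind, names(kernel_coefs))
  e <- switch(kind, pos = errors$ang, vel = errors$vel,
              end = errors$end, com = errors$com)
  if (is.null(e) || any(!is.finite(e))) stop("missing or non-finite '", kind,
                                             "' tracking errors")
  exp(-kernel_coefs[[kind]] * sum(e^2))
}

#' Imitation tracking reward
#'
#' @param errors see [tracking_subreward()].
#' @param spec a [reward_spec()] (only the fixed kernel coefficients and
#'   tracking weights are used).
#' @return `r_track` in `(0, 1]`.
#' @export
r_track <- function(errors, spec = reward_spec()) {
  w <- spec$track_weights
  sum(w * vapply(names(w), tracking_subreward, numeric(1), errors = errors))
}

#' Activation-minimisation reward
#'
#' `exp(-sum a_i^2)` over all muscle activations; optionally rescaled by
#' `92 / n` (see [reward_spec()]).
#'
#' @param activations per-muscle activations in `[0, 1]`.
#' @param normalize logical, exponent rescaling.
#' @return value in `(0, 1]`.
#' @export
r_activation <- function(activations, normalize = FALSE) {
  if (any(activations < 0 | activations > 1))
    stop("activations must lie in [0, 1]")
  s <- sum(activations^2)
  if (normalize) s <- s * 92 / length(activations)
  exp(-s)
}

#' Joint-stiffness-target reward
#'
#' `exp(-sum_j (S_target_j - S_j)^2)` over hip, knee and ankle; both the
#' measured and target stiffness must carry the same unit.
#'
#' @param S named measured stiffness `c(hip=, knee=, ankle=)`.
#' @param S_target named targets on the same scale.
#' @param unit,target_unit unit tags; a mismatch is an error.
#' @return value in `(0, 1]`.
#' @export
r_stiffness <- function(S, S_target, unit = "Nm/deg", target_unit = unit) {
  if (!identical(unit, target_unit))
    stop("stiffness unit mismatch: measured in ", unit, ", target in ",
         target_unit)
  j <- c("hip", "knee", "ankle")
  if (!all(j %in% names(S)) || !all(j %in% names(S_target)))
    stop("S and S_target must be named with hip, knee, ankle")
  exp(-sum((S_target[j] - S[j])^2))
}

#' Total shaped reward
#'
#' `w_track * r_track + w_A * r_A + w_S * r_S` with the variant's weights.
#' `S` may be omitted when `w_S = 0`.
#'
#' @param spec a [reward_spec()].
#' @param errors tracking errors (see [tracking_subreward()]).
#' @param activations per-muscle activations.
#' @param S named measured joint stiffness in the spec's unit (hip, knee,
#'   ankle), required when the variant has `w_S > 0`.
#' @return list with `total` and the components `r_track`, `r_A`, `r_S`.
#' @export
r_total <- function(spec, errors, activations, S = NULL) {
  w <- spec$weights
  rt <- r_track(errors, spec)
  ra <- if (w[["A"]] > 0)
    r_activation(activations, spec$normalize_activation) else 0
  rs <- if (w[["S"]] > 0) {
    if (is.null(S)) stop("variant ", spec$variant, " needs measured stiffness")
    r_stiffness(S, spec$s_target, unit = spec$stiffness_unit)
  } else 0
  list(total = w[["track"]] * rt + w[["A"]] * ra + w[["S"]] * rs,
       r_track = rt, r_A = ra, r_S = rs)
}

# Tracking errors of a simulator state against the reference at time t.
# step_out supplies the actual COM and end-effector positions (as returned by
# the simulator step); ref_frame is a reference_motion lookup at t.
tracking_errors <- function(model, ref_frame, state, com, eff) {
  nj <- length(joint_names(model))
  th <- state[4:(3 + nj)]
  thd <- state[(3 + nj + 4):(3 + nj + 3 + nj)]
  list(ang = ref_frame$theta - th,
       vel = ref_frame$theta_dot - thd,
       end = ref_frame$eff - eff,
       com = ref_frame$com - com)
}
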
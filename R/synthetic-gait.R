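# Synthetic periodic reference gait and EMG-like activation fixtures.
#
# Stands in for motion-capture input: sagittal joint-angle trajectories are
# built from normative gait curves (hip ~30 deg flexion / 10 deg extension,
# knee 0-60 deg flexion with loading and swing peaks, ankle -15/+10 deg),
# band-limited to at most four Fourier harmonics so velocities are exact
# spectral derivatives, with the left leg in antiphase. The pelvis height is
# chosen per frame so the lower foot just grazes the ground, which makes the
# center-of-mass and end-effector trajectories (computed by forward
# kinematics) mutually consistent with the angles.

# Periodic raised-cosine bump centred at phase c with full width w.
phase_bump <- function(phi, c, w, A) {
  d <- (phi - c) %% 1
  d[d > 0.5] <- d[d > 0.5] - 1
  ifelse(abs(d) < w / 2, A * 0.5 * (1 + cos(2 * pi * d / w)), 0)
}

# Project a periodic sample vector (n points over one cycle, no endpoint)
# onto its first K harmonics; returns the smoothed series and its exact time
# derivative for cycle duration T.
fourier_project <- function(y, K, T) {
  n <- length(y)
  Y <- fft(y) / n
  k <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1))
  keep <- abs(k) <= K
  Yk <- ifelse(keep, Y, 0)
  ys <- Re(fft(Yk, inverse = TRUE))
  dYk <- Yk * (2i * pi * k / T)
  dys <- Re(fft(dYk, inverse = TRUE))
  list(y = ys, dy = dys)
}

#' Generate a synthetic periodic reference gait
#'
#' @param model a `walker_model` (geometry for the kinematic consistency of
#'   pelvis height, COM and end-effectors).
#' @param speed walking speed (m/s, default 1.34).
#' @param cycle_duration gait-cycle duration (s, default 1.1).
#' @param hz sampling rate (default 100).
#' @param seed optional integer; adds small seeded harmonic perturbations so
#'   distinct references can be generated (0 perturbation when `NULL`).
#' @param harmonics number of Fourier harmonics retained (<= 4 by default).
#' @return object of class `reference_motion`: `time` (one cycle, endpoint
#'   included), `theta` / `theta_dot` (n x 6 matrices, rad and rad/s, columns
#'   in model joint order), `base` (n x 3: within-cycle x offset, pelvis
#'   height, trunk pitch), `base_dot`, `com` / `eff_*` trajectories relative
#'   to the cycle-average forward translation, `cycle_duration`, `speed`.
#' @export
synthetic_reference_gait <- function(model, speed = 1.34, cycle_duration = 1.1,
                                     hz = 100, seed = NULL, harmonics = 4) {
  if (speed <= 0 || cycle_duration <= 0)
    stop("speed and cycle_duration must be > 0")
  T <- cycle_duration
  n <- max(8L, round(T * hz))
  phi <- (seq_len(n) - 1) / n
  deg <- pi / 180

  leg_len <- model$standing_height
  if (speed * T > 2 * leg_len)
    warning("stride length ", speed * T, " m exceeds twice the leg length")

  pert <- if (is.null(seed)) c(0, 0, 0) else
    with_seed(seed, function() runif(3, -1.5, 1.5))

  hip <- (10 + (20 + pert[1]) * cos(2 * pi * phi) + 2 * sin(4 * pi * phi)) * deg
  knee <- (5 + phase_bump(phi, 0.15, 0.35, 16 + pert[2]) +
             phase_bump(phi, 0.72, 0.42, 55 + pert[3])) * deg
  ankle <- (phase_bump(phi, 0.42, 0.5, 10) -
              phase_bump(phi, 0.62, 0.24, 24)) * deg
  pitch <- 0.06 + 0.01 * sin(4 * pi * phi)

  sm <- lapply(list(hip = hip, knee = knee, ankle = ankle, pitch = pitch),
               fourier_project, K = harmonics, T = T)
  shift <- function(v) c(v[(n %/% 2 + 1):n], v[seq_len(n %/% 2)])

  jn <- joint_names(model)
  theta <- cbind(sm$hip$y, sm$knee$y, sm$ankle$y,
                 shift(sm$hip$y), shift(sm$knee$y), shift(sm$ankle$y))
  theta_dot <- cbind(sm$hip$dy, sm$knee$dy, sm$ankle$dy,
                     shift(sm$hip$dy), shift(sm$knee$dy), shift(sm$ankle$dy))
  colnames(theta) <- colnames(theta_dot) <- jn

  # pelvis height: lower foot-sphere bottom exactly on the ground
  core <- model_core(model)
  cs <- model$contact_spheres
  segmap <- setNames(seq_len(nrow(model$segments)) - 1L, model$segments$name)
  drop_y <- vapply(seq_len(n), function(i) {
    q <- c(0, 0, sm$pitch$y[i], theta[i, ])
    pts <- cpp_points_world(core, q, as.integer(segmap[cs$segment]),
                            rbind(cs$x, cs$y))
    min(pts[2, ] - cs$radius)
  }, numeric(1))
  # soften the vertical excursion toward the physiologic ~2-3 cm pelvis
  # oscillation; the compliant contact absorbs the residual mismatch
  y_raw <- -drop_y
  y_raw <- mean(y_raw) + 0.6 * (y_raw - mean(y_raw))
  base_y <- fourier_project(y_raw, harmonics, T)

  time <- (seq_len(n + 1) - 1) * (T / n)
  wrap <- c(seq_len(n), 1L)

  base <- cbind(x = numeric(n + 1), y = base_y$y[wrap], pitch = sm$pitch$y[wrap])
  base_dot <- cbind(x = rep(speed, n + 1), y = base_y$dy[wrap],
                    pitch = sm$pitch$dy[wrap])

  # COM and end-effector trajectories, relative to the forward translation
  eff <- model$effectors
  com <- matrix(0, n, 2)
  eff_pts <- array(0, c(2, nrow(eff), n))
  for (i in seq_len(n)) {
    q <- c(0, base_y$y[i], sm$pitch$y[i], theta[i, ])
    com[i, ] <- cpp_com(core, q, numeric(length(q)))$com
    eff_pts[, , i] <- cpp_points_world(core, q, as.integer(segmap[eff$segment]),
                                       rbind(eff$x, eff$y))
  }

  structure(list(
    time = time, theta = theta[wrap, ], theta_dot = theta_dot[wrap, ],
    base = base, base_dot = base_dot,
    com = com[wrap, ],
    eff = lapply(seq_len(nrow(eff)), function(e) t(eff_pts[, e, wrap])) |>
      setNames(eff$name),
    cycle_duration = T, speed = speed, hz = hz, n = n),
    class = "reference_motion")
}

#' Look up the reference at an absolute time
#'
#' Interpolates the periodic reference and adds the forward translation
#' `speed * t` to the x components.
#'
#' @param ref a `reference_motion`.
#' @param t absolute simulation time (s); `phase0` shifts the cycle origin.
#' @param phase0 initial phase in `[0, 1)`.
#' @return list with `theta`, `theta_dot` (length-6), `base` (x, y, pitch),
#'   `base_dot`, `com` (2), `eff` (2 x n_eff matrix), `phase`.
#' @export
ref_lookup <- function(ref, t, phase0 = 0) {
  T <- ref$cycle_duration
  phase <- ((t / T + phase0) %% 1)
  u <- phase * ref$n
  i0 <- floor(u); f <- u - i0
  i0 <- as.integer(i0) + 1L; i1 <- i0 + 1L
  lin <- function(M) {
    if (is.matrix(M)) (1 - f) * M[i0, ] + f * M[i1, ]
    else (1 - f) * M[i0] + f * M[i1]
  }
  fwd <- ref$speed * t
  eff <- vapply(ref$eff, lin, numeric(2))
  eff[1, ] <- eff[1, ] + fwd
  com <- lin(ref$com); com[1] <- com[1] + fwd
  base <- lin(ref$base); base[1] <- base[1] + fwd
  list(theta = lin(ref$theta), theta_dot = lin(ref$theta_dot),
       base = base, base_dot = lin(ref$base_dot), com = com, eff = eff,
       phase = phase)
}

#' Export a reference motion as a joint-angle table
#'
#' @param ref a `reference_motion`.
#' @param n_cycles number of cycles to tile.
#' @return data frame with `time` and one column per joint (radians).
#' @export
reference_motion_table <- function(ref, n_cycles = 1) {
  n <- ref$n
  idx <- rep(seq_len(n), n_cycles)
  t <- (seq_along(idx) - 1) * (ref$cycle_duration / n)
  data.frame(time = t, ref$theta[idx, , drop = FALSE])
}

#' Default phasic burst pattern per muscle group
#'
#' Burst centres/widths in gait phase (right-leg convention, heel strike at
#' phase 0) with amplitudes below saturation; mirrors typical on/off EMG
#' timing of walking.
#'
#' @return named list: per group a data frame of bursts (center, width,
#'   amplitude).
#' @export
default_burst_pattern <- function() {
  b <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], width = m[, 2], amplitude = m[, 3])
  }
  list(vastus = b(0.08, 0.25, 0.45),
       other = b(0.55, 0.25, 0.25),
       biceps_femoris = b(0.95, 0.25, 0.40),
       semitendinosus = b(0.93, 0.25, 0.35),
       tibialis_anterior = b(0.65, 0.25, 0.35, 0.02, 0.18, 0.30),
       soleus = b(0.35, 0.35, 0.55),
       gastrocnemius = b(0.33, 0.35, 0.50))
}

#' Generate EMG-like synthetic activation traces
#'
#' Per-muscle activations are sums of smooth raised-cosine bursts placed by
#' the group pattern (left-side muscles shifted half a cycle), plus optional
#' truncated Gaussian noise, clipped to `[0, 1]`.
#'
#' @param model a `walker_model` (muscle names and group tags), or `NULL`
#'   with `groups` given explicitly.
#' @param pattern burst pattern, see [default_burst_pattern()].
#' @param noise_sd Gaussian noise standard deviation (activation units).
#' @param seed integer seed for the noise.
#' @param cycle_duration gait-cycle duration (s).
#' @param n_cycles number of cycles.
#' @param hz sampling rate.
#' @param groups named character vector muscle -> group (defaults to
#'   [muscle_groups()] of the model).
#' @param baseline tonic activation added to every trace (default 0.02).
#' @return data frame: `time` plus one activation column per muscle.
#' @export
synthetic_activation_traces <- function(model = NULL,
                                        pattern = default_burst_pattern(),
                                        noise_sd = 0, seed = NULL,
                                        cycle_duration = 1.1, n_cycles = 1,
                                        hz = 100, groups = NULL,
                                        baseline = 0.02) {
  groups <- groups %||% muscle_groups(model)
  for (p in pattern)
    if (any(p$amplitude > 1)) stop("burst amplitude exceeds 1")
  n <- round(cycle_duration * hz) * n_cycles
  t <- (seq_len(n) - 1) / hz
  phi <- (t %% cycle_duration) / cycle_duration
  out <- data.frame(time = t)
  noise <- if (noise_sd > 0)
    with_seed(seed, function()
      matrix(rnorm(n * length(groups), 0, noise_sd), n)) else NULL
  for (k in seq_along(groups)) {
    nm <- names(groups)[k]
    pg <- pattern[[groups[[k]]]]
    if (is.null(pg)) stop("no burst pattern for group '", groups[[k]], "'")
    ph <- if (grepl("_l$", nm)) (phi + 0.5) %% 1 else phi
    a <- rep(baseline, n)
    for (bi in seq_len(nrow(pg)))
      a <- a + phase_bump(ph, pg$center[bi], pg$width[bi], pg$amplitude[bi])
    if (!is.null(noise)) a <- a + noise[, k]
    out[[nm]] <- pmin(1, pmax(0, a))
  }
  out
}
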
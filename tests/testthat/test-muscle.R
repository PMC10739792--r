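# Hill-type MTU: activation dynamics, dimensionless curves, equilibrium solve.

test_that("activation dynamics: fixed point, saturation rise, first-order decay", {
  p <- mtu_params(F0 = 100, l_opt = 0.1, l_slack = 0.2,
                  tau_act = 0.01, tau_deact = 0.04)
  expect_equal(activation_step(0.5, 0.5, 0.01, p), 0.5)
  # rise toward saturation: the rise time constant grows with activation
  # (tau_act * (0.5 + 1.5 a)), so 5 nominal time constants reach ~0.96 and
  # ten reach beyond 0.99
  expect_gt(activation_step(1, 0, 0.05, p), 0.95)
  expect_gt(activation_step(1, 0, 0.10, p), 0.99)
  # decay toward 0 from a = 1: the scaled time constant tau_deact/(0.5+1.5a)
  # starts at 0.02 s, so one 0.04 s step decays well below exp(-1)
  a1 <- activation_step(0, 1, 0.04, p)
  expect_lt(a1, exp(-1))
  expect_gt(a1, 0)
  # reference solution of the same ODE on a fine grid
  fine <- 1
  for (i in 1:4000) fine <- fine + 1e-5 * (0 - fine) / (0.04 / (0.5 + 1.5 * fine))
  expect_equal(a1, fine, tolerance = 2e-2)
})

test_that("activation update is a contraction toward the excitation", {
  p <- mtu_params(F0 = 1, l_opt = 0.1, l_slack = 0.1)
  set.seed(11)
  for (i in 1:50) {
    u <- runif(1); a <- runif(1); dt <- runif(1, 1e-4, 0.2)
    a2 <- activation_step(u, a, dt, p)
    expect_lte(abs(a2 - u), abs(a - u) + 1e-12)
    expect_true(a2 >= 0 && a2 <= 1)
  }
  expect_error(activation_step(0.5, 0.5, 0, p), "dt")
  expect_error(activation_step(1.2, 0.5, 0.01, p), "0, 1")
})

test_that("curve landmarks match their defining values", {
  expect_equal(evaluate_curves("active_fl", 1), 1)
  expect_equal(evaluate_curves("force_velocity", 0), 1)
  expect_equal(evaluate_curves("force_velocity", -1), 0)
  expect_equal(evaluate_curves("force_velocity", -1.5), 0)
  # nominal tendon strain carries exactly F0 by construction
  cc <- hill_curve_constants()
  expect_equal(evaluate_curves("tendon_fl", cc[["eps0"]]), 1)
  expect_equal(evaluate_curves("tendon_fl", 0), 0)
  expect_equal(evaluate_curves("passive_fl", 0.9), 0)
  expect_equal(evaluate_curves("passive_fl", 1 + cc[["e0_pass"]]), 1,
               tolerance = 1e-12)
  expect_error(evaluate_curves("nope", 1), "unknown curve kind")
})

test_that("curve shapes: bounds, monotonicity, eccentric plateau, continuity", {
  x <- seq(0.3, 1.8, by = 1e-3)
  afl <- evaluate_curves("active_fl", x)
  expect_true(all(afl >= 0 & afl <= 1))
  expect_equal(x[which.max(afl)], 1, tolerance = 2e-3)
  fv <- evaluate_curves("force_velocity", seq(-1.2, 3, by = 1e-3))
  expect_true(all(fv >= 0 & fv <= 1.4))
  expect_true(all(diff(fv) >= -1e-12))
  eps <- seq(1e-6, 0.12, by = 1e-4)
  tf <- evaluate_curves("tendon_fl", eps)
  expect_true(all(diff(tf) > 0))
  # continuity across the piecewise joins: jumps bounded by a Lipschitz
  # constant times the grid step, over each curve's working range
  ranges <- list(active_fl = c(0.2, 1.9), passive_fl = c(0.5, 1.7),
                 force_velocity = c(-1.3, 2.5), tendon_fl = c(-0.02, 0.12))
  for (kind in names(ranges)) {
    g <- seq(ranges[[kind]][1], ranges[[kind]][2], by = 1e-4)
    y <- evaluate_curves(kind, g)
    expect_lt(max(abs(diff(y))), 30 * 1e-4)
  }
})

test_that("rigid-tendon isometric optimum gives F0 cos(pennation)", {
  for (penn in c(0, 0.15, 0.4)) {
    p <- mtu_params(F0 = 2500, l_opt = 0.11, l_slack = 0.24, pennation = penn)
    eq <- solve_mtu_equilibrium(p, p$l_opt * cos(penn) + p$l_slack,
                                mtu_velocity = 0, a = 1, rigid_tendon = TRUE)
    expect_equal(eq$force, p$F0 * cos(penn), tolerance = 1e-3 * p$F0)
    expect_equal(eq$fiber_length, p$l_opt, tolerance = 1e-9)
  }
})

test_that("slack MTU carries no force", {
  p <- mtu_params(F0 = 1000, l_opt = 0.1, l_slack = 0.2)
  eq <- solve_mtu_equilibrium(p, 0.25, 0, a = 0)
  expect_equal(eq$force, 0)
  expect_lte(eq$fiber_length, p$l_opt + 1e-9)
})

test_that("equilibrium residual vanishes on a randomized grid", {
  set.seed(4)
  p <- mtu_params(F0 = 3000, l_opt = 0.1, l_slack = 0.25)
  for (i in 1:60) {
    L <- runif(1, 0.32, 0.40)
    a <- runif(1)
    eq <- solve_mtu_equilibrium(p, L, 0, a)
    expect_lt(abs(eq$residual), 1e-6 * p$F0)
    expect_gte(eq$force, 0)
  }
})

test_that("velocity ordering: concentric < isometric < eccentric force", {
  p <- mtu_params(F0 = 2000, l_opt = 0.1, l_slack = 0.22, v_max = 10)
  set.seed(5)
  for (i in 1:25) {
    L <- runif(1, 0.335, 0.36)
    a <- runif(1, 0.3, 1)
    fc <- solve_mtu_equilibrium(p, L, -0.3, a)$force  # shortening
    f0 <- solve_mtu_equilibrium(p, L, 0, a)$force
    fe <- solve_mtu_equilibrium(p, L, 0.3, a)$force   # lengthening
    expect_lt(fc, f0)
    expect_lt(f0, fe)
  }
})

test_that("mtu_stiffness: series combination and limits", {
  p <- mtu_params(F0 = 1000, l_opt = 0.1, l_slack = 0.2)
  # pure series arithmetic: equal springs halve
  ks <- list(K_M = 2, K_T = 2)
  expect_equal(1 / (1 / ks$K_M + 1 / ks$K_T), 1)
  # stiff-tendon limit: K_MTU -> K_M within 1%
  eq <- solve_mtu_equilibrium(p, 0.315, 0, 0.8)
  st <- list(fiber_length = eq$fiber_length, activation = 0.8,
             mtu_length = 0.315, fiber_velocity = 0)
  ks1 <- mtu_stiffness(p, st)
  p2 <- mtu_params(F0 = 1000, l_opt = 0.1, l_slack = 1e-4)
  eq2 <- solve_mtu_equilibrium(p2, eq$fiber_length + 1e-4 * (1 + 0.02), 0, 0.8)
  st2 <- list(fiber_length = eq2$fiber_length, activation = 0.8,
              mtu_length = eq2$fiber_length + 1e-4 * 1.02, fiber_velocity = 0)
  ks2 <- mtu_stiffness(p2, st2)
  expect_gt(ks2$K_T, 100 * abs(ks2$K_M))
  expect_equal(ks2$K_MTU, ks2$K_M, tolerance = 0.01 * abs(ks2$K_M))
  # K_MTU never exceeds either element (positive-stiffness regime)
  if (ks1$K_M > 0) {
    expect_lte(ks1$K_MTU, min(ks1$K_M, ks1$K_T) + 1e-9)
  }
})

test_that("fiber stiffness matches finite difference of fiber force", {
  p <- mtu_params(F0 = 1500, l_opt = 0.12, l_slack = 0.2)
  cc <- hill_curve_constants()
  set.seed(6)
  for (i in 1:20) {
    a <- runif(1, 0.1, 1)
    lf <- runif(1, 0.09, 0.15)
    fib_force <- function(l) {
      lt <- l / p$l_opt
      p$F0 * (a * evaluate_curves("active_fl", lt, cc) +
                evaluate_curves("passive_fl", lt, cc))
    }
    h <- 1e-6
    fd <- (fib_force(lf + h) - fib_force(lf - h)) / (2 * h)
    ks <- mtu_stiffness(p, list(fiber_length = lf, activation = a,
                                mtu_length = lf + p$l_slack * 1.01,
                                fiber_velocity = 0), cc)
    expect_equal(ks$K_M, fd, tolerance = 1e-4 * max(1, abs(fd)))
  }
})
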
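# Forward dynamics: conservation sanity, pendulum oracle, contact laws,
# episode bookkeeping and determinism.

test_that("a free body in zero gravity keeps its velocities", {
  m0 <- build_planar_model(list(gravity = 0))
  st <- sim_state_init(m0, activations = 0)
  st[2] <- 3  # well above ground
  out <- sim_step(m0, flat_terrain, st, rep(0, 18), n_substeps = 100)
  expect_lt(max(abs(out$state[10:18])), 1e-10)
})

test_that("passive pendulum matches the closed-form small-oscillation period", {
  pm <- pendulum_model(mass = 2, length = 0.5, com_frac = 0.5, rog_frac = 0.3)
  core <- planargait:::model_core(pm)
  tc <- planargait:::terrain_core(flat_terrain)
  st <- sim_state_init(pm, activations = 0)
  st[4] <- 0.08
  th <- numeric(6000)
  s <- st
  for (k in seq_along(th)) {
    s <- planargait:::cpp_step(core, tc, s, 0, 1L, 1e-3)$state
    th[k] <- s[4]
  }
  zc <- which(diff(sign(th)) > 0)
  period <- mean(diff(zc)) * 1e-3
  d <- 0.5 * 0.5
  I_o <- 2 * (0.3 * 0.5)^2 + 2 * d^2
  T_exact <- 2 * pi * sqrt(I_o / (2 * 9.81 * d))
  expect_equal(period, T_exact, tolerance = 0.02)
})

test_that("contact complementarity and the static-support oracle", {
  bm <- block_model(mass = 5, radius = 0.05)
  core <- planargait:::model_core(bm)
  tc <- planargait:::terrain_core(flat_terrain)
  # above ground: all forces zero
  cf <- contact_forces(sim_state_init(bm, q = c(0, 1, 0)), flat_terrain, bm)
  expect_true(all(cf$spheres$normal == 0))
  expect_true(all(cf$spheres$friction == 0))
  expect_true(all(is.na(cf$cop)))
  # let the block settle; the normal force balances the weight
  s <- sim_state_init(bm, q = c(0, 0.15, 0))
  for (k in 1:200) {
    out <- planargait:::cpp_step(core, tc, s, 0, 10L, 1e-3)
    s <- out$state
  }
  expect_equal(out$spheres[1, 1], 5 * 9.81, tolerance = 0.02 * 5 * 9.81)
  # force only with penetration
  cf2 <- contact_forces(s, flat_terrain, bm)
  expect_true(all((cf2$spheres$normal > 0) == (cf2$spheres$penetration > 0)))
})

test_that("sliding friction saturates the cone and opposes slip", {
  bm <- block_model(mass = 5, radius = 0.05)
  core <- planargait:::model_core(bm)
  tc <- planargait:::terrain_core(flat_terrain)
  s <- sim_state_init(bm, q = c(0, 0.15, 0))
  for (k in 1:100) s <- planargait:::cpp_step(core, tc, s, 0, 10L, 1e-3)$state
  s[4] <- 0.8  # push it sideways
  out <- planargait:::cpp_step(core, tc, s, 0, 1L, 1e-3)
  N <- out$spheres[1, 1]; ft <- out$spheres[1, 2]
  expect_gt(N, 0)
  expect_equal(abs(ft), 0.8 * N, tolerance = 1e-6 * N)
  expect_lt(ft, 0)  # opposes +x slip
})

test_that("friction cone holds on every logged frame of a walking episode", {
  pol <- tracking_policy(walker, walker_ref)
  ep <- simulate_episode(pol, walker, flat_terrain, walker_ref,
                         duration = 3, seed = 2, init_phase = 0.2)
  mu <- 0.8
  expect_true(all(abs(ep$grf[, 1]) <= mu * ep$grf[, 2] + 1e-9))
  expect_true(all(abs(ep$grf[, 3]) <= mu * ep$grf[, 4] + 1e-9))
})

test_that("zero-excitation walker collapses quickly", {
  ep <- simulate_episode(constant_policy(0), walker, flat_terrain, walker_ref,
                         duration = 4, seed = 1, init_phase = 0, record = FALSE)
  expect_false(ep$survived)
  expect_lt(ep$fall_time, 2)
})

test_that("standing fixture policy keeps the walker upright beyond 2 s", {
  pol <- stand_policy(walker)
  st <- sim_state_init(walker, activations = pol$u0, q = pol$q0)
  ep <- simulate_episode(pol, walker, flat_terrain, walker_ref,
                         duration = 4, seed = 1, init_state = st,
                         record = FALSE)
  t_up <- if (ep$survived) 4 else ep$fall_time
  expect_gte(t_up, 2)
})

test_that("episodes are bit-identical under a fixed seed", {
  pol <- tracking_policy(walker, walker_ref)
  e1 <- simulate_episode(pol, walker, flat_terrain, walker_ref, duration = 1.5,
                         seed = 42, init_phase = "random")
  e2 <- simulate_episode(pol, walker, flat_terrain, walker_ref, duration = 1.5,
                         seed = 42, init_phase = "random")
  expect_identical(e1$q, e2$q)
  expect_identical(e1$act, e2$act)
  expect_identical(e1$phase0, e2$phase0)
})

test_that("episode records carry consistent logs and heel strikes", {
  pol <- tracking_policy(walker, walker_ref)
  ep <- simulate_episode(pol, walker, flat_terrain, walker_ref,
                         duration = 3, seed = 3, init_phase = 0.3)
  n <- length(ep$time)
  expect_equal(nrow(ep$q), n)
  expect_equal(nrow(ep$act), n)
  expect_true(all(ep$act >= 0 & ep$act <= 1))
  expect_identical(ep$survived, !ep$fell)
  if (nrow(ep$heel_strikes) >= 2) {
    per_foot <- split(ep$heel_strikes$time, ep$heel_strikes$foot)
    for (tt in per_foot)
      if (length(tt) > 1) expect_true(all(diff(tt) > 0.1))
  }
  tb <- episode_tables(ep)
  expect_equal(names(tb$motion), c("time", joint_names(walker)))
})

test_that("excitations out of range are clipped and counted", {
  out <- sim_step(walker, flat_terrain, sim_state_init(walker),
                  c(rep(1.8, 9), rep(-0.5, 9)))
  expect_equal(out$clipped, 18)
  expect_true(all(out$state[19 + 1:18] <= 1))
})

test_that("NaN states are rejected with a diagnostic", {
  st <- sim_state_init(walker)
  st[5] <- NaN
  expect_error(sim_step(walker, flat_terrain, st, rep(0, 18)),
               "non-finite")
})
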
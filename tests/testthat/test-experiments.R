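# Survival experiments, heel-strike metrics, kinematics RMSD and the
# comparison statistics.

test_that("kinematics RMSD: identity, constant offset, phase shift", {
  mot <- reference_motion_table(walker_ref)
  expect_equal(unname(kinematics_rmsd(mot, mot)), rep(0, 6))
  off <- mot
  off$knee_r <- off$knee_r + 2 * pi / 180
  r <- kinematics_rmsd(off, mot)
  expect_equal(unname(r["knee_r"]), 2, tolerance = 1e-9)
  expect_equal(unname(r["hip_r"]), 0)
  # phase-shifted sinusoid: rmsd = A * sqrt(2 - 2 cos(phi)) / sqrt(2)
  t <- seq(0, 1, length.out = 400)
  A <- 0.3; phi <- 0.7
  a <- data.frame(time = t, j = A * sin(2 * pi * t))
  b <- data.frame(time = t, j = A * sin(2 * pi * t + phi))
  expected <- A * sqrt(1 - cos(phi)) * 180 / pi
  expect_equal(unname(kinematics_rmsd(a, b, n_points = 400)["j"]), expected,
               tolerance = 1e-2)
  expect_error(kinematics_rmsd(data.frame(time = t, x = t),
                               data.frame(time = t, y = t)), "shared joint")
})

test_that("Pearson chi-squared matches the textbook formula", {
  tb <- rbind(a = 90, b = 10)
  res <- survival_chi_squared(rbind(a = 90, b = 10), n_trials = 100)
  # hand-computed Pearson statistic for 90/10 vs 10/90 out of 100
  O <- matrix(c(90, 10, 10, 90), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$omnibus$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$omnibus$df, 1)
  expect_lt(res$omnibus$p, 1e-10)
})

test_that("identical survival rates give a null omnibus and capped pairwise", {
  res <- survival_chi_squared(rbind(a = 40, b = 40, c = 40), n_trials = 100)
  expect_equal(res$omnibus$statistic, 0)
  expect_equal(res$omnibus$p, 1)
  expect_equal(res$n_pairs, 3)
  expect_true(all(res$pairwise$p_adjusted ==
                    pmin(1, res$pairwise$p_raw * 3)))
  # degenerate margins route to the exact-test fallback
  expect_error(survival_chi_squared(rbind(a = 0, b = 0), n_trials = 10),
               "exact")
  ex <- survival_chi_squared(rbind(a = 0, b = 0), n_trials = 10, exact = TRUE)
  expect_equal(ex$omnibus$p, 1)
})

test_that("one-way ANOVA matches the hand-computed F", {
  vals <- list(A = c(30, 32, 34), B = c(40, 41, 45))
  res <- coactivation_anova(vals)
  y <- unlist(vals); g <- rep(c("A", "B"), each = 3)
  grand <- mean(y)
  ssb <- sum(3 * (tapply(y, g, mean) - grand)^2)
  ssw <- sum((y - ave(y, g))^2)
  Fhand <- (ssb / 1) / (ssw / 4)
  expect_equal(res$omnibus$F, Fhand, tolerance = 1e-10)
  expect_equal(res$omnibus$p, pf(Fhand, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(res$omnibus$degenerate)
  # degenerate: all groups identical constants
  resd <- coactivation_anova(list(A = c(5, 5), B = c(5, 5)))
  expect_equal(resd$omnibus$p, 1)
  expect_true(resd$omnibus$degenerate)
  expect_error(coactivation_anova(list(A = 1)), "at least 2")
})

test_that("ANOVA p-values are calibrated under the null", {
  set.seed(55)
  ps <- replicate(200, {
    coactivation_anova(list(a = rnorm(6), b = rnorm(6),
                            c = rnorm(6)))$omnibus$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("heel-strike metrics reduce to the scripted geometry", {
  ep <- structure(list(heel_strikes = data.frame(
    time = c(1, 2), foot = c("right", "left"),
    com_x = c(3.0, 3.6), cop_x = c(3.0, 3.45),
    foot_angle_deg = c(0, 12))), class = "episode_record")
  hm <- heel_strike_metrics(ep)
  expect_equal(hm$stability_margin, c(0, 0.15))
  expect_equal(hm$foot_angle_deg, c(0, 12))
  empty <- structure(list(heel_strikes = data.frame()),
                     class = "episode_record")
  expect_warning(h0 <- heel_strike_metrics(empty), "no heel strikes")
  expect_equal(nrow(h0), 0)
})

test_that("foot angle is zero for a flat foot and positive toes-up", {
  q <- default_q(walker)
  expect_equal(planargait:::foot_world_angle(walker, q, "right"), 0)
  q2 <- q
  q2[3 + 3] <- 0.2  # ankle dorsiflexion lifts the toes
  expect_gt(planargait:::foot_world_angle(walker, q2, "right"), 0)
})

test_that("survival tables: shape, determinism, degenerate terrain", {
  pols <- list(zero = constant_policy(0),
               track = tracking_policy(walker, walker_ref))
  tb <- run_slip_experiment(pols, mu_list = c(0.2, 0.4), n_trials = 2,
                            model = walker, ref = walker_ref, seed = 5,
                            duration = 2)
  expect_equal(dim(tb$survivals), c(2, 2))
  expect_true(all(tb$survivals >= 0 & tb$survivals <= 2))
  expect_equal(unname(tb$survivals["zero", ]), c(0L, 0L))
  tb2 <- run_slip_experiment(pols, mu_list = c(0.2, 0.4), n_trials = 2,
                             model = walker, ref = walker_ref, seed = 5,
                             duration = 2)
  expect_identical(tb$survivals, tb2$survivals)
  # a zero height scale reproduces flat-ground outcomes for the same seeds
  tu <- run_uneven_experiment(pols["track"], height_scales = c(0),
                              n_trials = 2, model = walker, ref = walker_ref,
                              seed = 5, duration = 2)
  flat_ep <- simulate_episode(pols$track, walker, flat_terrain, walker_ref,
                              duration = 2,
                              seed = planargait:::derive_seed(5, 1))
  expect_equal(unname(tu$survivals[1, 1]),
               as.integer(flat_ep$survived) +
                 as.integer(simulate_episode(pols$track, walker, flat_terrain,
                                             walker_ref, duration = 2,
                                             seed = planargait:::derive_seed(5, 2))$survived))
})
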
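# Synthetic reference gait and EMG-like activation fixtures.

test_that("reference motion satisfies its structural invariants", {
  ref <- walker_ref
  n <- nrow(ref$theta)
  # periodic: endpoint row equals the first
  expect_equal(ref$theta[n, ], ref$theta[1, ], tolerance = 1e-12)
  expect_equal(ref$base[n, ], ref$base[1, ], tolerance = 1e-12)
  # spectral velocities agree with finite differences to 2% RMS
  dt <- diff(ref$time[1:2])
  for (j in 1:6) {
    fd <- diff(ref$theta[, j]) / dt
    mid <- (ref$theta_dot[-n, j] + ref$theta_dot[-1, j]) / 2
    expect_lt(sqrt(mean((fd - mid)^2)) / max(sqrt(mean(mid^2)), 1e-9), 0.02)
  }
  # speed is the forward COM displacement per cycle by construction
  expect_equal(ref$speed, 1.34)
  expect_equal(ref$cycle_duration, 1.1)
})

test_that("left leg is the right leg shifted by half a cycle", {
  ref <- walker_ref
  n <- ref$n
  half <- n / 2
  for (pair in list(c("hip_r", "hip_l"), c("knee_r", "knee_l"),
                    c("ankle_r", "ankle_l"))) {
    r <- ref$theta[seq_len(n), pair[1]]
    l <- ref$theta[seq_len(n), pair[2]]
    expect_equal(l, r[((seq_len(n) - 1 + half) %% n) + 1], tolerance = 1e-9)
  }
})

test_that("normative sagittal amplitudes and ground contact", {
  ref <- walker_ref
  deg <- 180 / pi
  hip <- ref$theta[, "hip_r"] * deg
  knee <- ref$theta[, "knee_r"] * deg
  ankle <- ref$theta[, "ankle_r"] * deg
  expect_gt(max(hip), 20); expect_lt(min(hip), 0)
  expect_gt(max(knee), 45); expect_gt(min(knee), -10); expect_lt(max(knee), 75)
  expect_lt(min(ankle), -8); expect_gt(max(ankle), 4)
  # each foot grazes the ground at least once per cycle
  core <- planargait:::model_core(walker)
  cs <- walker$contact_spheres
  segmap <- setNames(seq_len(nrow(walker$segments)) - 1L,
                     walker$segments$name)
  for (side in c("right", "left")) {
    sel <- cs$foot == side
    minh <- vapply(seq_len(ref$n), function(i) {
      q <- c(0, ref$base[i, 2], ref$base[i, 3], ref$theta[i, ])
      pts <- planargait:::cpp_points_world(core, q,
                                           as.integer(segmap[cs$segment[sel]]),
                                           rbind(cs$x[sel], cs$y[sel]))
      min(pts[2, ] - cs$radius[sel])
    }, numeric(1))
    expect_lt(min(abs(minh)), 0.005)
  }
})

test_that("generator is deterministic per seed and warns on absurd stride", {
  r1 <- synthetic_reference_gait(walker, seed = 5)
  r2 <- synthetic_reference_gait(walker, seed = 5)
  expect_identical(r1$theta, r2$theta)
  r3 <- synthetic_reference_gait(walker, seed = 6)
  expect_false(identical(r1$theta, r3$theta))
  expect_warning(synthetic_reference_gait(walker, speed = 3, cycle_duration = 1.5),
                 "stride")
  expect_error(synthetic_reference_gait(walker, speed = -1), "> 0")
})

test_that("reference lookup tiles cycles with forward translation", {
  ref <- walker_ref
  f0 <- ref_lookup(ref, 0.25)
  f1 <- ref_lookup(ref, 0.25 + ref$cycle_duration)
  expect_equal(f1$theta, f0$theta, tolerance = 1e-12)
  expect_equal(f1$com[1] - f0$com[1], ref$speed * ref$cycle_duration,
               tolerance = 1e-9)
  expect_equal(f1$com[2], f0$com[2], tolerance = 1e-12)
})

test_that("activation fixtures: bounds, determinism, burst structure", {
  a0 <- synthetic_activation_traces(walker, noise_sd = 0)
  vals <- as.matrix(a0[-1])
  expect_true(all(vals >= 0 & vals <= 1))
  a1 <- synthetic_activation_traces(walker, noise_sd = 0.05, seed = 9)
  a2 <- synthetic_activation_traces(walker, noise_sd = 0.05, seed = 9)
  expect_identical(a1, a2)
  expect_false(identical(a1, synthetic_activation_traces(walker,
                                                         noise_sd = 0.05,
                                                         seed = 10)))
  bad <- default_burst_pattern()
  bad$vastus$amplitude[1] <- 1.2
  expect_error(synthetic_activation_traces(walker, pattern = bad), "exceeds 1")
})

test_that("identical and disjoint burst specs bracket the CI range", {
  groups <- c(a1 = "vastus", a2 = "vastus", b1 = "soleus")
  pat <- default_burst_pattern()
  same <- synthetic_activation_traces(groups = groups, pattern = pat)
  expect_equal(brute_ci(same$a1, same$a2), 100)
  # stance-only vs swing-only bursts barely overlap
  pat2 <- list(stance = data.frame(center = 0.2, width = 0.3, amplitude = 0.6),
               swing = data.frame(center = 0.75, width = 0.3, amplitude = 0.6))
  two <- synthetic_activation_traces(groups = c(x = "stance", y = "swing"),
                                     pattern = pat2, baseline = 0)
  expect_lt(brute_ci(two$x, two$y), 5)
})
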
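# Moment arms, series MTU stiffness and the analytic joint-stiffness chain,
# each checked against an independent finite-difference oracle.

test_that("a muscle confined to one segment has zero moment arm everywhere", {
  res <- mtu_length_and_moment_arm(pendulum_model(), "dummy", 0.3)
  expect_equal(unname(res$r), 0)
  expect_gt(res$L, 0)
})

test_that("analytic moment arms match finite differences of the path length", {
  km <- knee_model()
  set.seed(21)
  for (i in 1:30) {
    th <- runif(1, -0.1, 2.0)
    for (mus in c("ext", "flx")) {
      r <- mtu_length_and_moment_arm(km, mus, th)$r[["knee"]]
      h <- 1e-6
      Lp <- mtu_length_and_moment_arm(km, mus, th + h)$L
      Lm <- mtu_length_and_moment_arm(km, mus, th - h)$L
      fd <- (Lp - Lm) / (2 * h)
      expect_equal(r, fd, tolerance = 1e-6 * max(1, abs(fd)))
    }
  }
})

test_that("via-point muscles on the walker agree with the same oracle", {
  set.seed(22)
  for (i in 1:10) {
    q <- c(runif(1, -0.3, 0.9), runif(1, 0, 1.5), runif(1, -0.5, 0.5),
           runif(1, -0.3, 0.9), runif(1, 0, 1.5), runif(1, -0.5, 0.5))
    for (mus in c("vastus_r", "gastroc_l", "semiten_r")) {
      r <- mtu_length_and_moment_arm(walker, mus, q)$r
      for (j in seq_along(r)) {
        qp <- q; qp[j] <- q[j] + 1e-6
        qm <- q; qm[j] <- q[j] - 1e-6
        fd <- (mtu_length_and_moment_arm(walker, mus, qp)$L -
                 mtu_length_and_moment_arm(walker, mus, qm)$L) / 2e-6
        expect_equal(unname(r[j]), fd, tolerance = 1e-6 * max(1, abs(fd)))
      }
    }
  }
})

test_that("passive joint stiffness is finite and the breakdown is complete", {
  js <- joint_stiffness(walker, rep(0.3, 6), 0, "knee_r")
  expect_true(is.finite(js$K_nm_per_rad))
  expect_equal(nrow(js$breakdown), length(walker$muscles))
  expect_equal(sum(js$breakdown$contribution), js$K_nm_per_rad)
  expect_equal(js$K_nm_per_deg, js$K_nm_per_rad * pi / 180)
  expect_true(all(js$breakdown$mtu_force >= 0))
  expect_error(joint_stiffness(walker, rep(0, 6), 0, "elbow"), "not in model")
})

test_that("analytic stiffness equals the moment finite-difference oracle", {
  # randomized antagonist geometries on the planar knee; activations frozen,
  # equilibrium re-solved at the perturbed angles
  set.seed(23)
  n_cfg <- 0
  for (rep in 1:25) {
    km <- knee_model(
      org_ext = c(runif(1, 0.02, 0.05), runif(1, -0.2, -0.1)),
      via_ext = c(runif(1, 0.04, 0.06), -0.38),
      ins_ext = c(runif(1, 0.03, 0.05), runif(1, -0.08, -0.05)),
      org_flx = c(runif(1, -0.05, -0.02), runif(1, -0.18, -0.1)),
      ins_flx = c(runif(1, -0.05, -0.02), runif(1, -0.07, -0.04)),
      F0 = runif(2, 1500, 4000), ffrac = runif(2, 0.35, 0.5))
    for (th in runif(4, 0.1, 1.4)) {
      a <- runif(2, 0.2, 0.8)
      K <- joint_stiffness(km, th, a, "knee")$K_nm_per_rad
      h <- 1e-5
      Mp <- net_muscle_moment(km, th + h, a, "knee")
      Mm <- net_muscle_moment(km, th - h, a, "knee")
      fd <- (Mp - Mm) / (2 * h)
      expect_equal(K, fd, tolerance = 1e-3 * max(1, abs(fd)))
      n_cfg <- n_cfg + 1
    }
  }
  expect_gte(n_cfg, 100)
})

test_that("co-activating an antagonist pair never decreases joint stiffness", {
  # dorsiflexor-plantarflexor pair at the ankle: short fibers on the
  # ascending limb, near-constant moment arms - the spring-like regime in
  # which co-activation stiffens the joint
  idx <- which(names(walker$muscles) %in% c("tibant_r", "soleus_r",
                                            "gastroc_r"))
  for (th in c(-0.1, 0, 0.1)) {
    q <- replace(rep(0, 6), 3, th)
    prev <- -Inf
    for (lvl in c(0.1, 0.3, 0.5, 0.7)) {
      a <- rep(0, 18); a[idx] <- lvl
      K <- joint_stiffness(walker, q, a, "ankle_r")$K_nm_per_rad
      expect_gte(K, prev - 1e-9)
      prev <- K
    }
  }
})

test_that("doubling activations increases ankle stiffness in the linear regime", {
  idx <- which(names(walker$muscles) %in% c("tibant_r", "soleus_r",
                                            "gastroc_r"))
  a1 <- rep(0, 18); a1[idx] <- 0.25
  a2 <- rep(0, 18); a2[idx] <- 0.5
  K1 <- joint_stiffness(walker, rep(0, 6), a1, "ankle_r")$K_nm_per_rad
  K2 <- joint_stiffness(walker, rep(0, 6), a2, "ankle_r")$K_nm_per_rad
  expect_gt(K2, K1)
})

test_that("cycle-average stiffness reports both unit views consistently", {
  mot <- reference_motion_table(walker_ref)[seq(1, 110, by = 10), ]
  act <- synthetic_activation_traces(walker)[seq(1, 110, by = 10), ]
  act$time <- mot$time
  res <- analyze_trial_stiffness(walker, mot, act)
  expect_equal(res$average$K_nm_per_deg,
               res$average$K_nm_per_rad * pi / 180)
  expect_equal(nrow(res$per_frame), nrow(mot))
  expect_true(all(is.finite(as.matrix(res$per_frame))))
})
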
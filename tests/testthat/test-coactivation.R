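# Coactivation index: trapezoid overlap integral, group averaging, and the
# thigh/shank report.

test_that("identical traces give 100, disjoint bursts give 0", {
  a <- c(0.1, 0.5, 0.3, 0.2)
  expect_equal(coactivation_index(a, a), 100)
  b1 <- c(0.4, 0.4, 0, 0, 0, 0)
  b2 <- c(0, 0, 0, 0, 0.3, 0.3)
  expect_equal(coactivation_index(b1, b2), 0)
})

test_that("implementation matches the brute-force trapezoid oracle", {
  a1 <- c(0.2, 0.4, 0.4)
  a2 <- c(0.1, 0.5, 0.3)
  expect_equal(coactivation_index(a1, a2), brute_ci(a1, a2),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:30) {
    x <- runif(25); y <- runif(25)
    expect_equal(coactivation_index(x, y), brute_ci(x, y), tolerance = 1e-12)
  }
})

test_that("symmetry, scale invariance, bounds and baseline monotonicity", {
  set.seed(32)
  for (i in 1:25) {
    x <- runif(40); y <- runif(40)
    ci <- coactivation_index(x, y)
    expect_true(ci >= 0 && ci <= 100)
    expect_equal(ci, coactivation_index(y, x))
    c0 <- runif(1, 0.1, 3)
    expect_equal(coactivation_index(pmin(1, c0 * x / 3), pmin(1, c0 * y / 3)),
                 coactivation_index(c0 * x / 3, c0 * y / 3))
    expect_equal(coactivation_index(c0 * x / 3, c0 * y / 3), ci,
                 tolerance = 1e-10)
    base <- runif(1, 0, 0.3)
    expect_gte(coactivation_index(x / 2 + base, y / 2 + base) + 1e-9,
               coactivation_index(x / 2, y / 2))
  }
})

test_that("degenerate and error paths behave as defined", {
  expect_warning(z <- coactivation_index(rep(0, 5), rep(0, 5)),
                 "identically zero")
  expect_equal(z, 0)
  expect_error(coactivation_index(1:3 / 3, 1:4 / 4), "mismatched")
  expect_error(group_pair_index(matrix(numeric(0), 2, 0), matrix(0.5, 2, 1)),
               "empty")
})

test_that("group index equals the enumerate-all-pairs mean", {
  set.seed(33)
  A <- matrix(runif(60), 20, 3)
  B <- matrix(runif(40), 20, 2)
  manual <- mean(sapply(1:3, function(i)
    sapply(1:2, function(j) brute_ci(A[, i], B[, j]))))
  expect_equal(group_pair_index(A, B), manual, tolerance = 1e-12)
  expect_equal(group_pair_index(A[, 1], B[, 1]),
               coactivation_index(A[, 1], B[, 1]))
  same <- matrix(rep(runif(20), 6), 20)
  expect_equal(group_pair_index(same[, 1:3], same[, 4:5]), 100)
})

test_that("segment report: block structure and compositional oracle", {
  groups <- muscle_groups(walker)
  n <- 50
  t <- (0:(n - 1)) / 100
  tb <- data.frame(time = t)
  one <- 0.3 + 0.2 * sin(2 * pi * t)
  for (nm in names(groups)) tb[[nm]] <- one
  rep_all <- segment_indices(tb, groups)
  expect_equal(unname(rep_all$pairs), rep(100, 4))
  expect_equal(rep_all$thigh_index, 100)

  # thigh muscles phasic/disjoint, shank muscles identical
  tb2 <- tb
  thigh_groups <- c("vastus", "biceps_femoris", "semitendinosus")
  half1 <- c(rep(0.5, n / 2), rep(0, n / 2))
  half2 <- c(rep(0, n / 2), rep(0.5, n / 2))
  for (nm in names(groups)) {
    if (groups[[nm]] == "vastus") tb2[[nm]] <- half1
    else if (groups[[nm]] %in% thigh_groups) tb2[[nm]] <- half2
  }
  rep2 <- segment_indices(tb2, groups)
  expect_equal(rep2$thigh_index, 0)
  expect_equal(rep2$shank_index, 100)

  # compositional check against hand-built pair averaging
  set.seed(34)
  tb3 <- data.frame(time = t)
  for (nm in names(groups)) tb3[[nm]] <- runif(n)
  rep3 <- segment_indices(tb3, groups)
  hand_pair <- function(ga, gb, side) {
    sel <- grep(paste0("_", side, "$"), names(groups), value = TRUE)
    A <- as.matrix(tb3[sel[groups[sel] == ga]])
    B <- as.matrix(tb3[sel[groups[sel] == gb]])
    mean(outer(seq_len(ncol(A)), seq_len(ncol(B)),
               Vectorize(function(i, j) brute_ci(A[, i], B[, j]))))
  }
  hand <- mean(c(hand_pair("vastus", "biceps_femoris", "r"),
                 hand_pair("vastus", "biceps_femoris", "l")))
  expect_equal(unname(rep3$pairs[["vastus-biceps_femoris"]]), hand,
               tolerance = 1e-10)
  expect_equal(rep3$thigh_index, mean(rep3$pairs[1:2]))
  expect_equal(rep3$shank_index, mean(rep3$pairs[3:4]))
})

test_that("a missing muscle group is reported by name", {
  groups <- muscle_groups(walker)
  tb <- data.frame(time = 1:10 / 100)
  for (nm in names(groups)[groups != "vastus"]) tb[[nm]] <- runif(10)
  expect_error(segment_indices(tb, groups[groups != "vastus"]), "vastus")
})

test_that("phase-resolved indices cover the cycle", {
  act <- synthetic_activation_traces(walker, n_cycles = 2)
  pr <- phase_resolved_indices(act, muscle_groups(walker),
                               cycle_duration = 1.1, n_bins = 10)
  expect_equal(nrow(pr), 10)
  expect_true(all(pr$thigh_index >= 0 & pr$thigh_index <= 100))
})
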
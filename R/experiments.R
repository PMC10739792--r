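# Stability protocols: slippery-ground and uneven-terrain survival
# experiments, heel-strike stability metrics, kinematics RMSD, and the
# chi-squared / ANOVA statistics used to compare controllers.

run_survival <- function(policies, conditions, make_cond_terrain, n_trials,
                         model, ref, seed, duration, init_phase, record_ci) {
  if (is.null(names(policies))) names(policies) <- paste0("policy", seq_along(policies))
  counts <- matrix(0L, length(policies), length(conditions),
                   dimnames = list(names(policies), names(conditions)))
  invalid <- counts
  ci_rows <- list()
  trial_seeds <- vapply(seq_len(n_trials), function(tr)
    derive_seed(seed, tr), integer(1))
  for (ci in seq_along(conditions)) {
    for (pi in seq_along(policies)) {
      for (tr in seq_len(n_trials)) {
        terr <- make_cond_terrain(conditions[[ci]], trial_seeds[tr])
        ep <- tryCatch(
          simulate_episode(policies[[pi]], model, terr, ref,
                           duration = duration, seed = trial_seeds[tr],
                           init_phase = init_phase, record = record_ci),
          error = function(e) e)
        if (inherits(ep, "error")) {
          invalid[pi, ci] <- invalid[pi, ci] + 1L
          warning("invalid trial (", conditionMessage(ep), ") for ",
                  names(policies)[pi], " at condition ", names(conditions)[ci],
                  call. = FALSE)
          next
        }
        if (ep$survived) counts[pi, ci] <- counts[pi, ci] + 1L
        if (record_ci) {
          tb <- episode_tables(ep)
          rep_ci <- tryCatch(suppressWarnings(
            segment_indices(tb$activations, muscle_groups(model))),
            error = function(e) NULL)
          if (!is.null(rep_ci))
            ci_rows[[length(ci_rows) + 1]] <- data.frame(
              policy = names(policies)[pi], condition = names(conditions)[ci],
              trial = tr, thigh_index = rep_ci$thigh_index,
              shank_index = rep_ci$shank_index, survived = ep$survived,
              fall_time = ep$fall_time %||% NA_real_)
        }
      }
    }
  }
  structure(list(survivals = counts, invalid = invalid,
                 n_trials = n_trials, conditions = conditions,
                 ci_table = if (record_ci) do.call(rbind, ci_rows) else NULL,
                 seed = seed),
            class = "survival_table")
}

#' @export
print.survival_table <- function(x, ...) {
  cat("Survivals out of", x$n_trials, "trials\n")
  print(x$survivals)
  if (any(x$invalid > 0)) {
    cat("Invalid (excluded) trials:\n")
    print(x$invalid)
  }
  invisible(x)
}

#' Slippery-ground survival experiment
#'
#' For every controller and slippery friction coefficient, runs seeded 20-s
#' walking trials on the slip-transition terrain (5 m run-in at the normal
#' friction 0.8, then the slippery region) and counts survivals. Trial seeds
#' are shared across controllers and conditions so runs are comparable;
#' episodes that raise a simulator error are excluded from the denominator
#' and reported, never counted as falls.
#'
#' @param policies named list of policies.
#' @param mu_list slippery friction coefficients (default the study set
#'   0.20, 0.25, 0.30, 0.35, 0.40).
#' @param n_trials repetitions per cell (study scale: 100).
#' @param model a `walker_model`.
#' @param ref a `reference_motion`.
#' @param seed integer seed.
#' @param duration trial length (s).
#' @param init_phase initial gait phase, or `"random"`.
#' @param record_ci also compute per-trial thigh/shank coactivation indices.
#' @return a `survival_table`.
#' @export
run_slip_experiment <- function(policies, mu_list = c(0.20, 0.25, 0.30, 0.35, 0.40),
                                n_trials = 5, model = build_planar_model(),
                                ref, seed = 0, duration = 20,
                                init_phase = 0, record_ci = FALSE) {
  conds <- setNames(as.list(mu_list), paste0("mu_", format(mu_list)))
  run_survival(policies, conds,
               function(mu, s) make_terrain("slip", mu = mu),
               n_trials, model, ref, seed, duration, init_phase, record_ci)
}

#' Uneven-terrain survival experiment
#'
#' As the slip experiment, but the region beyond the 5 m run-in is a seeded
#' Perlin heightfield with the given height scale; the terrain seed varies
#' per trial. A height scale of zero reduces to flat ground.
#'
#' @param height_scales heightfield amplitudes (m; study set 0.01-0.04).
#' @inheritParams run_slip_experiment
#' @return a `survival_table`.
#' @export
run_uneven_experiment <- function(policies, height_scales = c(0.01, 0.02, 0.03, 0.04),
                                  n_trials = 3, model = build_planar_model(),
                                  ref, seed = 0, duration = 20,
                                  init_phase = 0, record_ci = FALSE) {
  conds <- setNames(as.list(height_scales), paste0("h_", format(height_scales)))
  run_survival(policies, conds,
               function(h, s) if (h == 0) make_terrain("flat") else
                 make_terrain("uneven", height_scale = h, seed = s),
               n_trials, model, ref, seed, duration, init_phase, record_ci)
}

#' Heel-strike stability metrics of an episode
#'
#' At every detected heel strike: the stability margin as the horizontal
#' distance between the whole-body centre of mass and the lead foot's centre
#' of pressure, and the sagittal foot angle (degrees, positive = dorsiflexed,
#' heel-first contact).
#'
#' @param episode an `episode_record`.
#' @param model a `walker_model` (unused fields reserved).
#' @return data frame with `time`, `foot`, `stability_margin`,
#'   `foot_angle_deg`; empty (with a warning) when no heel strikes occurred.
#' @export
heel_strike_metrics <- function(episode, model = NULL) {
  hs <- episode$heel_strikes
  if (is.null(hs) || nrow(hs) == 0) {
    warning("episode contains no heel strikes")
    return(data.frame(time = numeric(0), foot = character(0),
                      stability_margin = numeric(0),
                      foot_angle_deg = numeric(0)))
  }
  data.frame(time = hs$time, foot = hs$foot,
             stability_margin = abs(hs$com_x - hs$cop_x),
             foot_angle_deg = hs$foot_angle_deg)
}

#' Per-joint kinematics RMSD between two motions
#'
#' Both tables are time-normalised (resampled to `n_points` per table span,
#' the gait-cycle normalisation) over the shared joint columns, and the
#' root-mean-squared difference is reported in degrees.
#'
#' @param sim,ref data frames with `time` plus joint-angle columns (rad).
#' @param n_points resampling resolution (default 100 points/cycle).
#' @return named numeric vector of per-joint RMSD in degrees.
#' @export
kinematics_rmsd <- function(sim, ref, n_points = 100) {
  joints <- intersect(setdiff(names(sim), "time"), setdiff(names(ref), "time"))
  if (!length(joints)) stop("no shared joint columns between the two tables")
  resample <- function(tb) {
    u <- (tb$time - tb$time[1]) / (tb$time[nrow(tb)] - tb$time[1])
    grid <- seq(0, 1, length.out = n_points)
    vapply(joints, function(j) approx(u, tb[[j]], grid)$y, numeric(n_points))
  }
  A <- resample(sim); B <- resample(ref)
  setNames(sqrt(colMeans((A - B)^2)) * 180 / pi, joints)
}

#' Chi-squared comparison of survival counts
#'
#' Omnibus Pearson chi-squared on the controllers x (survive, fall) table
#' pooled over conditions, followed by pairwise 2x2 chi-squared tests with
#' Bonferroni adjustment (raw p times the number of pairs, capped at 1).
#' Continuity correction is off (plain Pearson statistic). With
#' `exact = TRUE` Fisher's exact test replaces the chi-squared everywhere,
#' the fallback suggested when expected counts vanish.
#'
#' @param table a `survival_table` or a numeric matrix of survival counts
#'   (rows = controllers) with attribute-free counts and `n_trials`.
#' @param n_trials trials per cell (taken from the `survival_table` if given).
#' @param alpha significance level reported alongside (default 0.05).
#' @param exact use Fisher's exact test.
#' @return list with `omnibus` (statistic, df, p), `pairwise` (data frame
#'   with raw and Bonferroni-adjusted p), `alpha`, `pooled` (the pooled
#'   survive/fall table).
#' @export
survival_chi_squared <- function(table, n_trials = NULL, alpha = 0.05,
                                 exact = FALSE) {
  if (inherits(table, "survival_table")) {
    counts <- table$survivals
    n_per_cell <- table$n_trials - table$invalid
  } else {
    counts <- as.matrix(table)
    if (is.null(n_trials)) stop("n_trials required for a bare matrix")
    n_per_cell <- matrix(n_trials, nrow(counts), ncol(counts))
  }
  if (nrow(counts) < 2) stop("need at least 2 controllers")
  surv <- rowSums(counts)
  fall <- rowSums(n_per_cell) - surv
  pooled <- cbind(survive = surv, fall = fall)
  if (!exact && (any(rowSums(pooled) == 0) || any(colSums(pooled) == 0)))
    stop("a margin of the pooled table is zero; use exact = TRUE ",
         "(Fisher) instead")
  omni <- if (exact) {
    ft <- fisher.test(pooled, simulate.p.value = nrow(pooled) > 2, B = 1e4)
    list(statistic = NA_real_, df = NA_integer_, p = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(pooled, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value))
  }
  nms <- rownames(counts) %||% paste0("c", seq_len(nrow(counts)))
  prs <- utils::combn(seq_len(nrow(counts)), 2)
  n_pairs <- ncol(prs)
  pw <- lapply(seq_len(n_pairs), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    tb <- pooled[c(a, b), , drop = FALSE]
    p_raw <- if (exact) fisher.test(tb)$p.value else {
      if (any(colSums(tb) == 0)) 1 else
        suppressWarnings(unname(chisq.test(tb, correct = FALSE)$p.value))
    }
    if (is.na(p_raw)) p_raw <- 1
    data.frame(a = nms[a], b = nms[b], p_raw = p_raw,
               p_adjusted = min(1, p_raw * n_pairs))
  })
  list(omnibus = omni, pairwise = do.call(rbind, pw), alpha = alpha,
       pooled = pooled, n_pairs = n_pairs)
}

#' One-way ANOVA of per-trial coactivation indices across controllers
#'
#' @param values either a named list of numeric vectors (per-trial CI values
#'   per controller) or a data frame with columns `policy` and a value column.
#' @param value_col value column name when `values` is a data frame.
#' @param alpha significance level.
#' @return list with `omnibus` (F, df, p; p = 1 with `degenerate = TRUE` when
#'   all groups are constant and identical), `pairwise` (Bonferroni-adjusted
#'   pairwise t-tests), `alpha`.
#' @export
coactivation_anova <- function(values, value_col = "thigh_index",
                               alpha = 0.05) {
  if (is.data.frame(values)) {
    values <- split(values[[value_col]], values$policy)
  }
  if (length(values) < 2) stop("need at least 2 controllers")
  if (any(vapply(values, length, integer(1)) < 2))
    stop("need at least 2 trials per controller")
  g <- factor(rep(names(values), vapply(values, length, integer(1))))
  y <- unlist(values, use.names = FALSE)
  if (sd(y) == 0) {
    return(list(omnibus = list(F = NA_real_, df = c(length(values) - 1L,
                                                    length(y) - length(values)),
                               p = 1, degenerate = TRUE),
                pairwise = NULL, alpha = alpha))
  }
  fit <- aov(y ~ g)
  an <- summary(fit)[[1]]
  omni <- list(F = an[["F value"]][1], df = c(an[["Df"]][1], an[["Df"]][2]),
               p = an[["Pr(>F)"]][1], degenerate = FALSE)
  prs <- utils::combn(levels(g), 2)
  n_pairs <- ncol(prs)
  pw <- lapply(seq_len(n_pairs), function(i) {
    a <- values[[prs[1, i]]]; b <- values[[prs[2, i]]]
    p_raw <- if (sd(c(a, b)) == 0) 1 else
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    data.frame(a = prs[1, i], b = prs[2, i], p_raw = p_raw,
               p_adjusted = min(1, p_raw * n_pairs))
  })
  list(omnibus = omni, pairwise = do.call(rbind, pw), alpha = alpha)
}
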
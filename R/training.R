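# Proximal-policy-optimisation training of the gait controllers, at
# desk-compatible scale: clipped surrogate objective, GAE(lambda) advantages,
# advantage normalisation, Adam, random-reference-frame episode
# initialisation, early termination on falls.

#' Trainer configuration
#'
#' Defaults are desk-scale; the full-scale counterparts (200 environments,
#' 40,000 samples per update, 65,000 updates for the standard controller and
#' 20,000 for fine-tuning, 512/256 networks) remain selectable but are far
#' outside an interactive budget.
#'
#' @param n_envs parallel episodes per update.
#' @param horizon episode segment length per update (s).
#' @param control_hz control frequency.
#' @param updates number of PPO updates.
#' @param clip PPO clipping parameter.
#' @param gamma discount factor.
#' @param lambda GAE parameter.
#' @param lr Adam learning rate.
#' @param epochs gradient epochs per update.
#' @param minibatches minibatches per epoch.
#' @param entropy_coef entropy bonus coefficient.
#' @param hidden policy hidden layer sizes.
#' @param seed integer seed.
#' @return list of class `trainer_config`; `samples_per_update` is
#'   `n_envs * horizon * control_hz` unless overridden.
#' @export
trainer_config <- function(n_envs = 8, horizon = 2, control_hz = 100,
                           updates = 100, clip = 0.2, gamma = 0.99,
                           lambda = 0.95, lr = 3e-4, epochs = 4,
                           minibatches = 4, entropy_coef = 1e-3,
                           hidden = c(64, 32), seed = 0) {
  structure(list(n_envs = n_envs, horizon = horizon, control_hz = control_hz,
                 updates = updates, clip = clip, gamma = gamma,
                 lambda = lambda, lr = lr, epochs = epochs,
                 minibatches = minibatches, entropy_coef = entropy_coef,
                 hidden = hidden, seed = seed,
                 samples_per_update = n_envs * horizon * control_hz),
            class = "trainer_config")
}

adam_new <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}
adam_step <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
}

# flatten/unflatten MLP layer lists for the optimiser
net_params <- function(net) {
  unlist(lapply(seq_along(net), function(i) {
    setNames(list(net[[i]]$W, net[[i]]$b), paste0(c("W", "b"), i))
  }), recursive = FALSE)
}
net_from_params <- function(params, nl) {
  lapply(seq_len(nl), function(i)
    list(W = params[[paste0("W", i)]], b = params[[paste0("b", i)]]))
}

# Gaussian log-density per row, summed over action dims.
gauss_logp <- function(a, mu, sd) {
  rowSums(-0.5 * ((a - mu) / matrix(sd, nrow(a), length(sd), byrow = TRUE))^2) -
    sum(log(sd)) - 0.5 * ncol(a) * log(2 * pi)
}

#' Train a gait controller
#'
#' Runs PPO imitation training of the walker against a reference motion.
#' Episodes start at a random reference frame (joint angles and velocities
#' from the frame; initial muscle excitations and activations from the
#' policy's own output) and terminate early on falls. The per-step reward is
#' the variant's shaped total: the tracking kernels always, plus the
#' activation and stiffness kernels as weighted by the variant (stiffness is
#' the instantaneous analytic joint stiffness averaged over left/right
#' limbs). The ACT_RANDOM variant redraws the ground friction uniformly from
#' `[0.2, 0.8]` per episode; all other variants train on flat ground with the
#' normal friction 0.8.
#'
#' @param variant reward variant name (see [reward_spec()]).
#' @param reference a `reference_motion`.
#' @param config a [trainer_config()].
#' @param model a `walker_model` (default planar walker).
#' @param base_policy optional warm-start policy (fine-tuning).
#' @param spec optional explicit [reward_spec()] overriding `variant`.
#' @return object of class `trained_controller`: `policy` (best by mean
#'   episode tracking score), `final_policy`, `log` (per-update data frame),
#'   `config`, `variant`.
#' @export
train_controller <- function(variant = "STANDARD", reference, config = trainer_config(),
                             model = build_planar_model(), base_policy = NULL,
                             spec = NULL) {
  spec <- spec %||% reward_spec(variant)
  core <- model_core(model)
  nm <- length(model$muscles)
  layout <- observation_layout(model)
  pol <- base_policy %||% {
    nrm <- walker_obs_norm(model)
    mlp_policy(policy_spec(layout$length, nm, config$hidden),
               seed = config$seed, obs_center = nrm$center,
               obs_scale = nrm$scale)
  }
  if (pol$spec$n_obs != layout$length || pol$spec$n_act != nm)
    stop("base policy layout does not match model/observation")

  flat_terr <- terrain_core(make_terrain("flat"))
  T_ref <- reference$cycle_duration
  hz <- config$control_hz
  n_tick <- round(config$horizon * hz)
  ne <- config$n_envs
  W <- sum(model$segments$mass) * model$options$gravity
  jn <- joint_names(model)
  hip_i <- match(c("hip_r", "hip_l"), jn)
  knee_i <- match(c("knee_r", "knee_l"), jn)
  ankle_i <- match(c("ankle_r", "ankle_l"), jn)
  s_unit <- if (spec$stiffness_unit == "Nm/deg") pi / 180 else 1
  need_S <- spec$weights[["S"]] > 0
  mu_log <- numeric(0)

  with_seed(config$seed, function() {
    envs <- vector("list", ne)
    reset_env <- function() {
      phase0 <- runif(1)
      st <- sim_state_init(model, reference, phase0)
      mu_e <- if (!is.null(spec$mu_random))
        runif(1, spec$mu_random[1], spec$mu_random[2]) else 0.8
      terr <- flat_terr
      terr$mu0 <- mu_e
      mu_log <<- c(mu_log, mu_e)
      obs <- build_observation(model, NULL, st, phase0,
                               contact = list(grf_r = c(0, 0), grf_l = c(0, 0),
                                              cop_x = c(0, 0)))
      u0 <- policy_action(pol, obs, stochastic = FALSE)
      st[2 * (3 + length(jn)) + 1:nm] <- u0
      list(state = st, phase0 = phase0, tick = 0L, terr = terr,
           last = NULL, ep_rt = 0, ep_len = 0L)
    }
    for (e in seq_len(ne)) envs[[e]] <- reset_env()

    log_rows <- vector("list", config$updates)
    best <- list(score = -Inf, pol = pol)
    adam_p <- NULL; adam_v <- NULL; adam_s <- NULL; adam_t <- 0

    for (up in seq_len(config$updates)) {
      nS <- ne * n_tick
      OBS <- matrix(0, nS, layout$length)
      ACT <- matrix(0, nS, nm)
      LOGP <- numeric(nS); REW <- numeric(nS); DONE <- logical(nS)
      VAL <- numeric(nS)
      RT <- numeric(nS); SS <- numeric(nS)
      MU <- numeric(nS)
      ep_scores <- numeric(0)
      ep_sums <- numeric(0)
      row <- 0L
      sd_now <- exp(pol$log_std)
      for (k in seq_len(n_tick)) {
        obs_mat <- matrix(0, ne, layout$length)
        for (e in seq_len(ne)) {
          en <- envs[[e]]
          obs_mat[e, ] <- if (is.null(en$last)) {
            build_observation(model, NULL, en$state,
                              (en$phase0 + en$tick / hz / T_ref) %% 1,
                              contact = list(grf_r = c(0, 0), grf_l = c(0, 0),
                                             cop_x = c(0, 0)))
          } else {
            build_observation(model, NULL, en$state,
                              (en$phase0 + en$tick / hz / T_ref) %% 1,
                              contact = en$last)
          }
        }
        pm <- policy_mean(pol, obs_mat)
        vv <- policy_value(pol, obs_mat)$out[, 1]
        noise <- matrix(rnorm(ne * nm), ne)
        a_mat <- pm$mean + sweep(noise, 2, sd_now, "*")
        lp <- gauss_logp(a_mat, pm$mean, sd_now)
        for (e in seq_len(ne)) {
          en <- envs[[e]]
          u <- pmin(1, pmax(0, a_mat[e, ]))
          out <- cpp_step(core, en$terr, en$state, u, 10L, 1 / (hz * 10))
          st2 <- out$state
          t_now <- (en$tick + 1) / hz
          fr <- ref_lookup(reference, t_now, en$phase0)
          err <- list(ang = fr$theta - st2[4:(3 + length(jn))],
                      vel = fr$theta_dot - st2[(6 + length(jn) + 1):(6 + 2 * length(jn))],
                      end = fr$eff - out$eff,
                      com = fr$com - out$com)
          acts <- st2[2 * (3 + length(jn)) + 1:nm]
          S <- NULL
          if (need_S) {
            Kj <- cpp_joint_stiffness_inst(core, st2[1:(3 + length(jn))],
                                           acts, st2[2 * (3 + length(jn)) + nm + 1:nm])
            S <- c(hip = mean(Kj[hip_i]), knee = mean(Kj[knee_i]),
                   ankle = mean(Kj[ankle_i])) * s_unit
          }
          rw <- r_total(spec, err, acts, S)
          fell <- st2[2] < 0.6 * model$standing_height || abs(st2[3]) > pi / 3
          row <- row + 1L
          OBS[row, ] <- obs_mat[e, ]; ACT[row, ] <- a_mat[e, ]
          LOGP[row] <- lp[e]; VAL[row] <- vv[e]
          REW[row] <- rw$total; DONE[row] <- fell
          RT[row] <- rw$r_track
          MU[row] <- mean(pm$mean[e, ])
          SS[row] <- if (need_S) mean(S) else NA_real_
          en$ep_rt <- en$ep_rt + rw$r_track; en$ep_len <- en$ep_len + 1L
          if (fell) {
            ep_scores <- c(ep_scores, en$ep_rt / en$ep_len)
            ep_sums <- c(ep_sums, en$ep_rt)
            envs[[e]] <- reset_env()
          } else {
            en$state <- st2
            en$tick <- en$tick + 1L
            en$last <- list(grf_r = out$grf_r, grf_l = out$grf_l,
                            cop_x = out$cop_x)
            envs[[e]] <- en
          }
        }
      }
      # bootstrap values for unfinished episodes
      obs_boot <- t(vapply(envs, function(en) {
        build_observation(model, NULL, en$state,
                          (en$phase0 + en$tick / hz / T_ref) %% 1,
                          contact = en$last %||% list(grf_r = c(0, 0),
                                                      grf_l = c(0, 0),
                                                      cop_x = c(0, 0)))
      }, numeric(layout$length)))
      v_boot <- policy_value(pol, obs_boot)$out[, 1]
      # rows are ordered tick-major (k, then env): compute GAE per env
      ADV <- numeric(nS); RET <- numeric(nS)
      for (e in seq_len(ne)) {
        idx <- seq(e, nS, by = ne)
        adv <- 0
        nxt_v <- v_boot[e]
        for (i in rev(seq_along(idx))) {
          r <- idx[i]
          nonterm <- !DONE[r]
          delta <- REW[r] + config$gamma * nxt_v * nonterm - VAL[r]
          adv <- delta + config$gamma * config$lambda * nonterm * adv
          ADV[r] <- adv
          RET[r] <- adv + VAL[r]
          nxt_v <- VAL[r]
          if (DONE[r]) adv <- 0
        }
      }
      ADV <- (ADV - mean(ADV)) / (sd(ADV) + 1e-8)

      # PPO epochs
      if (is.null(adam_p)) {
        adam_p <- adam_new(net_params(pol$net))
        adam_v <- adam_new(net_params(pol$value))
        adam_s <- adam_new(list(ls = pol$log_std))
      }
      nl <- length(pol$net)
      for (ep in seq_len(config$epochs)) {
        perm <- sample.int(nS)
        mbs <- if (config$minibatches <= 1) list(perm) else
          split(perm, cut(seq_along(perm), config$minibatches, labels = FALSE))
        for (mb in mbs) {
          X <- OBS[mb, , drop = FALSE]
          A <- ACT[mb, , drop = FALSE]
          pmb <- policy_mean(pol, X)
          sdv <- exp(pol$log_std)
          lp_new <- gauss_logp(A, pmb$mean, sdv)
          ratio <- exp(lp_new - LOGP[mb])
          adv <- ADV[mb]
          clipped <- (adv > 0 & ratio > 1 + config$clip) |
            (adv < 0 & ratio < 1 - config$clip)
          # d(-surrogate)/d(lp) per row
          g_lp <- ifelse(clipped, 0, -ratio * adv) / length(mb)
          SDm <- matrix(sdv, length(mb), nm, byrow = TRUE)
          dmu <- (A - pmb$mean) / SDm^2
          d_out <- (g_lp * dmu) * pmb$mean * (1 - pmb$mean)
          grads <- mlp_backward(pol$net, pmb$fw, d_out)
          # log-std gradient: surrogate + entropy bonus
          dls_rows <- ((A - pmb$mean)^2 / SDm^2 - 1)
          g_ls <- colSums(g_lp * dls_rows) - config$entropy_coef
          # value loss
          fwv <- policy_value(pol, X)
          verr <- (fwv$out[, 1] - RET[mb]) / length(mb)
          gv <- mlp_backward(pol$value, fwv, matrix(verr, ncol = 1))
          adam_t <- adam_t + 1
          for (i in seq_len(nl)) {
            r1 <- adam_step(pol$net[[i]]$W, grads[[i]]$W,
                            adam_p[[paste0("W", i)]], config$lr, adam_t)
            pol$net[[i]]$W <- r1$p; adam_p[[paste0("W", i)]] <- r1$st
            r2 <- adam_step(pol$net[[i]]$b, grads[[i]]$b,
                            adam_p[[paste0("b", i)]], config$lr, adam_t)
            pol$net[[i]]$b <- r2$p; adam_p[[paste0("b", i)]] <- r2$st
            r3 <- adam_step(pol$value[[i]]$W, gv[[i]]$W,
                            adam_v[[paste0("W", i)]], config$lr, adam_t)
            pol$value[[i]]$W <- r3$p; adam_v[[paste0("W", i)]] <- r3$st
            r4 <- adam_step(pol$value[[i]]$b, gv[[i]]$b,
                            adam_v[[paste0("b", i)]], config$lr, adam_t)
            pol$value[[i]]$b <- r4$p; adam_v[[paste0("b", i)]] <- r4$st
          }
          r5 <- adam_step(pol$log_std, g_ls, adam_s$ls, config$lr, adam_t)
          pol$log_std <- pmin(0, pmax(-4, r5$p)); adam_s$ls <- r5$st
          if (any(!is.finite(unlist(lapply(pol$net, `[[`, "W")))))
            stop("training diverged (non-finite policy weights) at update ", up)
        }
      }
      mean_rt <- mean(RT)
      log_rows[[up]] <- data.frame(
        update = up, mean_reward = mean(REW), mean_r_track = mean_rt,
        mean_ep_len = nS / max(1, sum(DONE) + ne),
        mean_stiffness = if (need_S) mean(SS) else NA_real_,
        mean_action = mean(MU),
        mean_ep_return = if (length(ep_sums)) mean(ep_sums) else NA_real_,
        value_ev = 1 - stats::var(RET - VAL) / max(stats::var(RET), 1e-9),
        sd_mean = mean(exp(pol$log_std)))
      if (mean_rt > best$score) best <- list(score = mean_rt, pol = pol)
    }
    structure(list(policy = best$pol, final_policy = pol,
                   log = do.call(rbind, log_rows), config = config,
                   variant = spec$variant, reward_spec = spec,
                   mu_values = mu_log),
              class = "trained_controller")
  })
}

#' Fine-tune a trained controller under a shaping variant
#'
#' Warm-starts PPO from an existing policy with the variant's reward
#' (activation minimisation and/or joint-stiffness targets per the objective
#' table); training ground is flat with friction 0.8 except for ACT_RANDOM's
#' per-episode random friction.
#'
#' @param policy a `walker_policy` or `trained_controller`.
#' @param variant one of ACT, STIF0, STIF1, STIF2, STIF3, ACT_RANDOM.
#' @param reference a `reference_motion`.
#' @param config a [trainer_config()].
#' @param model a `walker_model`.
#' @return a `trained_controller`.
#' @export
finetune <- function(policy, variant, reference, config = trainer_config(),
                     model = build_planar_model()) {
  if (inherits(policy, "trained_controller")) policy <- policy$policy
  if (!variant %in% c("ACT", "STIF0", "STIF1", "STIF2", "STIF3", "ACT_RANDOM"))
    stop("unknown fine-tuning variant '", variant, "'")
  train_controller(variant, reference, config, model, base_policy = policy)
}
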